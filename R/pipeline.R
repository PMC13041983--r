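# cli_pipeline: run the full analysis from a single config list and write a
# manifest. Stages: qc -> abego -> distances -> disulfides -> topology ->
# features -> structspace -> entropy.

#' Assemble a pipeline configuration
#'
#' Defaults equal the analysis parameters used throughout the package
#' (confidence 60 over 80% of the length, 70 residues, >1 helix, 0.99
#' dedup identity, correlation threshold 0.85, UMAP 30 neighbors / 0.05
#' min distance, Leiden resolution 1.2).
#'
#' @param structures_dir directory of PDB files (predicted models).
#' @param fasta optional FASTA of sequences (defaults to structure-derived
#'   sequences).
#' @param alignment optional aligned FASTA for the entropy stage.
#' @param reference_id alignment row / model id to map entropy onto.
#' @param output_dir output directory.
#' @param seed integer seed for embedding/clustering.
#' @param ... overrides for named parameters (`conf_cut`, `frac_cut`,
#'   `min_len`, `min_helices`, `dedup_identity`, `r_threshold`,
#'   `k_neighbors`, `resolution`, `n_neighbors`, `min_dist`, `probe`,
#'   `n_points`, `link_cutoff`, `min_run`, `max_ss`). Unknown keys are
#'   rejected.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(structures_dir, output_dir, fasta = NULL,
                            alignment = NULL, reference_id = NULL,
                            seed = 0, ...) {
  cfg <- list(structures_dir = structures_dir, output_dir = output_dir,
              fasta = fasta, alignment = alignment,
              reference_id = reference_id, seed = seed,
              conf_cut = 60, frac_cut = 0.80, min_len = 70, min_helices = 2,
              dedup_identity = 0.99, r_threshold = 0.85, k_neighbors = 15,
              resolution = 1.2, n_neighbors = 30, min_dist = 0.05,
              probe = 1.4, n_points = 960, link_cutoff = 14, min_run = 6,
              max_ss = 2.4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!dir.exists(structures_dir))
    stop("structures_dir does not exist: ", structures_dir)
  for (p in c(fasta, alignment))
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order, each writing its outputs before the next
#' reads them; identical config + seed reproduces identical outputs. Without
#' `force`, an existing non-empty output directory is refused.
#'
#' @param config a [pipeline_config()].
#' @param force overwrite existing outputs.
#' @return the manifest (named list; also written as `manifest.json`),
#'   invisibly containing per-stage outputs, parameters and item counts.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (dir.exists(out) && length(list.files(out)) && !force)
    stop("output dir ", out, " is not empty; use force = TRUE to overwrite")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg); cat(msg, "\n", file = logf, append = TRUE)
  }
  manifest <- list(parameters = unclass(config), stages = list())
  paths <- sort(list.files(config$structures_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  if (!length(paths)) stop("no PDB files in ", config$structures_dir)
  models <- lapply(paths, read_structure, is_predicted = TRUE)
  say("loaded %d models from %s", length(models), config$structures_dir)

  # qc
  qc <- qc_filter(models, conf_cut = config$conf_cut,
                  frac_cut = config$frac_cut, min_len = config$min_len,
                  min_helices = config$min_helices,
                  dedup_identity = config$dedup_identity,
                  min_run = config$min_run)
  utils::write.csv(qc$decisions, file.path(out, "qc_decisions.csv"),
                   row.names = FALSE)
  summ <- qc_summary(qc$decisions)
  jsonlite::write_json(as.list(summ), file.path(out, "qc_summary.json"),
                       auto_unbox = TRUE)
  say("qc: %d/%d models kept (removed: %d confidence, %d length/helix, %d duplicate)",
      summ$remaining, summ$initial, summ$removed_confidence,
      summ$removed_length_helix, summ$removed_duplicate)
  manifest$stages$qc <- list(outputs = c("qc_decisions.csv",
                                         "qc_summary.json"),
                             counts = as.list(summ))
  kept <- qc$kept
  if (length(kept) < 2) stop("pipeline aborted at stage qc: fewer than 2 ",
                             "models survive filtering")

  # abego
  abegos <- lapply(kept, abego_string)
  ab_df <- data.frame(model_id = vapply(abegos, `[[`, "", "model_id"),
                      abego = vapply(abegos, `[[`, "", "states"))
  utils::write.table(ab_df, file.path(out, "abego.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest$stages$abego <- list(outputs = "abego.tsv",
                                counts = list(models = nrow(ab_df)))
  say("abego: %d strings", nrow(ab_df))

  # distances (sequence + abego)
  seqs <- data.frame(id = vapply(kept, `[[`, "", "id"),
                     sequence = vapply(kept, model_sequence, ""))
  if (!is.null(config$fasta)) {
    fa <- read_fasta(config$fasta)
    hit <- match(seqs$id, fa$id)
    seqs$sequence[!is.na(hit)] <- fa$sequence[hit[!is.na(hit)]]
  }
  dm_seq <- distance_matrix(seqs)
  dm_ab <- distance_matrix(abegos)
  write_matrix_csv(dm_seq, file.path(out, "dist_sequence.csv"))
  write_matrix_csv(dm_ab, file.path(out, "dist_abego.csv"))
  manifest$stages$distances <- list(outputs = c("dist_sequence.csv",
                                                "dist_abego.csv"),
                                    counts = list(n = nrow(dm_seq)))
  say("distances: %d x %d sequence and ABEGO matrices", nrow(dm_seq),
      ncol(dm_seq))

  # disulfides
  ss_rows <- lapply(kept, function(m) {
    b <- analyze_disulfides(m, max_ss = config$max_ss)$bonds
    if (nrow(b)) cbind(model_id = m$id, b) else NULL
  })
  ss <- do.call(rbind, ss_rows)
  if (is.null(ss)) ss <- data.frame(model_id = character())
  utils::write.table(ss, file.path(out, "disulfides.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest$stages$disulfides <- list(outputs = "disulfides.tsv",
                                     counts = list(bonds = nrow(ss)))
  say("disulfides: %d bonds", nrow(ss))

  # topology
  topo <- do.call(rbind, lapply(seq_along(kept), function(i)
    topology_report(kept[[i]], sequence = seqs$sequence[i],
                    link_cutoff = config$link_cutoff,
                    min_run = config$min_run)))
  utils::write.table(topo, file.path(out, "topology.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest$stages$topology <- list(
    outputs = "topology.tsv",
    counts = as.list(table(topo$topology_label)))
  say("topology: %s", paste(names(table(topo$topology_label)),
                            table(topo$topology_label), collapse = ", "))

  # features
  feats <- feature_table(kept, probe = config$probe,
                         n_points = config$n_points)
  utils::write.csv(feats, file.path(out, "features.csv"), row.names = FALSE)
  pruned <- prune_correlated(feats, r_threshold = config$r_threshold)
  utils::write.csv(pruned$features, file.path(out, "features_reduced.csv"),
                   row.names = FALSE)
  manifest$stages$features <- list(
    outputs = c("features.csv", "features_reduced.csv"),
    counts = list(features = ncol(feats) - 1,
                  reduced = ncol(pruned$features) - 1))
  say("features: %d -> %d after pruning", ncol(feats) - 1,
      ncol(pruned$features) - 1)

  # structure space
  dm_tm <- all_vs_all(kept)
  write_matrix_csv(dm_tm, file.path(out, "dist_tm.csv"))
  n_items <- nrow(dm_tm)
  if (n_items >= 10) {
    cl <- embed_and_cluster(dm_tm, "tsne_on_distances",
                            k_neighbors = config$k_neighbors,
                            resolution = config$resolution,
                            seed = config$seed)
    utils::write.csv(data.frame(model_id = cl$labels,
                                cluster = cl$cluster_ids,
                                x = cl$embedding[, 1],
                                y = cl$embedding[, 2]),
                     file.path(out, "structspace_clusters.csv"),
                     row.names = FALSE)
    writeLines(cl$medoid_per_cluster, file.path(out, "medoids.txt"))
    manifest$stages$structspace <- list(
      outputs = c("dist_tm.csv", "structspace_clusters.csv", "medoids.txt"),
      counts = list(clusters = cl$n_clusters))
    say("structspace: %d clusters", cl$n_clusters)
  } else {
    manifest$stages$structspace <- list(outputs = "dist_tm.csv",
                                        counts = list(clusters = NA))
    say("structspace: %d models (< 10), skipped embedding", n_items)
  }

  # entropy
  if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    prof <- shannon_entropy(aln)
    utils::write.table(prof, file.path(out, "entropy.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- "entropy.tsv"
    ref_id <- config$reference_id
    if (!is.null(ref_id)) {
      ref <- kept[[which(vapply(kept, `[[`, "", "id") == ref_id)[1]]]
      mapped <- map_entropy(prof, aln, ref, ref_id)
      write_structure(mapped$model, file.path(out, "entropy_mapped.pdb"),
                      per_residue_values = mapped$values)
      outputs <- c(outputs, "entropy_mapped.pdb")
    }
    manifest$stages$entropy <- list(outputs = outputs,
                                    counts = list(columns = nrow(prof)))
    say("entropy: %d columns", nrow(prof))
  }

  manifest$versions <- list(
    bicyclefold = as.character(utils::packageVersion("bicyclefold")),
    R = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  say("pipeline complete: %d stages", length(manifest$stages))
  invisible(manifest)
}
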