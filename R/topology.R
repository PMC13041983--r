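# topology: grouping helices into bundles, tandem vs helix-swapped domain
# classification, C-Y-C motif counting.

#' Group helices into bundles by single-linkage clustering of midpoints
#'
#' @param helices data.frame from [find_helices()] (with midpoint columns).
#' @param link_cutoff single-linkage merge cutoff in Angstrom (default 14:
#'   between the generator's intra-bundle < 12 and inter-bundle > 20
#'   contract).
#' @return list of integer vectors of helix indices (1-based, sequence
#'   order), ordered by smallest member.
#' @export
cluster_bundles <- function(helices, link_cutoff = 14) {
  n <- nrow(helices)
  if (n < 1) stop("need at least one helix")
  if (n == 1) return(list(1L))
  mids <- as.matrix(helices[, c("mx", "my", "mz")])
  hc <- stats::hclust(stats::dist(mids), method = "single")
  memb <- stats::cutree(hc, h = link_cutoff)
  groups <- unname(split(seq_len(n), memb))
  groups <- lapply(groups, as.integer)
  groups[order(vapply(groups, min, integer(1)))]
}

#' Classify saposin-like domain topology from bundle membership
#'
#' With bundles ordered by smallest member, contiguous sequence blocks of the
#' same sizes are the tandem reference. `"tandem"` when every bundle is
#' exactly a contiguous block; `"helix-swapped"` when exactly one helix is
#' exchanged between two adjacent blocks (the alpha4/alpha4' swap);
#' `"single"` for one bundle; `"unresolved"` when any bundle has fewer than
#' 3 helices; anything else is `"mixed"`.
#'
#' @param bundles list of helix-index sets from [cluster_bundles()].
#' @param n_helices total helix count.
#' @return one of `"single"`, `"tandem"`, `"helix-swapped"`, `"mixed"`,
#'   `"unresolved"`.
#' @export
classify_topology <- function(bundles, n_helices) {
  if (any(vapply(bundles, length, integer(1)) < 3)) return("unresolved")
  if (length(bundles) == 1) return("single")
  bundles <- bundles[order(vapply(bundles, min, integer(1)))]
  sizes <- vapply(bundles, length, integer(1))
  ends <- cumsum(sizes)
  blocks <- lapply(seq_along(sizes), function(k)
    (ends[k] - sizes[k] + 1L):ends[k])
  extra <- lapply(seq_along(bundles), function(k)
    setdiff(bundles[[k]], blocks[[k]]))
  n_extra <- vapply(extra, length, integer(1))
  if (all(n_extra == 0)) return("tandem")
  off <- which(n_extra > 0)
  if (length(off) == 2 && all(n_extra[off] == 1) && diff(off) == 1) {
    # one helix exchanged between two adjacent blocks
    a <- off[1]; b <- off[2]
    if (extra[[a]] %in% blocks[[b]] && extra[[b]] %in% blocks[[a]])
      return("helix-swapped")
  }
  "mixed"
}

#' Count C-Y-C motifs and name the cycle class
#'
#' Non-overlapping exact `CYC` tripeptides, scanned left to right.
#'
#' @param sequence uppercase amino-acid string.
#' @return list with `n` (count) and `cycle_class` (`"unicycle"`,
#'   `"bicycle"`, ... `"hexacycle"`, else `"<n>-cycle"`).
#' @export
count_cyc_motifs <- function(sequence) {
  hits <- gregexpr("CYC", sequence, fixed = TRUE)[[1]]
  n <- if (hits[1] == -1) 0L else length(hits)
  names6 <- c("unicycle", "bicycle", "tricycle", "tetracycle", "pentacycle",
              "hexacycle")
  cls <- if (n >= 1 && n <= 6) names6[n] else paste0(n, "-cycle")
  list(n = n, cycle_class = cls)
}

#' Full topology report for one model
#'
#' Runs the ABEGO/helix/bundle pipeline and motif counting and assembles one
#' report row.
#'
#' @param model a `structure_model`.
#' @param sequence optional sequence for motif counting (defaults to the
#'   model's own sequence).
#' @param link_cutoff bundle clustering cutoff (Angstrom).
#' @param min_run minimum helix length (residues).
#' @return one-row data.frame: `model_id`, `n_helices`, `n_domains`,
#'   `topology_label`, `n_cyc_motifs`, `cycle_class`, and `bundles` as a
#'   `;`-separated string of comma-joined helix indices.
#' @export
topology_report <- function(model, sequence = NULL, link_cutoff = 14,
                            min_run = 6) {
  if (is.null(sequence)) sequence <- model_sequence(model)
  ab <- abego_string(model)
  hs <- find_helices(ab, model, min_run = min_run)
  if (nrow(hs) == 0) {
    bundles <- list()
    label <- "unresolved"
  } else {
    bundles <- cluster_bundles(hs, link_cutoff = link_cutoff)
    label <- classify_topology(bundles, nrow(hs))
  }
  cyc <- count_cyc_motifs(sequence)
  data.frame(
    model_id = model$id, n_helices = nrow(hs),
    n_domains = sum(vapply(bundles, length, integer(1)) >= 3),
    topology_label = label, n_cyc_motifs = cyc$n,
    cycle_class = cyc$cycle_class,
    bundles = paste(vapply(bundles, function(b)
      paste(b, collapse = ","), character(1)), collapse = ";"),
    stringsAsFactors = FALSE)
}
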