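# sequence_space: normalized Levenshtein distances over amino-acid and ABEGO
# strings, isolation statistic, near-duplicate removal, hierarchical
# clustering, Shannon-entropy conservation profiles.

#' Length-normalized Levenshtein distance
#'
#' D(a, b) = d(a, b) / max(|a|, |b|), where d is the unit-cost edit distance
#' (substitutions, insertions, deletions). Symmetric, in \[0, 1\], zero iff
#' the strings are equal.
#'
#' @param a,b character strings; at least one non-empty.
#' @return distance in \[0, 1\].
#' @export
normalized_levenshtein <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 && lb == 0)
    stop("both strings empty: normalized distance undefined (0/0)")
  as.numeric(utils::adist(a, b)) / max(la, lb)
}

#' All-vs-all normalized Levenshtein distance matrix
#'
#' The same routine serves amino-acid sequences and ABEGO backbone-state
#' strings.
#'
#' @param records data.frame with `id` and `sequence` columns, a named
#'   character vector, or a list of `abego_string` objects.
#' @return a `distance_matrix` (symmetric, zero diagonal, labelled).
#' @export
distance_matrix <- function(records) {
  if (is.list(records) && length(records) &&
      inherits(records[[1]], "abego_string")) {
    records <- data.frame(
      id = vapply(records, `[[`, character(1), "model_id"),
      sequence = vapply(records, `[[`, character(1), "states"),
      stringsAsFactors = FALSE)
  }
  records <- as_sequence_records(records)
  if (nrow(records) < 2) stop("need at least 2 records")
  if (anyDuplicated(records$id))
    stop("duplicate labels: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  d <- utils::adist(records$sequence)
  lens <- nchar(records$sequence)
  norm <- outer(lens, lens, pmax)
  as_distance_matrix(d / norm, labels = records$id)
}

#' Isolation fraction profile
#'
#' For each label a, the fraction of other members b whose distance
#' D(a, b) >= T.
#'
#' @param matrix a `distance_matrix`.
#' @param T threshold in \[0, 1\].
#' @return data.frame with `label` and `frac_ge_T`.
#' @export
isolation_fraction <- function(matrix, T) {
  stopifnot(T >= 0, T <= 1)
  n <- nrow(matrix)
  if (n < 2) stop("need at least 2 labels")
  frac <- vapply(seq_len(n), function(i)
    sum(matrix[i, -i] >= T) / (n - 1), numeric(1))
  data.frame(label = rownames(matrix), frac_ge_T = frac,
             stringsAsFactors = FALSE)
}

#' Greedy near-duplicate removal
#'
#' Records are scanned in input order; a record is removed when its identity
#' (1 - normalized Levenshtein) to any already-kept record exceeds the
#' threshold. Kept order is stable.
#'
#' @param records data.frame with `id`, `sequence` (or named character).
#' @param identity_threshold records with identity strictly greater than this
#'   to a kept record are dropped (default 0.99, i.e. ">99.0% identity").
#' @return list with `kept` and `removed` data.frames.
#' @export
deduplicate <- function(records, identity_threshold = 0.99) {
  records <- as_sequence_records(records)
  n <- nrow(records)
  keep <- logical(n)
  kept_idx <- integer()
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in kept_idx) {
      idy <- 1 - normalized_levenshtein(records$sequence[i],
                                        records$sequence[j])
      if (idy > identity_threshold) { dup <- TRUE; break }
    }
    if (!dup) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' @param matrix a `distance_matrix`.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return an [stats::hclust] object (merge list with heights).
#' @export
hierarchical_cluster <- function(matrix,
                                 linkage = c("average", "single",
                                             "complete")) {
  linkage <- match.arg(linkage)
  stats::hclust(stats::as.dist(matrix), method = linkage)
}

#' Per-column Shannon entropy of an alignment
#'
#' H_j = -sum_a p_aj log2 p_aj over the 20 amino acids; gaps are excluded
#' from the counts. Columns with more than half gaps are flagged
#' low-coverage.
#'
#' @param alignment an `aa_alignment`.
#' @param base `"bits"` (log2, default) or `"nats"`.
#' @return data.frame with `column`, `entropy`, `n_ungapped`,
#'   `low_coverage`.
#' @export
shannon_entropy <- function(alignment, base = c("bits", "nats")) {
  base <- match.arg(base)
  logf <- if (base == "bits") log2 else log
  m <- do.call(rbind, strsplit(alignment$records$sequence, ""))
  ent <- numeric(alignment$n_columns)
  nug <- integer(alignment$n_columns)
  for (j in seq_len(alignment$n_columns)) {
    col <- m[, j]
    col <- col[col %in% names(AA123)]
    nug[j] <- length(col)
    if (length(col) == 0) { ent[j] <- NA_real_; next }
    p <- table(col) / length(col)
    ent[j] <- -sum(p * logf(p))
  }
  data.frame(column = seq_len(alignment$n_columns), entropy = ent,
             n_ungapped = nug,
             low_coverage = nug < nrow(m) / 2)
}

#' Map an entropy profile onto a reference structure
#'
#' Alignment columns that are non-gap in the reference row are mapped, in
#' order, to the residues of the reference structure; the entropy values are
#' written into the structure's B-factor column (use [write_structure()] to
#' export). The reference row's ungapped sequence must match the structure's
#' sequence.
#'
#' @param profile data.frame from [shannon_entropy()].
#' @param alignment the `aa_alignment` the profile came from.
#' @param reference a `structure_model`.
#' @param reference_row_id id of the alignment row corresponding to the
#'   reference structure.
#' @return list with `model` (the structure with entropy in its B-factors)
#'   and `values` (per-residue entropy vector).
#' @export
map_entropy <- function(profile, alignment, reference, reference_row_id) {
  row <- alignment$records$sequence[alignment$records$id == reference_row_id]
  if (length(row) != 1)
    stop("reference row '", reference_row_id, "' not found in alignment")
  chars <- strsplit(row, "")[[1]]
  non_gap <- which(chars != "-")
  degapped <- paste(chars[non_gap], collapse = "")
  sseq <- model_sequence(reference)
  if (degapped != sseq) {
    cmp <- utils::head(which(strsplit(degapped, "")[[1]] !=
                               strsplit(sseq, "")[[1]]), 1)
    if (!length(cmp)) cmp <- min(nchar(degapped), nchar(sseq)) + 1
    stop("reference row does not match structure sequence ",
         "(first mismatch at position ", cmp, ")")
  }
  values <- profile$entropy[non_gap]
  key <- paste(reference$atoms$chain, reference$atoms$resno,
               reference$atoms$insert, sep = "\r")
  rt <- residue_table(reference)
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  reference$atoms$b <- values[match(key, rkey)]
  list(model = reference, values = values)
}
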