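# qc_filter: model-retention rules for predicted-structure cohorts
# (confidence, length, helix content, near-duplicate sequences).

#' Quality-filter a set of predicted structure models
#'
#' A model passes confidence when the fraction of residues with pLDDT >=
#' `conf_cut` is at least `frac_cut` (`rule = "fraction"`, default), or —
#' under `rule = "median_window"` — when some contiguous window covering
#' `frac_cut` of the chain has median pLDDT >= `conf_cut`. It passes length
#' when it has at least `min_len` residues, and helix content when it has at
#' least `min_helices` helices. Survivors are deduplicated at
#' `dedup_identity` sequence identity ([deduplicate()]). All applicable fail
#' reasons are recorded; stage-wise attribution follows the order
#' confidence, then length/helix, then duplicate.
#'
#' @param models list of `structure_model` objects carrying per-residue
#'   confidence.
#' @param conf_cut pLDDT cutoff (default 60).
#' @param frac_cut fraction of the length the cutoff must cover
#'   (default 0.80).
#' @param min_len minimum residue count (default 70).
#' @param min_helices minimum number of helices (default 2, i.e. "more than
#'   one").
#' @param dedup_identity sequence-identity threshold for duplicate removal
#'   (default 0.99).
#' @param rule confidence rule, `"fraction"` or `"median_window"`.
#' @param min_run minimum helix run length passed to [find_helices()].
#' @return list with `kept` (list of passing models) and `decisions`
#'   (data.frame: `model_id`, `n_res`, `frac_confident`, `n_helices`,
#'   `passed`, `fail_reasons` as comma-joined string).
#' @export
qc_filter <- function(models, conf_cut = 60, frac_cut = 0.80, min_len = 70,
                      min_helices = 2, dedup_identity = 0.99,
                      rule = c("fraction", "median_window"), min_run = 6) {
  rule <- match.arg(rule)
  rows <- lapply(models, function(m) {
    rt <- residue_table(m)
    conf <- rt$confidence
    if (any(is.na(conf)))
      stop("model '", m$id, "' lacks per-residue confidence values")
    n <- nrow(rt)
    frac_conf <- mean(conf >= conf_cut)
    conf_ok <- if (rule == "fraction") {
      frac_conf >= frac_cut
    } else {
      w <- ceiling(frac_cut * n)
      if (w > n) w <- n
      any(vapply(seq_len(n - w + 1), function(s)
        stats::median(conf[s:(s + w - 1)]) >= conf_cut, logical(1)))
    }
    nhel <- nrow(find_helices(abego_string(m), min_run = min_run))
    reasons <- character()
    if (!conf_ok) reasons <- c(reasons, "confidence")
    if (n < min_len) reasons <- c(reasons, "length")
    if (nhel < min_helices) reasons <- c(reasons, "helix_content")
    data.frame(model_id = m$id, n_res = n, frac_confident = frac_conf,
               n_helices = nhel,
               fail_reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, rows)
  surv <- which(decisions$fail_reasons == "")
  if (length(surv)) {
    recs <- data.frame(
      id = decisions$model_id[surv],
      sequence = vapply(models[surv], model_sequence, character(1)),
      stringsAsFactors = FALSE)
    dd <- deduplicate(recs, identity_threshold = dedup_identity)
    dup_ids <- dd$removed$id
    is_dup <- decisions$model_id %in% dup_ids &
      decisions$fail_reasons == ""
    decisions$fail_reasons[is_dup] <- "duplicate"
  }
  decisions$passed <- decisions$fail_reasons == ""
  kept <- models[decisions$passed]
  list(kept = kept, decisions = decisions)
}

#' Stage-wise summary of QC decisions
#'
#' Counts partition the input exactly: each failing model is attributed to
#' its first failing stage (confidence, then length/helix, then duplicate).
#'
#' @param decisions the `decisions` data.frame from [qc_filter()].
#' @return one-row data.frame: `initial`, `removed_confidence`,
#'   `removed_length_helix`, `removed_duplicate`, `remaining`.
#' @export
qc_summary <- function(decisions) {
  first_reason <- vapply(strsplit(decisions$fail_reasons, ","), function(r)
    if (length(r) == 0 || r[1] == "") "" else r[1], character(1))
  out <- data.frame(
    initial = nrow(decisions),
    removed_confidence = sum(first_reason == "confidence"),
    removed_length_helix = sum(first_reason %in%
                                 c("length", "helix_content")),
    removed_duplicate = sum(first_reason == "duplicate"),
    remaining = sum(decisions$passed))
  stopifnot(out$initial == out$remaining + out$removed_confidence +
              out$removed_length_helix + out$removed_duplicate)
  out
}
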