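# structure_space: TM-score with a simplified alignment search
# (threading + ABEGO-seeded Needleman-Wunsch, iteratively refined by Kabsch
# superposition and distance-matrix re-alignment), all-vs-all distance
# matrices, embedding, Leiden graph clustering, medoids.

tm_d0 <- function(L) {
  if (L <= 21) return(0.5)
  max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8)
}

#' TM-score of an aligned coordinate pair
#'
#' TM = (1/L_target) sum_i 1 / (1 + (d_i/d0)^2) with d0 =
#' 1.24 (L_target - 15)^(1/3) - 1.8, floored at 0.5 (and fixed to 0.5 for
#' L_target <= 21). The superposition maximizing the score is searched by
#' iterated Kabsch fits on the d_i < d0-cutoff subset, seeded from the full
#' set and from contiguous fragments.
#'
#' @param coords_a,coords_b equal-length n x 3 CA coordinate matrices
#'   (n >= 3), already residue-aligned.
#' @param L_target normalization length (defaults to n).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(coords_a, coords_b, L_target = nrow(coords_a)) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  if (n < 3 || nrow(coords_b) != n)
    stop("need >= 3 aligned coordinate pairs of equal length")
  d0 <- tm_d0(L_target)
  score_of <- function(sub) {
    if (length(sub) < 3) return(NULL)
    fit <- kabsch_superpose(coords_a[sub, , drop = FALSE],
                            coords_b[sub, , drop = FALSE])
    a2 <- apply_transform(coords_a, fit)
    d <- sqrt(rowSums((a2 - coords_b)^2))
    list(tm = sum(1 / (1 + (d / d0)^2)) / L_target, d = d)
  }
  seeds <- list(seq_len(n))
  if (n >= 6) {
    half <- max(3, n %/% 2); quarter <- max(3, n %/% 4)
    seeds <- c(seeds, list(1:half, (n - half + 1):n,
                           (max(1, (n - quarter) %/% 2 + 1)):
                             (max(1, (n - quarter) %/% 2) + quarter)))
  }
  best <- 0
  for (s in seeds) {
    res <- score_of(s)
    if (is.null(res)) next
    for (iter in 1:20) {
      cut <- max(d0, 3.0)
      sub <- which(res$d < cut)
      while (length(sub) < 3) { cut <- cut + 0.5; sub <- which(res$d < cut) }
      new <- score_of(sub)
      if (is.null(new) || new$tm <= res$tm + 1e-12) break
      res <- new
    }
    best <- max(best, res$tm)
  }
  best
}

# One Needleman-Wunsch pass on a score matrix (free end gaps).
nw_align <- function(S, gap) .nw_align_c(S, gap)

#' Simplified TM-align structural alignment of two models
#'
#' Initial alignments come from gapless threading at a set of sequence
#' offsets and from a Needleman-Wunsch alignment of the two ABEGO strings;
#' each is refined by iterating Kabsch superposition of the currently aligned
#' CA pairs with dynamic-programming re-alignment on the inter-CA distance
#' score matrix (gap penalty `gap`), until stable or `max_iter` iterations.
#' The best-scoring alignment is kept and scored with both chain-length
#' normalizations.
#'
#' @param model_a,model_b `structure_model`s with at least 10 CA atoms.
#' @param gap DP gap penalty (default 0.6).
#' @param max_iter refinement cap per initialization (default 20).
#' @param offset_stride stride of threading offsets (default 4).
#' @return list of class `tm_result`: `id_a`, `id_b`, `tm_by_a`, `tm_by_b`,
#'   `aligned_length`, `rmsd_aligned`, `alignment` (2-column index matrix).
#' @export
tm_align_lite <- function(model_a, model_b, gap = 0.6, max_iter = 20,
                          offset_stride = 4) {
  A <- ca_xyz(model_a); B <- ca_xyz(model_b)
  na <- nrow(A); nb <- nrow(B)
  if (na < 10 || nb < 10) stop("models too short: need >= 10 CA atoms each")
  d0 <- tm_d0(min(na, nb))
  score_matrix <- function(Atr) {
    d2 <- outer(rowSums(Atr^2), rep(1, nb)) +
      outer(rep(1, na), rowSums(B^2)) - 2 * Atr %*% t(B)
    1 / (1 + pmax(d2, 0) / d0^2)
  }
  eval_aln <- function(aln) {
    # score an alignment with the superposition refined on the close-pair
    # subset (d < max(d0, 3)), so outlier segments do not drag the fit
    if (nrow(aln) < 3) return(NULL)
    pa <- A[aln[, 1], , drop = FALSE]
    pb <- B[aln[, 2], , drop = FALSE]
    sub <- seq_len(nrow(aln))
    best <- NULL
    for (it in 1:20) {
      fit <- kabsch_superpose(pa[sub, , drop = FALSE],
                              pb[sub, , drop = FALSE])
      Atr <- apply_transform(A, fit)
      d <- sqrt(rowSums((Atr[aln[, 1], , drop = FALSE] - pb)^2))
      tm <- sum(1 / (1 + (d / d0)^2)) / min(na, nb)
      if (!is.null(best) && tm <= best$tm + 1e-12) break
      best <- list(fit = fit, Atr = Atr, tm = tm, d = d)
      cut <- max(d0, 3.0)
      nsub <- which(d < cut)
      while (length(nsub) < 3) { cut <- cut + 0.5; nsub <- which(d < cut) }
      sub <- nsub
    }
    best
  }
  inits <- list()
  for (off in seq(-(nb - 10), na - 10, by = offset_stride)) {
    i <- max(1, 1 + off):min(na, nb + off)
    j <- i - off
    ok <- j >= 1 & j <= nb
    if (sum(ok) >= 10) inits[[length(inits) + 1]] <- cbind(i[ok], j[ok])
  }
  ab_a <- strsplit(abego_string(model_a)$states, "")[[1]]
  ab_b <- strsplit(abego_string(model_b)$states, "")[[1]]
  # residue tables may include CA-less residues; align states to CA count
  if (length(ab_a) == na && length(ab_b) == nb) {
    S_ab <- outer(ab_a, ab_b, function(x, y) ifelse(x == y, 2, -1))
    inits[[length(inits) + 1]] <- nw_align(S_ab, 1)
  }
  best <- NULL; best_aln <- NULL
  take <- function(res, aln) {
    if (is.null(best) || res$tm > best$tm) {
      best <<- res; best_aln <<- aln
    }
  }
  for (aln in inits) {
    res <- eval_aln(aln)
    if (is.null(res)) next
    take(res, aln)
    for (iter in seq_len(max_iter)) {
      new_aln <- nw_align(score_matrix(res$Atr), gap)
      if (nrow(new_aln) < 3) break
      if (nrow(new_aln) == nrow(aln) && all(new_aln == aln)) break
      new_res <- eval_aln(new_aln)
      if (is.null(new_res)) break
      aln <- new_aln; res <- new_res
      take(res, aln)
    }
  }
  if (is.null(best)) stop("no alignment with >= 3 pairs found")
  pa <- A[best_aln[, 1], , drop = FALSE]
  pb <- B[best_aln[, 2], , drop = FALSE]
  structure(list(
    id_a = model_a$id, id_b = model_b$id,
    tm_by_a = tm_score(pa, pb, L_target = na),
    tm_by_b = tm_score(pa, pb, L_target = nb),
    aligned_length = nrow(best_aln),
    rmsd_aligned = kabsch_superpose(pa, pb)$rmsd,
    alignment = best_aln), class = "tm_result")
}

#' All-vs-all TM-based structural distance matrix
#'
#' Distance = 1 - mean of the two per-chain TM normalizations.
#'
#' @param models list of `structure_model`s (n >= 2).
#' @param ... forwarded to [tm_align_lite()].
#' @return a `distance_matrix`; attribute `tm_results` holds the pairwise
#'   `tm_result` objects.
#' @export
all_vs_all <- function(models, ...) {
  n <- length(models)
  if (n < 2) stop("need at least 2 models")
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate model ids")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  results <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tr <- tm_align_lite(models[[i]], models[[j]], ...)
    d <- 1 - (tr$tm_by_a + tr$tm_by_b) / 2
    D[i, j] <- D[j, i] <- max(0, d)
    results[[paste(ids[i], ids[j], sep = "|")]] <- tr
  }
  out <- as_distance_matrix(D, ids)
  attr(out, "tm_results") <- results
  out
}

# k-nearest-neighbour similarity graph from a distance matrix; edge weight
# is 1 - d/max(d) so the full metric range maps onto [0, 1].
knn_graph <- function(D, k) {
  n <- nrow(D)
  k <- min(k, n - 1)
  mx <- max(D)
  if (mx <= 0) mx <- 1
  edges <- integer(0); wts <- numeric(0)
  for (i in seq_len(n)) {
    nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
    wts <- c(wts, 1 - D[i, nb] / mx)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(g)$weight <- wts
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Embed and cluster a structure or feature space
#'
#' Leiden community detection runs on a k-nearest-neighbour graph built from
#' the input metric (not on embedded coordinates); the 2-D embedding (t-SNE
#' for a distance matrix, UMAP for a feature table) is for visualization.
#' Cluster medoids minimize the summed within-cluster distance.
#'
#' @param x a `distance_matrix` (`method = "tsne_on_distances"`) or a
#'   feature data.frame with `model_id` (`method = "umap_on_features"`,
#'   features are z-scaled and compared by Euclidean distance).
#' @param method embedding/metric mode.
#' @param k_neighbors kNN graph degree (default 15).
#' @param resolution Leiden resolution (default 1.2).
#' @param perplexity t-SNE perplexity (default 30, reduced for small n).
#' @param n_neighbors,min_dist UMAP parameters (defaults 30 and 0.05).
#' @param seed integer seed controlling embedding and Leiden refinement.
#' @return list of class `cluster_assignment`: `labels`, `cluster_ids`,
#'   `medoid_per_cluster`, `embedding` (n x 2), `n_clusters`.
#' @export
embed_and_cluster <- function(x, method = c("tsne_on_distances",
                                            "umap_on_features"),
                              k_neighbors = 15, resolution = 1.2,
                              perplexity = 30, n_neighbors = 30,
                              min_dist = 0.05, seed = 0) {
  method <- match.arg(method)
  if (method == "tsne_on_distances") {
    D <- as.matrix(x)
    labels <- rownames(D)
    n <- nrow(D)
    if (n < 10) stop("n < 10: too few items to embed; inspect directly")
    perp <- min(perplexity, floor((n - 1) / 3))
    emb <- with_seed(seed, Rtsne::Rtsne(stats::as.dist(D),
                                        perplexity = perp, theta = 0,
                                        is_distance = TRUE))$Y
  } else {
    labels <- x$model_id
    feats <- as.matrix(x[, setdiff(names(x), "model_id"), drop = FALSE])
    keep <- apply(feats, 2, function(v) stats::sd(v) > 0)
    feats <- scale(feats[, keep, drop = FALSE])
    n <- nrow(feats)
    if (n < 10) stop("n < 10: too few items to embed; inspect directly")
    D <- as.matrix(stats::dist(feats))
    emb <- with_seed(seed, uwot::umap(feats,
                                      n_neighbors = min(n_neighbors, n - 1),
                                      min_dist = min_dist,
                                      n_sgd_threads = 1, n_threads = 1))
  }
  g <- knn_graph(D, k_neighbors)
  cl <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 10))
  memb <- igraph::membership(cl)
  medoids <- vapply(sort(unique(memb)), function(k) {
    members <- which(memb == k)
    sums <- rowSums(D[members, members, drop = FALSE])
    labels[members[which.min(sums)]]
  }, character(1))
  structure(list(labels = labels, cluster_ids = as.integer(memb),
                 medoid_per_cluster = medoids,
                 embedding = emb, n_clusters = length(medoids)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d items in %d clusters; medoids: %s\n",
              length(x$labels), x$n_clusters,
              paste(x$medoid_per_cluster, collapse = ", ")))
  invisible(x)
}
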