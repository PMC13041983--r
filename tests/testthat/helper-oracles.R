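# Independent oracles and shared fixtures. Oracles deliberately avoid the
# package's own code paths.

# Classic DP edit distance (unit costs), independent of utils::adist.
edit_distance_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0L, n + 1, m + 1)
  M[, 1] <- 0:n; M[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- min(M[i, j] + (A[i] != B[j]),
                           M[i, j + 1] + 1L, M[i + 1, j] + 1L)
  }
  M[n + 1, m + 1]
}

# Horn's quaternion method for optimal rigid superposition RMSD; an
# SVD-free oracle for kabsch_superpose.
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  S <- crossprod(Ac, Bc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lmax) / nrow(A)
  sqrt(max(0, msd))
}

# TM-score formula evaluated directly for a fixed residue pairing, searching
# superpositions by brute force over every contiguous seed window (>= 3) with
# quaternion-based fits refined once on the close subset.
tm_oracle <- function(A, B, L_target = nrow(A)) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  d0 <- if (L_target <= 21) 0.5 else
    max(0.5, 1.24 * (L_target - 15)^(1 / 3) - 1.8)
  fit_on <- function(idx) {
    a <- A[idx, , drop = FALSE]; b <- B[idx, , drop = FALSE]
    ac <- colMeans(a); bc <- colMeans(b)
    sv <- svd(crossprod(sweep(a, 2, ac), sweep(b, 2, bc)))
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    At <- sweep(sweep(A, 2, ac) %*% t(R), 2, bc, `+`)
    sqrt(rowSums((At - B)^2))
  }
  best <- 0
  for (w in unique(c(3, 5, n %/% 2, n))) {
    if (w < 3 || w > n) next
    for (s in seq_len(n - w + 1)) {
      d <- fit_on(s:(s + w - 1))
      best <- max(best, sum(1 / (1 + (d / d0)^2)) / L_target)
      close <- which(d < max(d0, 3))
      if (length(close) >= 3) {
        d2 <- fit_on(close)
        best <- max(best, sum(1 / (1 + (d2 / d0)^2)) / L_target)
      }
    }
  }
  best
}

# Small predicted-model cohort used by several tests.
make_cohort <- function(n_tandem, n_swapped, helix_length = 10,
                        loop_length = 2, seed0 = 1000) {
  mods <- list()
  for (i in seq_len(n_tandem)) {
    mods[[length(mods) + 1]] <- build_bundle_model(
      bundle_spec(8, helix_length, loop_length, "tandem"),
      seed = seed0 + i, id = sprintf("tan%02d", i))$model
  }
  for (i in seq_len(n_swapped)) {
    mods[[length(mods) + 1]] <- build_bundle_model(
      bundle_spec(8, helix_length, loop_length, "swapped"),
      seed = seed0 + 500 + i, id = sprintf("swp%02d", i))$model
  }
  mods
}

rigid_move <- function(model, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), sin(angle), 0, -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  model$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, `+`)
  model
}
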