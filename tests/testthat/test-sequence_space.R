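test_that("normalized Levenshtein matches an independent DP oracle", {
  expect_equal(normalized_levenshtein("ACDE", "ACDE"), 0)
  expect_equal(normalized_levenshtein("KITTEN", "SITTING"), 3 / 7)
  expect_equal(normalized_levenshtein("", "AAAA"), 1)
  expect_error(normalized_levenshtein("", ""), "undefined")
  set.seed(3)
  aa <- c("A", "C", "D", "E", "F")
  for (i in 1:25) {
    a <- paste(sample(aa, sample(1:12, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:12, 1), TRUE), collapse = "")
    expect_equal(normalized_levenshtein(a, b),
                 edit_distance_dp(a, b) / max(nchar(a), nchar(b)))
  }
})

test_that("raw edit distances satisfy the triangle inequality", {
  set.seed(11)
  aa <- c("A", "C", "D")
  for (i in 1:30) {
    s <- vapply(1:3, function(k)
      paste(sample(aa, sample(2:10, 1), TRUE), collapse = ""),
      character(1))
    d_ab <- edit_distance_dp(s[1], s[2])
    d_bc <- edit_distance_dp(s[2], s[3])
    d_ac <- edit_distance_dp(s[1], s[3])
    expect_lte(d_ac, d_ab + d_bc)
  }
})

test_that("distance matrix is symmetric and serves ABEGO strings too", {
  recs <- data.frame(id = c("x", "y", "z"),
                     sequence = c(strrep("A", 10), strrep("A", 10),
                                  strrep("C", 10)))
  dup <- recs; dup$id <- c("x", "x", "z")
  expect_error(distance_matrix(dup), "duplicate")
  D <- distance_matrix(recs)
  expect_equal(sort(unique(as.numeric(D))), c(0, 1))
  expect_equal(D["x", "y"], 0)
  expect_equal(D["x", "z"], 1)
  expect_identical(D, t(D), ignore_attr = TRUE)
  same <- distance_matrix(data.frame(id = letters[1:3],
                                     sequence = rep("MKV", 3)))
  expect_true(all(same == 0))
  abs <- lapply(1:3, function(i) {
    m <- build_ideal_helix(8 + i, id = paste0("h", i))
    abego_string(m)
  })
  Dab <- distance_matrix(abs)
  expect_equal(rownames(Dab), c("h1", "h2", "h3"))
  expect_true(all(diag(Dab) == 0))
})

test_that("isolation fraction matches brute-force counting", {
  labs <- c("a", "b", "c")
  M <- matrix(0, 3, 3, dimnames = list(labs, labs))
  M["a", "b"] <- M["b", "a"] <- 0.8
  M["a", "c"] <- M["c", "a"] <- 0.2
  M["b", "c"] <- M["c", "b"] <- 0.5
  dm <- as_distance_matrix(M)
  prof <- isolation_fraction(dm, 0.5)
  expect_equal(prof$frac_ge_T[prof$label == "a"], 0.5)
  expect_true(all(isolation_fraction(dm, 0)$frac_ge_T == 1))
  set.seed(21)
  for (trial in 1:100) {
    n <- 20
    V <- matrix(stats::runif(n * n), n, n)
    V <- (V + t(V)) / 2; diag(V) <- 0
    dm2 <- as_distance_matrix(V, sprintf("s%02d", 1:n))
    T <- stats::runif(1)
    prof2 <- isolation_fraction(dm2, T)
    brute <- sapply(1:n, function(i) sum(V[i, -i] >= T) / (n - 1))
    expect_equal(prof2$frac_ge_T, brute)
  }
})

test_that("isolation fraction is monotone non-increasing in T", {
  fam <- simulate_sequences(15, 60, 0.4, 1, seed = 2)
  dm <- distance_matrix(fam)
  Ts <- seq(0, 1, by = 0.1)
  profs <- sapply(Ts, function(T) isolation_fraction(dm, T)$frac_ge_T)
  for (i in seq_len(nrow(profs)))
    expect_true(all(diff(profs[i, ]) <= 1e-12))
})

test_that("greedy deduplication mirrors the >99% identity rule", {
  recs <- data.frame(id = c("a", "b"), sequence = rep(strrep("MKVL", 25),
                                                      2))
  dd <- deduplicate(recs)
  expect_equal(dd$kept$id, "a")
  expect_equal(dd$removed$id, "b")
  # 2 substitutions in 100 residues: 98% identity, both kept
  s <- strrep("MKVL", 25)
  s2 <- paste0("AA", substr(s, 3, 100))
  dd2 <- deduplicate(data.frame(id = c("a", "b"), sequence = c(s, s2)))
  expect_equal(nrow(dd2$kept), 2)
  # 1 substitution in 100: 99% identity, not > 99%, both kept
  s3 <- paste0("A", substr(s, 2, 100))
  dd3 <- deduplicate(data.frame(id = c("a", "b"), sequence = c(s, s3)))
  expect_equal(nrow(dd3$kept), 2)
  div <- simulate_sequences(12, 80, 0.3, 0, seed = 4)
  dd4 <- deduplicate(div)
  expect_equal(nrow(dd4$removed), 0)
})

test_that("hierarchical clustering merges tight pairs first", {
  labs <- c("a1", "a2", "b1", "b2")
  M <- matrix(0.9, 4, 4, dimnames = list(labs, labs))
  M[1, 2] <- M[2, 1] <- 0.05
  M[3, 4] <- M[4, 3] <- 0.10
  diag(M) <- 0
  hc <- hierarchical_cluster(as_distance_matrix(M))
  expect_equal(hc$height[1:2], c(0.05, 0.10))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_equal(sort(hc$merge[2, ]), c(-4, -3))
  flat <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(flat) <- 0
  hc2 <- hierarchical_cluster(as_distance_matrix(flat))
  expect_true(all(hc2$height == 0.5))
  pair <- matrix(c(0, 0.3, 0.3, 0), 2,
                 dimnames = list(c("p", "q"), c("p", "q")))
  hc3 <- hierarchical_cluster(as_distance_matrix(pair))
  expect_equal(hc3$height, 0.3)
})

test_that("column entropies match closed forms", {
  aln <- new_alignment(data.frame(
    id = paste0("r", 1:4),
    sequence = c("AAKA", "AAKC", "ACKA", "ACKC")))
  prof <- shannon_entropy(aln)
  expect_equal(prof$entropy, c(0, 1, 0, 1))
  perm <- new_alignment(data.frame(
    id = paste0("r", 1:20),
    sequence = names(bicyclefold:::AA123)))
  expect_equal(shannon_entropy(perm)$entropy, log2(20))
  # gaps excluded from counts; heavy-gap columns flagged
  g <- new_alignment(data.frame(id = c("r1", "r2", "r3", "r4"),
                                sequence = c("A-", "A-", "A-", "AK")))
  pg <- shannon_entropy(g)
  expect_equal(pg$entropy, c(0, 0))
  expect_equal(pg$low_coverage, c(FALSE, TRUE))
})

test_that("entropy is invariant to row order and alphabet relabeling", {
  aln <- simulate_alignment(12, 8, conserved_cols = 2, seed = 3)
  e0 <- shannon_entropy(aln)$entropy
  shuf <- aln
  shuf$records <- shuf$records[sample(nrow(shuf$records)), ]
  expect_equal(shannon_entropy(shuf)$entropy, e0)
  aa <- names(bicyclefold:::AA123)
  relab <- aln
  relab$records$sequence <- chartr(paste(aa, collapse = ""),
                                   paste(rev(aa), collapse = ""),
                                   relab$records$sequence)
  expect_equal(shannon_entropy(relab)$entropy, e0)
})

test_that("entropy maps onto a structure and round-trips via B-factors", {
  res <- build_bundle_model(bundle_spec(4, 16, 4, "single"), seed = 6,
                            id = "ref")
  m <- res$model
  n <- n_residues(m)
  aln <- new_alignment(data.frame(
    id = c("ref", "other"),
    sequence = c(paste0(model_sequence(m), "--"),
                 paste0(strrep("A", n), "KK"))))
  prof <- shannon_entropy(aln)
  mapped <- map_entropy(prof, aln, m, "ref")
  expect_equal(length(mapped$values), n)
  tf <- tempfile(fileext = ".pdb")
  write_structure(mapped$model, tf, per_residue_values = mapped$values)
  back <- read_structure(tf)
  expect_equal(residue_table(back)$confidence, mapped$values,
               tolerance = 1e-2)
  bad <- aln
  bad$records$sequence[1] <- paste0("W", substr(bad$records$sequence[1], 2,
                                                n + 2))
  expect_error(map_entropy(shannon_entropy(bad), bad, m, "ref"),
               "position 1")
})
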