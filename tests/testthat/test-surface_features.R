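single_atom_model <- function(x = 0, y = 0, z = 0, elety = "CA",
                              elesy = "C", resid = "GLY", resno = 1L) {
  data.frame(chain = "A", resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z, o = 1, b = 0,
             stringsAsFactors = FALSE)
}

test_that("SASA of isolated and non-interacting atoms is closed-form", {
  m <- structure_model("one", single_atom_model())
  s <- compute_sasa(m)
  expect_equal(s$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
  two <- structure_model("two", rbind(
    single_atom_model(), single_atom_model(x = 100, resno = 2L)))
  s2 <- compute_sasa(two)
  expect_equal(s2$total, 2 * s$total, tolerance = 1e-9)
})

test_that("a caged atom has near-zero accessible area", {
  # octahedral cage of large S atoms at 3 A around a carbon
  shell <- do.call(rbind, lapply(seq_len(18), function(i) {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1),
                  cbind(c(1, 1, -1, -1, 1, 1, -1, -1, 0, 0, 0, 0) / sqrt(2),
                        c(1, -1, 1, -1, 0, 0, 0, 0, 1, 1, -1, -1) / sqrt(2),
                        c(0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1) / sqrt(2)))
    p <- dirs[i, ] * 3
    single_atom_model(p[1], p[2], p[3], elety = "S", elesy = "S",
                      resno = i + 1L)
  }))
  m <- structure_model("cage", rbind(single_atom_model(), shell))
  s <- compute_sasa(m)
  expect_lt(s$per_atom[1] / (4 * pi * (1.7 + 1.4)^2), 0.01)
})

test_that("SASA converges under point-set doubling", {
  m <- build_bundle_model(bundle_spec(4, 12, 3, "single"), seed = 3)$model
  s1 <- compute_sasa(m, n_points = 960)
  s2 <- compute_sasa(m, n_points = 1920)
  expect_lt(abs(s1$total - s2$total) / s2$total, 0.005)
})

test_that("SASA partitions are consistent and class-correct", {
  h <- build_ideal_helix(15, strrep("L", 15), id = "polyL")
  s <- compute_sasa(h)
  expect_equal(s$total, sum(s$per_atom), tolerance = 1e-6)
  expect_equal(s$total, sum(s$per_residue), tolerance = 1e-6)
  expect_equal(s$hydrophobic, s$total)  # all-Leu: everything hydrophobic
  expect_equal(s$positive, 0)
  k <- build_ideal_helix(15, strrep("K", 15), id = "polyK")
  sk <- compute_sasa(k)
  expect_equal(sk$positive, sk$total)
  expect_equal(sk$hydrophobic, 0)
})

test_that("hydrophobic moment matches hand-computed values", {
  expect_equal(hydrophobic_moment(rep(0, 11)), 0)
  expect_equal(hydrophobic_moment(c(1, 1)), cos(50 * pi / 180),
               tolerance = 1e-12)
  # resonant pattern: scores tracking the helical period maximize mu
  n <- 18
  resonant <- cos((seq_len(n) - 1) * 100 * pi / 180)
  direct <- sqrt(sum(resonant * cos((seq_len(n) - 1) * 100 * pi / 180))^2 +
                   sum(resonant * sin((seq_len(n) - 1) *
                                        100 * pi / 180))^2) / n
  expect_equal(hydrophobic_moment(resonant), direct)
  set.seed(2)
  for (i in 1:20) {
    expect_lte(hydrophobic_moment(sample(resonant)),
               hydrophobic_moment(resonant) + 1e-9)
  }
})

test_that("descriptor suite covers composition identities", {
  k <- build_ideal_helix(20, strrep("K", 20), id = "polyK")
  fv <- surface_descriptors(k)
  expect_equal(fv$net_charge, 20)
  expect_equal(fv$frac_positive, 1)
  expect_equal(fv$frac_negative, 0)
  expect_equal(fv$f_sasa_hydrophobic, 0)
  expect_equal(fv$n_hydrophobic_patches, 0)
  expect_equal(fv$hydrophobic_patchiness, 0)
  expect_equal(fv$helix_fraction, 18 / 20)  # termini lack dihedrals
  expect_equal(ncol(fv) - 1, 23)
  expect_true(all(!is.na(as.numeric(fv[, -1]))))
})

test_that("an idealized amphipathic helix outscores a scrambled one", {
  # Leu on one helical face: position i gets L when the wheel angle is in
  # the hydrophobic half, K otherwise
  ang <- ((seq_len(24) - 1) * 100) %% 360
  seq_amph <- paste(ifelse(ang < 180, "L", "K"), collapse = "")
  amph <- build_ideal_helix(24, seq_amph, id = "amph")
  f_amph <- surface_descriptors(amph)
  expect_gt(f_amph$amphipathic_helical_fraction, 0.8)
  set.seed(9)
  scram <- paste(sample(strsplit(seq_amph, "")[[1]]), collapse = "")
  f_scram <- surface_descriptors(build_ideal_helix(24, scram, id = "scr"))
  expect_gt(f_amph$max_hydrophobic_moment, f_scram$max_hydrophobic_moment)
})

test_that("all descriptors are rigid-motion invariant", {
  m <- build_bundle_model(bundle_spec(4, 16, 4, "single"), seed = 2)$model
  f1 <- surface_descriptors(m)
  f2 <- surface_descriptors(rigid_move(m))
  exact <- c("n_res", "frac_hydrophobic", "frac_positive", "frac_negative",
             "net_charge", "charge_density", "helix_fraction",
             "radius_of_gyration", "amphipathic_helical_fraction",
             "max_hydrophobic_moment", "mean_helix_hydrophobic_moment",
             "dipole_asymmetry")
  for (k in exact)
    expect_equal(f2[[k]], f1[[k]], tolerance = 1e-6, label = k)
  sasa_like <- c("sasa_total", "sasa_hydrophobic", "sasa_positive",
                 "sasa_negative", "f_sasa_hydrophobic", "f_surface_polar",
                 "surface_roughness", "hydrophobic_patchiness",
                 "largest_patch_area")
  for (k in sasa_like)
    expect_lt(abs(f2[[k]] - f1[[k]]) / max(abs(f1[[k]]), 1), 0.01)
  expect_lt(abs(f2$surface_hydropathy - f1$surface_hydropathy), 0.01)
  expect_equal(f1$sasa_total, f2$sasa_total, tolerance = 2e-3)
})

test_that("correlation pruning drops duplicates and size flags", {
  set.seed(10)
  base <- data.frame(model_id = sprintf("m%03d", 1:50),
                     alpha = rnorm(50), beta = rnorm(50))
  base$alpha_copy <- base$alpha
  pr <- prune_correlated(base, exclude_size_dependent = FALSE)
  expect_setequal(names(pr$features), c("model_id", "alpha", "beta"))
  expect_true("alpha_copy" %in% pr$dropped$feature ||
                "alpha" %in% pr$dropped$feature)
  # independent features survive at n = 1000
  set.seed(11)
  ind <- data.frame(model_id = sprintf("m%04d", 1:1000),
                    u = rnorm(1000), v = rnorm(1000))
  pr2 <- prune_correlated(ind, exclude_size_dependent = FALSE)
  expect_setequal(names(pr2$features), c("model_id", "u", "v"))
  # size-dependent bookkeeping on a real feature table
  mods <- lapply(1:3, function(i)
    build_bundle_model(bundle_spec(4, 12, 3, "single"), seed = 30 + i,
                       id = paste0("f", i))$model)
  ft <- feature_table(mods, n_points = 240)
  pr3 <- suppressWarnings(prune_correlated(ft, r_threshold = 1.1))
  flagged <- pr3$dropped$feature[pr3$dropped$reason == "size_dependent"]
  expect_setequal(flagged, bicyclefold:::SIZE_DEPENDENT_FEATURES)
  expect_false(any(flagged %in% names(pr3$features)))
  const <- data.frame(model_id = letters[1:5], a = rnorm(5), b = rep(1, 5))
  expect_warning(pr4 <- prune_correlated(const,
                                         exclude_size_dependent = FALSE),
                 "constant")
  expect_false("b" %in% names(pr4$features))
})
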