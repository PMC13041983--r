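# surface_features: Shrake-Rupley solvent-accessible surface area with a
# deterministic Fibonacci point set, hydrophobic moments, the physicochemical
# descriptor suite, and correlation-based feature pruning.

# residue classes (pH 7; His counted positive)
HYDROPHOBIC_AA <- c("I", "L", "V", "F", "C", "M", "A", "W", "Y", "P")
POSITIVE_AA <- c("K", "R", "H")
NEGATIVE_AA <- c("D", "E")

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Kyte-Doolittle hydropathy
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# Eisenberg consensus hydrophobicity
EISENBERG_SCALE <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                     Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                     L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                     S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# Theoretical maximum SASA per residue (Tien et al. values, A^2), for
# relative solvent accessibility.
MAX_SASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
              G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
              P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from a deterministic Fibonacci sphere lattice of
#' `n_points` test points at radius r_vdw + `probe`; a point is occluded when
#' it falls inside any neighboring atom's probe-inflated sphere. Hydrogens
#' are ignored; radii are C 1.70, N 1.55, O 1.52, S 1.80 (default 1.70).
#' Partitions sum residue-level areas over the hydrophobic
#' (I,L,V,F,C,M,A,W,Y,P), positive (K,R,H) and negative (D,E) classes.
#'
#' @param model a `structure_model`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return list of class `sasa_result`: `per_atom` (named by heavy-atom row),
#'   `per_residue`, `total`, `hydrophobic`, `positive`, `negative`,
#'   `rel_per_residue` (relative accessibility), `atom_index` (row indices of
#'   the heavy atoms in the model's atom table).
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960) {
  atoms <- model$atoms
  heavy <- which(atoms$elesy != "H" & atoms$elesy != "D")
  if (!length(heavy)) stop("no heavy atoms in model '", model$id, "'")
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  r <- unname(VDW_RADII[atoms$elesy[heavy]])
  r[is.na(r)] <- 1.70
  n <- length(heavy)
  sphere <- fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  cut <- outer(r + probe, r + probe, `+`)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < cut[i, ]^2)
    nb <- nb[nb != i]
    Ri <- r[i] + probe
    if (!length(nb)) { per_atom[i] <- 4 * pi * Ri^2; next }
    pts <- sweep(sphere * Ri, 2, xyz[i, ], `+`)
    cn <- xyz[nb, , drop = FALSE]
    rn2 <- (r[nb] + probe)^2
    dd <- outer(rowSums(pts^2), rep(1, length(nb))) +
      outer(rep(1, n_points), rowSums(cn^2)) - 2 * pts %*% t(cn)
    free <- rowSums(sweep(dd, 2, rn2, `<`)) == 0
    per_atom[i] <- 4 * pi * Ri^2 * mean(free)
  }
  rt <- residue_table(model)
  akey <- paste(atoms$chain[heavy], atoms$resno[heavy], atoms$insert[heavy],
                sep = "\r")
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  per_res <- vapply(rkey, function(k) sum(per_atom[akey == k]), numeric(1))
  names(per_res) <- rkey
  aa1 <- rt$aa1
  rel <- per_res / unname(MAX_SASA[aa1])
  structure(list(
    per_atom = per_atom, per_residue = unname(per_res),
    total = sum(per_atom),
    hydrophobic = sum(per_res[aa1 %in% HYDROPHOBIC_AA]),
    positive = sum(per_res[aa1 %in% POSITIVE_AA]),
    negative = sum(per_res[aa1 %in% NEGATIVE_AA]),
    rel_per_residue = unname(rel), atom_index = heavy,
    probe = probe, n_points = n_points), class = "sasa_result")
}

#' Helical-wheel hydrophobic moment
#'
#' mu_H = |sum_n H_n (cos(n delta), sin(n delta))| / N over the window, with
#' n starting at 0 and delta = 100 degrees per residue (alpha-helical
#' periodicity).
#'
#' @param window_scores per-residue hydrophobicity values.
#' @param delta rotation per residue in degrees (default 100).
#' @return nonnegative moment (same units as the scale, per residue).
#' @export
hydrophobic_moment <- function(window_scores, delta = 100) {
  n <- length(window_scores)
  if (n == 0) stop("empty window")
  ang <- (seq_len(n) - 1) * delta * DEG
  sqrt(sum(window_scores * cos(ang))^2 +
         sum(window_scores * sin(ang))^2) / n
}

# Moments of all `width`-residue windows of a helix segment's sequence.
helix_window_moments <- function(aa1, start, end, width = 11, delta = 100) {
  idx <- start:end
  if (length(idx) < width) return(NULL)
  starts <- idx[seq_len(length(idx) - width + 1)]
  data.frame(start = starts, end = starts + width - 1,
             mu = vapply(starts, function(s) {
               sc <- EISENBERG_SCALE[aa1[s:(s + width - 1)]]
               sc[is.na(sc)] <- 0
               hydrophobic_moment(sc, delta)
             }, numeric(1)))
}

#' Physicochemical descriptor suite for one model
#'
#' Computes the full named feature set from the model's composition, SASA
#' partition, helix segments and hydrophobic-moment windows. Degenerate
#' models yield defined zeros (e.g. no helices gives amphipathic fraction 0).
#'
#' Features: `n_res`; `sasa_total`, `sasa_hydrophobic`, `sasa_positive`,
#' `sasa_negative`; `f_sasa_hydrophobic`; `frac_hydrophobic`,
#' `frac_positive`, `frac_negative`; `net_charge` ((K+R+H) - (D+E));
#' `charge_density` (net charge per residue); `surface_hydropathy`
#' (SASA-weighted Kyte-Doolittle mean; see `rsa_cut`); `surface_roughness` (SASA at the standard probe divided by SASA at
#' a 3.0-Angstrom smoothing probe — a texture index, larger for more rugged
#' surfaces); `hydrophobic_patchiness` (largest patch area / hydrophobic
#' SASA); `n_hydrophobic_patches` and `largest_patch_area` (connected
#' components of exposed hydrophobic atoms within 6 Angstrom);
#' `amphipathic_helical_fraction` (helical residues inside 11-residue
#' windows with Eisenberg moment >= 0.25); `max_hydrophobic_moment` and
#' `mean_helix_hydrophobic_moment`; `dipole_asymmetry` (magnitude of the
#' first moment of +-1 charges at CA positions, e*Angstrom);
#' `f_surface_polar`; `helix_fraction`; `radius_of_gyration` (CA-based).
#'
#' @param model a `structure_model`.
#' @param sasa optional precomputed [compute_sasa()] result.
#' @param probe,n_points forwarded to [compute_sasa()] when `sasa` is NULL.
#' @param moment_cut amphipathicity threshold on the per-residue moment
#'   (default 0.25).
#' @param patch_cut atom-pair distance defining patch connectivity
#'   (default 6).
#' @param rsa_cut relative-accessibility floor for the hydropathy average
#'   (default 0: weight every residue by its SASA, which is continuous and
#'   rigid-motion stable; 0.2 restricts to clearly exposed residues).
#' @return one-row data.frame (first column `model_id`).
#' @export
surface_descriptors <- function(model, sasa = NULL, probe = 1.4,
                                n_points = 960, moment_cut = 0.25,
                                patch_cut = 6, rsa_cut = 0) {
  if (is.null(sasa)) sasa <- compute_sasa(model, probe, n_points)
  rt <- residue_table(model)
  aa1 <- rt$aa1
  n <- nrow(rt)
  npos <- sum(aa1 %in% POSITIVE_AA)
  nneg <- sum(aa1 %in% NEGATIVE_AA)
  # surface hydropathy: SASA-weighted KD; weighting by accessible area
  # already suppresses buried residues, and a zero rsa_cut keeps the value
  # continuous (rigid-motion stable). Set rsa_cut = 0.2 to restrict to
  # clearly exposed residues.
  exposed <- which(!is.na(sasa$rel_per_residue) &
                     sasa$rel_per_residue > rsa_cut)
  kd <- KD_SCALE[aa1[exposed]]
  w <- sasa$per_residue[exposed]
  ok <- !is.na(kd) & w > 0
  surf_hyd <- if (any(ok)) sum(kd[ok] * w[ok]) / sum(w[ok]) else 0
  # roughness: probe-ratio texture index
  smooth <- compute_sasa(model, probe = 3.0, n_points = sasa$n_points)
  roughness <- sasa$total / smooth$total
  # hydrophobic patches on the surface
  atoms <- model$atoms
  akey <- paste(atoms$chain[sasa$atom_index], atoms$resno[sasa$atom_index],
                sep = "\r")
  res_aa <- stats::setNames(aa1, paste(rt$chain, rt$resno, sep = "\r"))
  hyd_atom <- which(res_aa[akey] %in% HYDROPHOBIC_AA &
                      sasa$per_atom > 1e-6)
  n_patches <- 0L; largest <- 0
  if (length(hyd_atom)) {
    xyz <- as.matrix(atoms[sasa$atom_index[hyd_atom], c("x", "y", "z")])
    adj <- as.matrix(stats::dist(xyz)) < patch_cut
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    areas <- tapply(sasa$per_atom[hyd_atom], comp, sum)
    n_patches <- length(areas)
    largest <- max(areas)
  }
  patchiness <- if (sasa$hydrophobic > 0) largest / sasa$hydrophobic else 0
  # helices and amphipathicity
  hel <- find_helices(abego_string(model), model)
  helical <- logical(n)
  mus <- numeric(0)
  amph <- logical(n)
  if (nrow(hel)) {
    for (k in seq_len(nrow(hel))) {
      helical[hel$start[k]:hel$end[k]] <- TRUE
      wm <- helix_window_moments(aa1, hel$start[k], hel$end[k])
      if (is.null(wm)) next
      mus <- c(mus, wm$mu)
      for (r in which(wm$mu >= moment_cut))
        amph[wm$start[r]:wm$end[r]] <- TRUE
    }
  }
  amph_frac <- if (any(helical)) sum(amph & helical) / sum(helical) else 0
  # charge first moment and radius of gyration at CA positions
  cas <- ca_xyz(model)
  ctr <- colMeans(cas)
  q <- ifelse(aa1 %in% POSITIVE_AA, 1, ifelse(aa1 %in% NEGATIVE_AA, -1, 0))
  q <- q[seq_len(nrow(cas))]
  dipole <- vnorm(colSums(sweep(cas, 2, ctr) * q))
  rg <- sqrt(mean(rowSums(sweep(cas, 2, ctr)^2)))
  data.frame(
    model_id = model$id, n_res = n,
    sasa_total = sasa$total, sasa_hydrophobic = sasa$hydrophobic,
    sasa_positive = sasa$positive, sasa_negative = sasa$negative,
    f_sasa_hydrophobic = if (sasa$total > 0)
      sasa$hydrophobic / sasa$total else 0,
    frac_hydrophobic = sum(aa1 %in% HYDROPHOBIC_AA) / n,
    frac_positive = npos / n, frac_negative = nneg / n,
    net_charge = npos - nneg, charge_density = (npos - nneg) / n,
    surface_hydropathy = surf_hyd, surface_roughness = roughness,
    hydrophobic_patchiness = patchiness,
    n_hydrophobic_patches = n_patches, largest_patch_area = largest,
    amphipathic_helical_fraction = amph_frac,
    max_hydrophobic_moment = if (length(mus)) max(mus) else 0,
    mean_helix_hydrophobic_moment = if (length(mus)) mean(mus) else 0,
    dipole_asymmetry = dipole,
    f_surface_polar = if (sasa$total > 0)
      (sasa$total - sasa$hydrophobic) / sasa$total else 0,
    helix_fraction = sum(helical) / n, radius_of_gyration = rg,
    stringsAsFactors = FALSE)
}

#' Feature table for a set of models
#' @param models list of `structure_model` objects.
#' @param ... forwarded to [surface_descriptors()].
#' @return data.frame, one row per model.
#' @export
feature_table <- function(models, ...) {
  do.call(rbind, lapply(models, surface_descriptors, ...))
}

# Features that scale with protein size (dropped before embedding).
SIZE_DEPENDENT_FEATURES <- c(
  "n_res", "sasa_total", "sasa_hydrophobic", "sasa_positive",
  "sasa_negative", "net_charge", "n_hydrophobic_patches",
  "largest_patch_area", "dipole_asymmetry", "radius_of_gyration")

#' Correlation-based feature pruning
#'
#' Optionally drops the size-dependent features first, then greedily resolves
#' correlated pairs: while any |Pearson r| exceeds the threshold, take the
#' most correlated pair and drop the member with the larger mean absolute
#' correlation to all remaining features (ties broken by feature-name order).
#' Constant features are dropped with a warning (undefined correlation).
#'
#' @param features data.frame from [feature_table()] (`model_id` column plus
#'   numeric features).
#' @param r_threshold absolute Pearson correlation threshold (default 0.85).
#' @param exclude_size_dependent drop `SIZE_DEPENDENT_FEATURES` first
#'   (default TRUE).
#' @return list with `features` (reduced data.frame, `model_id` retained) and
#'   `dropped` (data.frame `feature`, `reason`).
#' @export
prune_correlated <- function(features, r_threshold = 0.85,
                             exclude_size_dependent = TRUE) {
  if (nrow(features) < 3) stop("need at least 3 rows to estimate correlation")
  id <- features$model_id
  x <- features[, setdiff(names(features), "model_id"), drop = FALSE]
  dropped <- data.frame(feature = character(), reason = character(),
                        stringsAsFactors = FALSE)
  note <- function(f, why) dropped <<- rbind(
    dropped, data.frame(feature = f, reason = why, stringsAsFactors = FALSE))
  if (exclude_size_dependent) {
    for (f in intersect(SIZE_DEPENDENT_FEATURES, names(x)))
      note(f, "size_dependent")
    x <- x[, setdiff(names(x), SIZE_DEPENDENT_FEATURES), drop = FALSE]
  }
  const <- names(x)[vapply(x, function(v) stats::sd(v) == 0 || !all(
    is.finite(v)), logical(1))]
  if (length(const)) {
    warning("constant/degenerate feature(s) dropped: ",
            paste(const, collapse = ", "))
    for (f in const) note(f, "constant")
    x <- x[, setdiff(names(x), const), drop = FALSE]
  }
  repeat {
    if (ncol(x) < 2) break
    cm <- abs(stats::cor(x))
    diag(cm) <- 0
    if (max(cm) <= r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)
    pair <- sort(colnames(cm)[idx[1, ]])
    mean_abs <- colMeans(abs(stats::cor(x)))
    # drop the member with larger mean |r|; ties keep the earlier column
    cand <- pair[order(-mean_abs[pair], -match(pair, names(x)))]
    note(cand[1], sprintf("correlated_with_%s_r_%.3f", cand[2], max(cm)))
    x <- x[, setdiff(names(x), cand[1]), drop = FALSE]
  }
  list(features = cbind(data.frame(model_id = id,
                                   stringsAsFactors = FALSE), x),
       dropped = dropped)
}
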