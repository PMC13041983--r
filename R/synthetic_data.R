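# synthetic_data: seeded generators for structures, sequences, alignments and
# confidence profiles. Everything is deterministic given the seed; geometry is
# built analytically (NeRF internal-to-Cartesian), no minimization.

# Ideal backbone internal coordinates (Angstrom / degrees).
BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ca_cb = 1.521, cb_sg = 1.808, ss = 2.05,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4, ang_ca_cb_sg = 114.2,
  ang_cb_s_s = 104.2, cb_improper = 122.6)

# Run code under a temporary RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)

# Build backbone atoms for one chain segment from per-residue torsion targets.
# phi[1] and omega[1] are unused; psi[n] is used only to place the final O.
# Returns an atoms data.frame (N, CA, C, O per residue; CB for non-Gly; SG
# for Cys at torsion `chi1`).
build_backbone <- function(sequence, phi, psi, omega, chain = "A",
                           start_resno = 1L, chi1 = -60) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  stopifnot(length(phi) == n, length(psi) == n, length(omega) == n, n >= 1)
  Nx <- CAx <- Cx <- vector("list", n)
  Nx[[1]] <- c(0, 0, 0)
  CAx[[1]] <- c(BB$n_ca, 0, 0)
  th <- BB$ang_n_ca_c * DEG
  Cx[[1]] <- CAx[[1]] + BB$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    Nx[[i]] <- place_atom(Nx[[i - 1]], CAx[[i - 1]], Cx[[i - 1]],
                          BB$c_n, BB$ang_ca_c_n, psi[i - 1])
    CAx[[i]] <- place_atom(CAx[[i - 1]], Cx[[i - 1]], Nx[[i]],
                           BB$n_ca, BB$ang_c_n_ca, omega[i])
    Cx[[i]] <- place_atom(Cx[[i - 1]], Nx[[i]], CAx[[i]],
                          BB$ca_c, BB$ang_n_ca_c, phi[i])
  }
  rows <- list()
  aa1_to_3 <- function(a) if (a %in% names(AA123)) AA123[[a]] else "UNK"
  for (i in seq_len(n)) {
    res3 <- aa1_to_3(aa[i])
    resno <- start_resno + i - 1L
    add <- function(elety, elesy, p)
      data.frame(chain = chain, resno = resno, insert = "", resid = res3,
                 elety = elety, elesy = elesy, x = p[1], y = p[2], z = p[3],
                 o = 1, b = 0, stringsAsFactors = FALSE)
    O <- place_atom(Nx[[i]], CAx[[i]], Cx[[i]], BB$c_o, BB$ang_ca_c_o,
                    psi[i] + 180)
    res_rows <- list(add("N", "N", Nx[[i]]), add("CA", "C", CAx[[i]]),
                     add("C", "C", Cx[[i]]), add("O", "O", O))
    if (aa[i] != "G") {
      CB <- place_atom(Cx[[i]], Nx[[i]], CAx[[i]], BB$ca_cb,
                       BB$ang_n_ca_cb, BB$cb_improper)
      res_rows <- c(res_rows, list(add("CB", "C", CB)))
      if (aa[i] == "C") {
        SG <- place_atom(Nx[[i]], CAx[[i]], CB, BB$cb_sg,
                         BB$ang_ca_cb_sg, chi1)
        res_rows <- c(res_rows, list(add("SG", "S", SG)))
      }
    }
    rows[[i]] <- do.call(rbind, res_rows)
  }
  do.call(rbind, rows)
}

#' Build an ideal alpha helix
#'
#' Backbone placed analytically with phi = -57, psi = -47, omega = 180 and
#' standard bond lengths/angles; CB on non-glycine, SG on cysteine.
#'
#' @param n_res number of residues (>= 2).
#' @param sequence optional 1-letter sequence of length `n_res`
#'   (default poly-alanine).
#' @param id model label.
#' @return a `structure_model`.
#' @export
build_ideal_helix <- function(n_res, sequence = NULL, id = "ideal_helix") {
  if (n_res < 2) stop("n_res must be >= 2")
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  if (nchar(sequence) != n_res)
    stop("sequence length (", nchar(sequence), ") != n_res (", n_res, ")")
  atoms <- build_backbone(sequence, rep(-57, n_res), rep(-47, n_res),
                          rep(180, n_res))
  structure_model(id, atoms)
}

#' Specification of a synthetic helix-bundle model
#'
#' @param n_helices number of helices (>= 1; tandem/swapped need 8).
#' @param helix_length residues per helix (>= 6).
#' @param loop_length residues between consecutive helices.
#' @param topology `"single"`, `"tandem"` or `"swapped"`.
#' @param bundle_assignment optional integer vector mapping helix index to
#'   bundle index, overriding the topology default.
#' @return list of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices, helix_length, loop_length = 4,
                        topology = c("single", "tandem", "swapped"),
                        bundle_assignment = NULL) {
  topology <- match.arg(topology)
  if (helix_length < 6) stop("helix_length must be >= 6")
  if (n_helices < 1) stop("n_helices must be >= 1")
  if (topology %in% c("tandem", "swapped") && n_helices < 8)
    stop("tandem/swapped topologies require n_helices >= 8 ",
         "(two four-helix bundles)")
  if (is.null(bundle_assignment)) {
    bundle_assignment <- switch(topology,
      single = rep(1L, n_helices),
      tandem = rep(c(1L, 2L), each = 4L)[seq_len(n_helices)],
      swapped = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L)[seq_len(n_helices)])
  }
  if (length(bundle_assignment) != n_helices)
    stop("bundle_assignment must have one entry per helix")
  structure(list(n_helices = as.integer(n_helices),
                 helix_length = as.integer(helix_length),
                 loop_length = as.integer(loop_length),
                 topology = topology,
                 bundle_assignment = as.integer(bundle_assignment)),
            class = "bundle_spec")
}

#' Specification of one planted disulfide bridge
#'
#' @param residue_a,residue_b residue numbers of the two cysteines (chain A).
#' @param chi the five target dihedrals (chi1, chi2, chi3, chi2', chi1') in
#'   degrees.
#' @return list of class `disulfide_spec`.
#' @export
disulfide_spec <- function(residue_a, residue_b,
                           chi = c(-60, -60, -90, -60, -60)) {
  if (length(chi) != 5) stop("chi must have exactly 5 angles")
  structure(list(residue_a = as.integer(residue_a),
                 residue_b = as.integer(residue_b), chi = as.numeric(chi)),
            class = "disulfide_spec")
}

# Rigid-place the atoms of one helix so its axis lies along `direction` with
# CA centroid at `site`.
place_helix_at <- function(atoms, site, direction) {
  cas <- as.matrix(atoms[atoms$elety == "CA", c("x", "y", "z")])
  ctr <- colMeans(cas)
  ax <- svd(sweep(cas, 2, ctr))$v[, 1]
  # orient along requested direction
  if (sum(ax * direction) < 0) ax <- -ax
  v <- vcross(ax, direction)
  s <- vnorm(v); cth <- sum(ax * direction)
  if (s < 1e-9) {
    R <- diag(3) * sign(cth)
    if (cth > 0) R <- diag(3)
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
    R <- t(R)  # row-vector convention
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, ctr)
  xyz <- sweep(xyz %*% R, 2, site, `+`)
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

#' Build a synthetic helix-bundle model
#'
#' Helices are packed on a per-bundle 2x2 square lattice (8 Angstrom spacing,
#' antiparallel alternation, bundles 36 Angstrom apart) so that helices
#' sharing a bundle have pairwise midpoint distances < 12 Angstrom and
#' inter-bundle distances > 20 Angstrom. Sequence-order-to-bundle mapping
#' follows the topology (tandem: helices 1-4 / 5-8; swapped: 1,2,3,8 /
#' 4,5,6,7). Requested disulfides are built analytically from the first
#' residue's backbone frame through the five chi targets, and the partner
#' helix is rigid-body placed onto the bridge-derived frame, giving an S-S
#' distance of 2.05 Angstrom and chi dihedrals within numerical precision of
#' the targets. A helix can be re-targeted by at most one bridge; bridge-moved
#' helices are exempt from the lattice separation contract (their position is
#' owned by the bridge), which is re-measured for all remaining helices.
#'
#' @param spec a [bundle_spec()].
#' @param disulfides list of [disulfide_spec()] objects.
#' @param seed integer seed (mandatory; same seed, same output).
#' @param extra_cysteines residue numbers to set to free (unbridged) Cys.
#' @param id model label.
#' @return list with `model` (a `structure_model`) and `sequence` (data.frame
#'   record with `id`, `sequence`).
#' @export
build_bundle_model <- function(spec, disulfides = list(), seed,
                               extra_cysteines = integer(), id = "bundle") {
  stopifnot(inherits(spec, "bundle_spec"))
  nh <- spec$n_helices; L <- spec$helix_length; loop <- spec$loop_length
  n_res <- nh * L + (nh - 1) * loop
  helix_start <- (seq_len(nh) - 1L) * (L + loop) + 1L
  helix_range <- lapply(seq_len(nh), function(i)
    helix_start[i]:(helix_start[i] + L - 1L))
  seq_chars <- with_seed(seed, sample(setdiff(names(AA123), c("C", "G")),
                                      n_res, replace = TRUE))
  for (ds in disulfides) {
    for (r in c(ds$residue_a, ds$residue_b)) {
      if (r < 1 || r > n_res) stop("disulfide residue ", r, " out of range")
      seq_chars[r] <- "C"
    }
  }
  if (length(extra_cysteines) &&
      (min(extra_cysteines) < 1 || max(extra_cysteines) > n_res))
    stop("extra_cysteines out of range 1..", n_res)
  seq_chars[extra_cysteines] <- "C"
  # lattice sites: 2x2 per bundle, 8 A spacing, bundles offset along x
  lattice <- list(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  bnd <- spec$bundle_assignment
  sites <- matrix(NA_real_, nh, 3)
  dirs <- matrix(NA_real_, nh, 3)
  for (b in unique(bnd)) {
    members <- which(bnd == b)
    if (length(members) > 4)
      stop("bundle ", b, " has more than 4 helices; no lattice site free")
    for (k in seq_along(members)) {
      i <- members[k]
      sites[i, ] <- c((b - 1) * 36 + lattice[[k]][1], lattice[[k]][2], 0)
      dirs[i, ] <- c(0, 0, if (k %% 2 == 1) 1 else -1)
    }
  }
  helices <- lapply(seq_len(nh), function(i) {
    sq <- paste(seq_chars[helix_range[[i]]], collapse = "")
    at <- build_backbone(sq, rep(-57, L), rep(-47, L), rep(180, L),
                         start_resno = helix_start[i])
    place_helix_at(at, sites[i, ], dirs[i, ])
  })
  # plant disulfide bridges
  moved <- rep(FALSE, nh)
  helix_of <- function(r) {
    h <- which(vapply(helix_range, function(rg) r %in% rg, logical(1)))
    if (!length(h)) stop("disulfide residue ", r, " falls in a loop, ",
                         "not a helix")
    h
  }
  get_at <- function(h, resno, elety) {
    at <- helices[[h]]
    i <- which(at$resno == resno & at$elety == elety)
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  set_at <- function(h, resno, elety, p) {
    at <- helices[[h]]
    i <- which(at$resno == resno & at$elety == elety)
    at[i[1], c("x", "y", "z")] <- p
    helices[[h]] <<- at
  }
  for (ds in disulfides) {
    ha <- helix_of(ds$residue_a); hb <- helix_of(ds$residue_b)
    if (ha == hb) stop("disulfide within a single helix is not supported")
    if (moved[hb]) stop("helix ", hb, " already re-targeted by another ",
                        "bridge; disulfide set infeasible")
    chi <- ds$chi
    Na <- get_at(ha, ds$residue_a, "N")
    CAa <- get_at(ha, ds$residue_a, "CA")
    CBa <- get_at(ha, ds$residue_a, "CB")
    SGa <- place_atom(Na, CAa, CBa, BB$cb_sg, BB$ang_ca_cb_sg, chi[1])
    SGb <- place_atom(CAa, CBa, SGa, BB$ss, BB$ang_cb_s_s, chi[2])
    CBb <- place_atom(CBa, SGa, SGb, BB$cb_sg, BB$ang_cb_s_s, chi[3])
    CAb <- place_atom(SGa, SGb, CBb, BB$ca_cb, BB$ang_ca_cb_sg, chi[4])
    Nb <- place_atom(SGb, CBb, CAb, BB$n_ca, BB$ang_n_ca_cb, chi[5])
    cur <- rbind(get_at(hb, ds$residue_b, "N"),
                 get_at(hb, ds$residue_b, "CA"),
                 get_at(hb, ds$residue_b, "CB"))
    fit <- kabsch_superpose(cur, rbind(Nb, CAb, CBb))
    helices[[hb]][, c("x", "y", "z")] <-
      apply_transform(as.matrix(helices[[hb]][, c("x", "y", "z")]), fit)
    set_at(ha, ds$residue_a, "SG", SGa)
    set_at(hb, ds$residue_b, "SG", SGb)
    moved[hb] <- TRUE
  }
  # contract re-measurement on lattice-placed helices
  mids <- t(vapply(helices, function(at)
    colMeans(as.matrix(at[at$elety == "CA", c("x", "y", "z")])), numeric(3)))
  for (i in seq_len(nh)) for (j in seq_len(nh)) {
    if (i >= j || moved[i] || moved[j]) next
    d <- vnorm(mids[i, ] - mids[j, ])
    if (bnd[i] == bnd[j] && d >= 12)
      stop("generation contract violated: intra-bundle midpoints ", i, ",",
           j, " at ", round(d, 1), " A")
    if (bnd[i] != bnd[j] && d <= 20)
      stop("generation contract violated: inter-bundle midpoints ", i, ",",
           j, " at ", round(d, 1), " A")
  }
  # loops: extended continuation from the preceding helix C-terminus
  all_atoms <- helices[[1]]
  for (i in seq_len(nh)[-1]) {
    if (loop > 0) {
      lstart <- helix_start[i - 1] + L
      lseq <- paste(seq_chars[lstart:(lstart + loop - 1)], collapse = "")
      prev <- helices[[i - 1]]
      last <- max(prev$resno)
      a <- prev[prev$resno == last, ]
      anchor <- lapply(c("N", "CA", "C"), function(e)
        as.numeric(a[a$elety == e, c("x", "y", "z")]))
      lat <- build_loop(lseq, anchor, start_resno = lstart)
      all_atoms <- rbind(all_atoms, lat)
    }
    all_atoms <- rbind(all_atoms, helices[[i]])
  }
  model <- structure_model(id, all_atoms)
  list(model = model,
       sequence = data.frame(id = id,
                             sequence = paste(seq_chars, collapse = ""),
                             stringsAsFactors = FALSE))
}

# Extended-strand loop continuing from anchor atoms (N, CA, C of the previous
# residue); chain-broken from whatever follows.
build_loop <- function(sequence, anchor, start_resno) {
  n <- nchar(sequence)
  ext <- build_backbone(paste0("A", sequence),
                        phi = rep(-120, n + 1), psi = rep(130, n + 1),
                        omega = rep(180, n + 1), start_resno = start_resno - 1L)
  # superpose the dummy first residue onto the anchor, then drop it
  cur <- rbind(ext[ext$resno == start_resno - 1L & ext$elety == "N",
                   c("x", "y", "z")],
               ext[ext$resno == start_resno - 1L & ext$elety == "CA",
                   c("x", "y", "z")],
               ext[ext$resno == start_resno - 1L & ext$elety == "C",
                   c("x", "y", "z")])
  fit <- kabsch_superpose(as.matrix(cur), do.call(rbind, anchor))
  ext[, c("x", "y", "z")] <-
    apply_transform(as.matrix(ext[, c("x", "y", "z")]), fit)
  ext[ext$resno >= start_resno, ]
}

#' Simulate a sequence family with controlled pairwise identity
#'
#' Sequences share planted, non-overlapping C-Y-C motifs at fixed positions;
#' all other positions derive from a random template and are independently
#' resampled so the expected pairwise identity matches `target_identity`
#' (closed-form calibration; non-motif alphabet excludes C and Y so the motif
#' count stays exact).
#'
#' @param n number of sequences.
#' @param length sequence length (>= 3 * `n_cyc_motifs`).
#' @param target_identity desired mean pairwise identity in \[0, 1\].
#' @param n_cyc_motifs exact number of C-Y-C motifs per sequence.
#' @param seed integer seed.
#' @return data.frame of records (`id`, `sequence`, `species` = NA).
#' @export
simulate_sequences <- function(n, length, target_identity, n_cyc_motifs = 0,
                               seed) {
  if (length < 3 * n_cyc_motifs)
    stop("length must be >= 3 * n_cyc_motifs")
  if (target_identity < 0 || target_identity > 1)
    stop("target_identity must be in [0, 1]")
  alpha <- setdiff(names(AA123), c("C", "Y"))  # 18 letters
  M <- n_cyc_motifs
  motif_pos <- if (M > 0)
    round_half_up(seq_len(M) * length / (M + 1)) else integer()
  motif_pos <- pmin(pmax(motif_pos, 1), length - 2)
  if (M > 1 && any(diff(motif_pos) < 3))
    motif_pos <- cumsum(c(1, rep(3, M - 1)))
  if (M > 0 && (any(diff(motif_pos) < 3) || max(motif_pos) + 2 > length))
    stop("cannot place ", M, " non-overlapping C-Y-C motifs in length ",
         length)
  motif_sites <- if (M > 0)
    as.integer(outer(c(0, 1, 2), motif_pos, `+`)) else integer()
  free_sites <- setdiff(seq_len(length), motif_sites)
  a_needed <- (target_identity * length - 3 * M) / max(1, length(free_sites))
  k <- length(alpha)
  p2 <- (a_needed - 1 / k) / (1 - 1 / k)
  p <- if (p2 <= 0) 0 else if (p2 >= 1) 1 else sqrt(p2)
  if (a_needed > 1 + 1e-9)
    stop("target_identity unattainable with the requested motifs")
  with_seed(seed, {
    template <- sample(alpha, length, replace = TRUE)
    recs <- vapply(seq_len(n), function(i) {
      s <- template
      keep <- stats::runif(length(free_sites)) < p
      resamp <- free_sites[!keep]
      s[resamp] <- sample(alpha, length(resamp), replace = TRUE)
      for (m in motif_pos) s[m:(m + 2)] <- c("C", "Y", "C")
      paste(s, collapse = "")
    }, character(1))
    data.frame(id = sprintf("sim%03d", seq_len(n)), sequence = recs,
               species = NA_character_, stringsAsFactors = FALSE)
  })
}

#' Simulate a per-residue confidence (pLDDT) profile
#'
#' Exactly `round(frac_high * n_res)` residues (round-half-up) receive
#' `high_value`, the rest `low_value`; the residue subset is drawn with the
#' seed. The returned model is flagged as predicted.
#'
#' @param model a `structure_model`.
#' @param frac_high fraction of residues at `high_value`, in \[0, 1\].
#' @param high_value,low_value confidence values in \[0, 100\].
#' @param seed integer seed.
#' @return the model with confidence written into its B-factor column and
#'   `is_predicted = TRUE`.
#' @export
simulate_confidence <- function(model, frac_high, high_value = 80,
                                low_value = 30, seed) {
  stopifnot(frac_high >= 0, frac_high <= 1,
            high_value >= 0, high_value <= 100,
            low_value >= 0, low_value <= 100)
  rt <- residue_table(model)
  n <- nrow(rt)
  k <- round_half_up(frac_high * n)
  hi <- with_seed(seed, sample.int(n, k))
  vals <- rep(low_value, n)
  vals[hi] <- high_value
  key <- paste(model$atoms$chain, model$atoms$resno, model$atoms$insert,
               sep = "\r")
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  model$atoms$b <- vals[match(key, rkey)]
  model$is_predicted <- TRUE
  validate_structure_model(model)
  model
}

#' Simulate a multiple sequence alignment with planted conserved columns
#'
#' Conserved columns contain a single residue type; all other columns are
#' drawn uniformly from the 20 amino acids.
#'
#' @param n_rows,n_cols alignment dimensions.
#' @param conserved_cols column indices to make fully conserved.
#' @param seed integer seed.
#' @return an `aa_alignment`.
#' @export
simulate_alignment <- function(n_rows, n_cols, conserved_cols = integer(),
                               seed) {
  if (length(conserved_cols) &&
      (min(conserved_cols) < 1 || max(conserved_cols) > n_cols))
    stop("conserved_cols out of range")
  aa <- names(AA123)
  with_seed(seed, {
    m <- matrix(sample(aa, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
    for (j in conserved_cols) m[, j] <- sample(aa, 1)
    new_alignment(data.frame(
      id = sprintf("row%03d", seq_len(n_rows)),
      sequence = apply(m, 1, paste, collapse = ""),
      stringsAsFactors = FALSE))
  })
}
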