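# backbone_geometry: phi/psi/omega dihedrals, ABEGO backbone-state encoding,
# helix segment detection with least-squares axes.

#' Backbone dihedral angles of a model
#'
#' Computes phi, psi and omega per residue (degrees, IUPAC convention,
#' (-180, 180]). omega of residue i is the peptide-bond torsion
#' CA(i-1)-C(i-1)-N(i)-CA(i). Angles are undefined (`NA`) at chain termini,
#' at chain breaks (consecutive C-N distance > `break_cutoff`), and for
#' backbone-incomplete residues — never silently zero.
#'
#' @param model a `structure_model`.
#' @param break_cutoff peptide C-N distance (Angstrom) beyond which
#'   consecutive residues are treated as unbonded; default 1.8.
#' @return data.frame with columns `chain`, `resno`, `insert`, `phi`, `psi`,
#'   `omega`.
#' @export
compute_dihedrals <- function(model, break_cutoff = 1.8) {
  rt <- residue_table(model)
  n <- nrow(rt)
  get <- function(i, name) {
    if (i < 1 || i > n) return(NULL)
    atom_xyz(model, rt$chain[i], rt$resno[i], name, rt$insert[i])
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  bonded <- function(i, j) {
    # is C(i) bonded to N(j)?
    ci <- get(i, "C"); nj <- get(j, "N")
    !is.null(ci) && !is.null(nj) && rt$chain[i] == rt$chain[j] &&
      vnorm(ci - nj) < break_cutoff
  }
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1 && bonded(i - 1, i)) {
      Cp <- get(i - 1, "C"); CAp <- get(i - 1, "CA")
      phi[i] <- torsion_angle(Cp, Ni, CAi, Ci)
      if (!is.null(CAp)) omega[i] <- torsion_angle(CAp, Cp, Ni, CAi)
    }
    if (i < n && bonded(i, i + 1)) {
      Nn <- get(i + 1, "N")
      psi[i] <- torsion_angle(Ni, CAi, Ci, Nn)
    }
  }
  data.frame(chain = rt$chain, resno = rt$resno, insert = rt$insert,
             phi = phi, psi = psi, omega = omega, stringsAsFactors = FALSE)
}

#' ABEGO backbone-state encoding
#'
#' Maps each residue's (phi, psi, omega) to one of five backbone states:
#' `O` if the peptide bond is cis (|omega| < 90); otherwise for phi < 0,
#' `A` (helical) if -75 <= psi < 50 else `B` (extended); for phi >= 0,
#' `G` if -100 <= psi < 100 else `E`. Undefined dihedrals give `X`.
#'
#' @param dihedrals data.frame from [compute_dihedrals()].
#' @param model_id label stored on the result.
#' @return object of class `abego_string`: list with `model_id`, `states`
#'   (single character string) and the residue index table.
#' @export
abego_encode <- function(dihedrals, model_id = "model") {
  st <- vapply(seq_len(nrow(dihedrals)), function(i) {
    phi <- dihedrals$phi[i]; psi <- dihedrals$psi[i]
    omega <- dihedrals$omega[i]
    if (is.na(phi) || is.na(psi)) return("X")
    if (!is.na(omega) && abs(omega) < 90) return("O")
    if (phi < 0) {
      if (psi >= -75 && psi < 50) "A" else "B"
    } else {
      if (psi >= -100 && psi < 100) "G" else "E"
    }
  }, character(1))
  structure(list(model_id = model_id, states = paste(st, collapse = ""),
                 residues = dihedrals[, c("chain", "resno", "insert")]),
            class = "abego_string")
}

#' @export
print.abego_string <- function(x, ...) {
  cat(sprintf("<abego_string> %s (%d residues)\n%s\n", x$model_id,
              nchar(x$states), x$states))
  invisible(x)
}

#' Convenience: ABEGO string straight from a model
#' @param model a `structure_model`.
#' @return an `abego_string`.
#' @export
abego_string <- function(model) {
  abego_encode(compute_dihedrals(model), model_id = model$id)
}

#' Detect helical segments from an ABEGO string
#'
#' A helix is a maximal run of at least `min_run` consecutive `A` states
#' within one chain. Each segment carries a least-squares axis through its CA
#' atoms (first principal component) and the CA centroid as midpoint.
#'
#' @param abego an `abego_string`.
#' @param model the `structure_model` the string was computed from (for axis
#'   geometry); if `NULL` only start/end indices are returned.
#' @param min_run minimum run length, default 6.
#' @return data.frame, one row per helix: `chain`, `start`, `end` (1-based
#'   residue indices into the model's residue table, inclusive), midpoint and
#'   axis endpoints (`mx,my,mz`, `ax1..az1`, `ax2..az2`).
#' @export
find_helices <- function(abego, model = NULL, min_run = 6) {
  st <- strsplit(abego$states, "")[[1]]
  ch <- abego$residues$chain
  runs <- rle(paste0(st, "\r", ch))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  is_helix <- startsWith(runs$values, "A\r") & runs$lengths >= min_run
  out <- data.frame(chain = ch[starts[is_helix]],
                    start = starts[is_helix], end = ends[is_helix],
                    stringsAsFactors = FALSE)
  geom <- matrix(NA_real_, nrow(out), 9,
                 dimnames = list(NULL, c("mx", "my", "mz", "ax1", "ay1",
                                         "az1", "ax2", "ay2", "az2")))
  if (!is.null(model) && nrow(out)) {
    rt <- residue_table(model)
    for (k in seq_len(nrow(out))) {
      idx <- out$start[k]:out$end[k]
      cas <- t(vapply(idx, function(i)
        atom_xyz(model, rt$chain[i], rt$resno[i], "CA", rt$insert[i]),
        numeric(3)))
      ctr <- colMeans(cas)
      ax <- svd(sweep(cas, 2, ctr))$v[, 1]
      proj <- as.numeric(sweep(cas, 2, ctr) %*% ax)
      geom[k, ] <- c(ctr, ctr + min(proj) * ax, ctr + max(proj) * ax)
    }
  }
  cbind(out, as.data.frame(geom))
}
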