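# disulfide_analysis: bridge detection, the five chi dihedrals, conformation
# classification (handedness x spiral/hook/staple with sign prefixes) and
# dihedral strain energy.

# Torsional-potential coefficients (kJ/mol): 3-fold terms on chi1/chi1' and
# chi2/chi2', a 2-fold plus 3-fold pair on chi3.
DSE_COEF <- c(chi1 = 8.37, chi2 = 4.18, chi3_2fold = 14.64, chi3_3fold = 2.51)

#' Detect disulfide bridges in a model
#'
#' All unordered cysteine SG pairs with S-S distance at most `max_ss` are
#' reported once, with residues canonically ordered by (chain, residue
#' number). Cysteines without a bonded partner are returned as free
#' sulfhydryls; cysteines lacking an SG atom are excluded with a warning.
#'
#' @param model a `structure_model`.
#' @param max_ss detection cutoff in Angstrom (default 2.4; covalent S-S is
#'   about 2.05 plus model noise).
#' @return list with `bonds` (data.frame: `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `ss_distance`) and `free` (data.frame of unpartnered
#'   cysteines: `chain`, `resno`).
#' @export
detect_disulfides <- function(model, max_ss = 2.4) {
  rt <- residue_table(model)
  cys <- rt[rt$resid == "CYS", , drop = FALSE]
  sg <- lapply(seq_len(nrow(cys)), function(i)
    atom_xyz(model, cys$chain[i], cys$resno[i], "SG", cys$insert[i]))
  has_sg <- !vapply(sg, is.null, logical(1))
  if (any(!has_sg))
    warning("cysteine(s) without SG atom excluded: ",
            paste(cys$resno[!has_sg], collapse = ", "))
  cys <- cys[has_sg, , drop = FALSE]
  sg <- sg[has_sg]
  nb <- nrow(cys)
  bonds <- data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      ss_distance = numeric(), stringsAsFactors = FALSE)
  partnered <- rep(FALSE, nb)
  if (nb >= 2) {
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      d <- vnorm(sg[[i]] - sg[[j]])
      if (d <= max_ss) {
        ord <- order(c(cys$chain[i], cys$chain[j]),
                     c(cys$resno[i], cys$resno[j]))
        ij <- c(i, j)[ord]
        bonds <- rbind(bonds, data.frame(
          chain_a = cys$chain[ij[1]], resno_a = cys$resno[ij[1]],
          chain_b = cys$chain[ij[2]], resno_b = cys$resno[ij[2]],
          ss_distance = d, stringsAsFactors = FALSE))
        partnered[c(i, j)] <- TRUE
      }
    }
  }
  list(bonds = bonds,
       free = data.frame(chain = cys$chain[!partnered],
                         resno = cys$resno[!partnered],
                         stringsAsFactors = FALSE))
}

#' Measure the five chi dihedrals of a disulfide bridge
#'
#' chi1 = N-CA-CB-SG of residue a, chi2 = CA-CB-SG-SG', chi3 =
#' CB-SG-SG'-CB', with chi2' and chi1' mirrored on residue b. The residue
#' pair is first canonically ordered by (chain, residue number) so the
#' primed/unprimed assignment is deterministic.
#'
#' @param model a `structure_model`.
#' @param record one row of the `bonds` table from [detect_disulfides()],
#'   or a list with `chain_a`, `resno_a`, `chain_b`, `resno_b`.
#' @return one-row data.frame: the canonical residue addresses,
#'   `ss_distance`, `chi1`, `chi2`, `chi3`, `chi2p`, `chi1p`, and a logical
#'   `measurable` (FALSE with NA chis when a backbone/CB/SG atom is missing).
#' @export
measure_chi <- function(model, record) {
  ord <- order(c(record$chain_a, record$chain_b),
               c(record$resno_a, record$resno_b))
  addr <- list(list(chain = record$chain_a, resno = record$resno_a),
               list(chain = record$chain_b, resno = record$resno_b))[ord]
  a <- addr[[1]]; b <- addr[[2]]
  g <- function(r, e) atom_xyz(model, r$chain, r$resno, e)
  atoms <- list(Na = g(a, "N"), CAa = g(a, "CA"), CBa = g(a, "CB"),
                SGa = g(a, "SG"), Nb = g(b, "N"), CAb = g(b, "CA"),
                CBb = g(b, "CB"), SGb = g(b, "SG"))
  out <- data.frame(chain_a = a$chain, resno_a = a$resno,
                    chain_b = b$chain, resno_b = b$resno,
                    ss_distance = NA_real_, chi1 = NA_real_, chi2 = NA_real_,
                    chi3 = NA_real_, chi2p = NA_real_, chi1p = NA_real_,
                    measurable = FALSE, stringsAsFactors = FALSE)
  if (any(vapply(atoms, is.null, logical(1)))) return(out)
  out$ss_distance <- vnorm(atoms$SGa - atoms$SGb)
  out$chi1 <- torsion_angle(atoms$Na, atoms$CAa, atoms$CBa, atoms$SGa)
  out$chi2 <- torsion_angle(atoms$CAa, atoms$CBa, atoms$SGa, atoms$SGb)
  out$chi3 <- torsion_angle(atoms$CBa, atoms$SGa, atoms$SGb, atoms$CBb)
  out$chi2p <- torsion_angle(atoms$CAb, atoms$CBb, atoms$SGb, atoms$SGa)
  out$chi1p <- torsion_angle(atoms$Nb, atoms$CAb, atoms$CBb, atoms$SGb)
  out$measurable <- TRUE
  out
}

#' Classify a disulfide conformation from its five chi dihedrals
#'
#' Handedness is LH for chi3 < 0, RH for chi3 > 0. The base shape compares
#' the signs of chi2 and chi2' with sign(chi3): both matching gives Spiral,
#' exactly one Hook, neither Staple. A sign prefix summarizes chi1/chi1':
#' `-` if both negative, `+` if both positive, `+/-` if mixed; the prefix is
#' omitted when either chi1 is trans (|chi1| > 150).
#'
#' @param chi numeric vector of five angles (chi1, chi2, chi3, chi2', chi1')
#'   in degrees; chi3 must be nonzero.
#' @return classification string, e.g. `"-LHSpiral"`, `"RHStaple"`.
#' @export
classify_geometry <- function(chi) {
  if (length(chi) != 5 || any(is.na(chi)))
    stop("need five defined chi angles")
  chi1 <- chi[1]; chi2 <- chi[2]; chi3 <- chi[3]
  chi2p <- chi[4]; chi1p <- chi[5]
  if (chi3 == 0) stop("chi3 = 0: planar bridge, handedness undefined")
  hand <- if (chi3 < 0) "LH" else "RH"
  s3 <- sign(chi3)
  n_match <- (sign(chi2) == s3) + (sign(chi2p) == s3)
  shape <- c("Staple", "Hook", "Spiral")[n_match + 1]
  prefix <- ""
  if (abs(chi1) <= 150 && abs(chi1p) <= 150) {
    prefix <- if (chi1 < 0 && chi1p < 0) "-"
    else if (chi1 > 0 && chi1p > 0) "+"
    else "+/-"
  }
  paste0(prefix, hand, shape)
}

#' Dihedral strain energy of a disulfide bridge
#'
#' DSE = 8.37(1 + cos 3chi1) + 8.37(1 + cos 3chi1') + 4.18(1 + cos 3chi2) +
#' 4.18(1 + cos 3chi2') + 14.64(1 + cos 2chi3) + 2.51(1 + cos 3chi3), in
#' kJ/mol. The all-trans bridge scores 29.28 kJ/mol; the relaxed left-handed
#' spiral (-60, -60, -90, -60, -60) scores 2.51 kJ/mol.
#'
#' @param chi numeric vector of five angles (chi1, chi2, chi3, chi2', chi1')
#'   in degrees.
#' @param coefficients named coefficient set (kJ/mol); see `DSE_COEF` for the
#'   default torsional-potential values.
#' @return strain energy in kJ/mol (>= 0).
#' @export
dihedral_strain_energy <- function(chi, coefficients = DSE_COEF) {
  if (length(chi) != 5 || any(is.na(chi)))
    stop("need five defined chi angles")
  r <- chi * DEG
  coefficients[["chi1"]] * (2 + cos(3 * r[1]) + cos(3 * r[5])) +
    coefficients[["chi2"]] * (2 + cos(3 * r[2]) + cos(3 * r[4])) +
    coefficients[["chi3_2fold"]] * (1 + cos(2 * r[3])) +
    coefficients[["chi3_3fold"]] * (1 + cos(3 * r[3]))
}

#' Full disulfide analysis of one model
#'
#' Detects bridges, measures chi dihedrals, classifies geometry and computes
#' strain energy for each.
#'
#' @param model a `structure_model`.
#' @param max_ss detection cutoff (Angstrom).
#' @return list with `bonds` (data.frame with chis, `geometry_class`, `dse`)
#'   and `free` (unpartnered cysteines).
#' @export
analyze_disulfides <- function(model, max_ss = 2.4) {
  det <- detect_disulfides(model, max_ss = max_ss)
  if (nrow(det$bonds) == 0)
    return(list(bonds = cbind(det$bonds, chi1 = numeric(), chi2 = numeric(),
                              chi3 = numeric(), chi2p = numeric(),
                              chi1p = numeric(), geometry_class = character(),
                              dse = numeric()),
                free = det$free))
  rows <- lapply(seq_len(nrow(det$bonds)), function(i) {
    rec <- measure_chi(model, det$bonds[i, ])
    chi <- c(rec$chi1, rec$chi2, rec$chi3, rec$chi2p, rec$chi1p)
    if (rec$measurable && rec$chi3 != 0) {
      rec$geometry_class <- classify_geometry(chi)
      rec$dse <- dihedral_strain_energy(chi)
    } else {
      rec$geometry_class <- NA_character_
      rec$dse <- NA_real_
    }
    rec
  })
  list(bonds = do.call(rbind, rows), free = det$free)
}
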