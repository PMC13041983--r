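# io_core: structure/sequence I/O and the shared domain containers.
#
# A StructureModel is a light S3 wrapper around a bio3d-style atom table:
# one row per atom with chain/resno/insert/resid/elety/elesy/x/y/z/o/b.
# Per-residue confidence (pLDDT for predicted models, B-factor otherwise)
# lives in the `b` column and is summarized per residue via the CA atom.

AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA123 <- stats::setNames(names(AA321), unname(AA321))

# Residues treated as amino acids when they appear as HETATM (e.g. MSE).
NONSTANDARD_AA <- c("MSE", "SEC", "PYL", "MLY", "CSO", "HYP", "SEP", "TPO")

aa_three_to_one <- function(resid) {
  out <- unname(AA321[resid])
  out[is.na(out)] <- "X"
  out
}

#' Construct a StructureModel
#'
#' @param id character label for the model.
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `elesy`, `x`, `y`, `z`, `o`, `b` (one row per atom).
#' @param is_predicted logical; if `TRUE` the `b` column is interpreted as
#'   per-residue pLDDT and must lie in \[0, 100\].
#' @param source_path optional originating file path.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(id, atoms, is_predicted = FALSE,
                            source_path = NA_character_) {
  stopifnot(is.data.frame(atoms))
  needed <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "x", "y", "z", "o", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  m <- structure(
    list(id = as.character(id), atoms = atoms,
         is_predicted = isTRUE(is_predicted),
         source_path = as.character(source_path)),
    class = "structure_model")
  validate_structure_model(m)
  m
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<structure_model> %s: %d chain(s), %d residues, %d atoms%s\n",
              x$id, length(unique(x$atoms$chain)), nrow(rt), nrow(x$atoms),
              if (x$is_predicted) " (predicted; b = pLDDT)" else ""))
  invisible(x)
}

validate_structure_model <- function(model) {
  atoms <- model$atoms
  if (nrow(atoms) == 0) stop("structure model '", model$id, "' has no atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates in model '", model$id, "'")
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, ]
    key <- paste(sub$resno, sub$insert)
    resno <- sub$resno[!duplicated(key)]
    ins <- sub$insert[!duplicated(key)]
    ord <- order(resno, ins)
    if (is.unsorted(ord, strictly = TRUE) && !identical(ord, seq_along(ord)))
      stop("residue numbering not increasing in chain ", ch,
           " of model '", model$id, "'")
  }
  if (model$is_predicted) {
    conf <- residue_table(model)$confidence
    bad <- conf[!is.na(conf)]
    if (length(bad) && (any(bad < 0) || any(bad > 100)))
      stop("predicted model '", model$id,
           "' has confidence values outside [0, 100]")
  }
  invisible(model)
}

#' Per-residue summary table of a model
#'
#' One row per residue in order of appearance: chain, residue number,
#' insertion code, 3-letter and 1-letter residue names, and confidence
#' (B-factor of the CA atom, or the mean over the residue's atoms if no CA).
#'
#' @param model a `structure_model`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `aa1`, `confidence`.
#' @export
residue_table <- function(model) {
  atoms <- model$atoms
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(key)
  idx <- which(first)
  conf <- vapply(idx, function(i) {
    rows <- which(key == key[i])
    ca <- rows[atoms$elety[rows] == "CA"]
    if (length(ca)) atoms$b[ca[1]] else mean(atoms$b[rows])
  }, numeric(1))
  data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    insert = atoms$insert[first], resid = atoms$resid[first],
    aa1 = aa_three_to_one(atoms$resid[first]),
    confidence = conf, stringsAsFactors = FALSE)
}

#' @rdname residue_table
#' @export
n_residues <- function(model) nrow(residue_table(model))

#' One-letter sequence of a model (chains concatenated in order)
#' @param model a `structure_model`.
#' @return single character string; nonstandard residues appear as `X`.
#' @export
model_sequence <- function(model) {
  paste(residue_table(model)$aa1, collapse = "")
}

#' CA coordinates of a model
#' @param model a `structure_model`.
#' @return n x 3 matrix of CA atom positions (residues lacking CA skipped).
#' @export
ca_xyz <- function(model) {
  a <- model$atoms[model$atoms$elety == "CA", ]
  as.matrix(a[, c("x", "y", "z")])
}

# Coordinates of one named atom of one residue, or NULL if absent.
atom_xyz <- function(model, chain, resno, elety, insert = "") {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$insert == insert &
               a$elety == elety)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Read a PDB file into a StructureModel
#'
#' Parsing is delegated to [bio3d::read.pdb()]; only the first MODEL of a
#' multi-model file is retained, waters and non-amino-acid heteroatoms are
#' dropped, and for alternate locations the highest-occupancy copy wins (ties
#' broken by altloc letter order).
#'
#' @param path PDB file.
#' @param is_predicted logical; interpret the B-factor column as pLDDT.
#' @param altloc_policy only `"occupancy"` is implemented.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, is_predicted = FALSE,
                           altloc_policy = "occupancy") {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  altloc_policy <- match.arg(altloc_policy, "occupancy")
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" | at$resid %in% NONSTANDARD_AA
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop("no amino-acid residues found in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # altloc resolution: highest occupancy, tie by altloc letter
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(akey)) {
    ord <- order(akey, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(akey[ord]), , drop = FALSE]
    at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                         unique(paste(at$chain, at$resno, at$insert,
                                      sep = "\r")))), , drop = FALSE]
  }
  at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$insert), ,
           drop = FALSE]
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert, resid = at$resid,
    elety = at$elety, elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                                     substr(gsub("[0-9]", "", at$elety), 1, 1),
                                     at$elesy),
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    stringsAsFactors = FALSE)
  structure_model(id = sub("\\.(pdb|ent)$", "", basename(path)),
                  atoms = atoms, is_predicted = is_predicted,
                  source_path = path)
}

#' Write a StructureModel to a PDB file
#'
#' Optionally overwrites the B-factor column with per-residue values (e.g. a
#' conservation profile), every atom of a residue receiving that residue's
#' value.
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @param per_residue_values optional numeric vector, one value per residue in
#'   [residue_table()] order.
#' @export
write_structure <- function(model, path, per_residue_values = NULL) {
  atoms <- model$atoms
  b <- atoms$b
  if (!is.null(per_residue_values)) {
    rt <- residue_table(model)
    if (length(per_residue_values) != nrow(rt))
      stop("per_residue_values length (", length(per_residue_values),
           ") != residue count (", nrow(rt), ")")
    key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
    rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
    b <- per_residue_values[match(key, rkey)]
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = "ATOM", resno = atoms$resno, resid = atoms$resid,
    eleno = seq_len(nrow(atoms)), elety = atoms$elety,
    chain = atoms$chain, insert = ifelse(atoms$insert == "", NA,
                                         atoms$insert),
    o = atoms$o, b = b, elesy = atoms$elesy)
  invisible(NULL)
}

#' Read/write FASTA sequence records
#'
#' @param path FASTA file.
#' @return `read_fasta()`: data.frame with columns `id`, `sequence`,
#'   `species` (NA unless the header carries a `species=` tag).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path)
  seqs <- toupper(as.character(ss))
  sp <- rep(NA_character_, length(ss))
  hit <- regmatches(names(ss), regexpr("species=\\S+", names(ss)))
  has <- grepl("species=", names(ss))
  sp[has] <- sub("species=", "", hit)
  data.frame(id = names(ss), sequence = unname(seqs), species = sp,
             stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param records data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @export
write_fasta <- function(records, path) {
  records <- as_sequence_records(records)
  ss <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(NULL)
}

as_sequence_records <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    records <- data.frame(id = ids, sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in%
                                          names(records)))
  records$sequence <- toupper(records$sequence)
  if (any(nchar(records$sequence) == 0)) stop("empty sequence in records")
  records
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length; a ragged alignment is an error naming the
#' first offending record.
#'
#' @param path aligned FASTA file with `-` gap characters.
#' @return object of class `aa_alignment`: list with `records` (data.frame
#'   `id`, `sequence`) and `n_columns`.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path)
  w <- nchar(recs$sequence)
  if (length(unique(w)) > 1) {
    bad <- which(w != w[1])[1]
    stop("ragged alignment in ", path, ": record '", recs$id[bad],
         "' has length ", w[bad], ", expected ", w[1])
  }
  new_alignment(recs)
}

#' Construct an alignment from equal-length records
#' @param records data.frame with `id` and `sequence` columns (rows of equal
#'   length, `-` for gaps) or a named character vector.
#' @return an `aa_alignment`.
#' @export
new_alignment <- function(records) {
  records <- as_sequence_records(records)
  w <- unique(nchar(records$sequence))
  if (length(w) != 1) stop("alignment rows differ in length")
  structure(list(records = records[, c("id", "sequence")], n_columns = w),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d rows x %d columns\n",
              nrow(x$records), x$n_columns))
  invisible(x)
}

#' Validate / construct a labelled symmetric distance matrix
#'
#' @param values square numeric matrix, symmetric within 1e-9, zero diagonal.
#' @param labels row/column labels; defaults to existing dimnames.
#' @return the matrix with dimnames set, class `c("distance_matrix","matrix")`.
#' @export
as_distance_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels) || length(labels) != nrow(values))
    stop("labels must match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (any(values < -1e-12)) stop("negative distances")
  if (max(abs(values - t(values))) > 1e-9) stop("matrix not symmetric")
  if (max(abs(diag(values))) > 1e-9) stop("nonzero diagonal")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  class(values) <- c("distance_matrix", "matrix", "array")
  values
}

#' Write / read a labelled matrix as CSV (header row + label column)
#' @param m matrix with dimnames; `path` file path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(NULL)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
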