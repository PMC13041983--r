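# Hand-rolled PDB text lines for parser fixtures (fixed-column format).
pdb_atom_line <- function(serial, name, alt, res, chain, resno, x, y, z,
                          occ = 1, b = 0, ele = substr(name, 1, 1)) {
  sprintf(paste0("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f",
                 "%6.2f%6.2f          %2s"),
          serial, name, alt, res, chain, resno, x, y, z, occ, b, ele)
}

write_mini_pdb <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

# three-residue glycine strand with backbone only
mini_tripeptide_lines <- function(b = c(10, 20, 30)) {
  k <- 0
  out <- character()
  for (i in 1:3) {
    x0 <- (i - 1) * 3.8
    out <- c(out,
      pdb_atom_line(k + 1, "N", " ", "GLY", "A", i, x0, 0, 0, b = b[i]),
      pdb_atom_line(k + 2, "CA", " ", "GLY", "A", i, x0 + 1.46, 0, 0,
                    b = b[i], ele = "C"),
      pdb_atom_line(k + 3, "C", " ", "GLY", "A", i, x0 + 2.2, 1.2, 0,
                    b = b[i]))
    k <- k + 3
  }
  out
}
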