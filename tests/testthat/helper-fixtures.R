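# Small shared fixtures, built in code at load time.

simple_molecule <- function(elements, xyz, bonds = NULL, fc = 0L,
                            name = "test") {
  molecule(name,
           data.frame(element = elements, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3],
                      formal_charge = rep_len(as.integer(fc), length(elements))),
           bonds)
}

water_molecule <- function() {
  # exactly mirror-symmetric so geometry-sensitive methods keep the
  # two hydrogens at identical charges
  simple_molecule(c("O", "H", "H"),
                  rbind(c(0, 0, 0), c(0.757, 0.586, 0), c(-0.757, 0.586, 0)),
                  data.frame(i = c(1, 1), j = c(2, 3), order = 1L),
                  name = "water")
}

ethanol_graph <- function() {
  # C1(H x3) - C2(H x2) - O - H, no coordinates needed
  molecule("ethanol",
           data.frame(element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
                      formal_charge = 0L),
           data.frame(i = c(1, 2, 3, 1, 1, 1, 2, 2),
                      j = c(2, 3, 9, 4, 5, 6, 7, 8),
                      order = 1L))
}

write_sdf_v2000 <- function(mol, path, dim = "3D", append = FALSE) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  xyz <- mol$atoms[, c("x", "y", "z")]
  if (anyNA(xyz)) xyz[is.na(xyz)] <- 0
  lines <- c(mol$name, paste0("  testthat ", dim), "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     xyz$x, xyz$y, xyz$z, mol$atoms$element),
             if (nb) sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                             mol$bonds$order))
  fc <- which(mol$atoms$formal_charge != 0)
  for (i in fc) {
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i,
                              mol$atoms$formal_charge[i]))
  }
  lines <- c(lines, "M  END", "$$$$")
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

phenols_dir <- function() system.file("extdata", "phenols", package = "atomcharge")

# Index of the phenolic hydrogen: the H bonded to an O.
hydroxyl_h_index <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (el[b$i[k]] == "O" && el[b$j[k]] == "H") return(b$j[k])
    if (el[b$j[k]] == "O" && el[b$i[k]] == "H") return(b$i[k])
  }
  NA_integer_
}
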