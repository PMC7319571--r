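# Charge output: PQR (proteins), MOL2 (small molecules) and plain text.

#' Write computed charges to a file
#'
#' \code{txt}: two lines per molecule -- the name, then the charges in
#' atom order with four decimals.  \code{mol2}: TRIPOS blocks with the
#' charge in column 9 of the atom records and the charge-type line set
#' to the method id.  \code{pqr}: white-space-delimited PQR rows whose
#' charge column comes from the result and whose radius column comes
#' from the bundled covalent-radius table; requires residue annotation
#' (polymer inputs).
#'
#' @param results a \code{charge_result} or list of them.
#' @param mols the corresponding \code{molecule} or list of molecules.
#' @param format \code{"txt"}, \code{"mol2"} or \code{"pqr"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_charges <- function(results, mols, format = c("txt", "mol2", "pqr"),
                          path) {
  format <- match.arg(format)
  if (inherits(results, "charge_result")) results <- list(results)
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (length(results) != length(mols)) {
    stop("results and molecules are not aligned (", length(results),
         " vs ", length(mols), ")")
  }
  lines <- switch(format,
    txt = unlist(lapply(seq_along(results), function(k) {
      c(results[[k]]$molecule,
        paste(sprintf("%.4f", results[[k]]$charges), collapse = " "))
    })),
    mol2 = unlist(lapply(seq_along(results), function(k) {
      format_mol2(results[[k]], mols[[k]])
    })),
    pqr = unlist(lapply(seq_along(results), function(k) {
      format_pqr(results[[k]], mols[[k]])
    })))
  writeLines(lines, path)
  invisible(path)
}

format_mol2 <- function(res, mol) {
  atoms <- mol$atoms
  n <- nrow(atoms)
  xyz <- atoms[, c("x", "y", "z")]
  if (anyNA(xyz)) xyz[is.na(xyz)] <- 0
  sybyl_order <- function(o) c("1", "2", "3")[o]
  c("@<TRIPOS>MOLECULE",
    mol$name,
    sprintf(" %d %d 0 0 0", n, nrow(mol$bonds)),
    "SMALL",
    toupper(res$method),
    "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-5s %5d %-8s %10.4f",
            seq_len(n), paste0(atoms$element, seq_len(n)),
            xyz$x, xyz$y, xyz$z, atoms$element,
            ifelse(is.na(atoms$resid), 1L, atoms$resid),
            ifelse(is.na(atoms$resname), "UNL", atoms$resname),
            res$charges),
    "@<TRIPOS>BOND",
    if (nrow(mol$bonds)) {
      sprintf("%6d %5d %5d %4s", seq_len(nrow(mol$bonds)),
              mol$bonds$i, mol$bonds$j, sybyl_order(mol$bonds$order))
    } else character())
}

format_pqr <- function(res, mol) {
  atoms <- mol$atoms
  if (all(is.na(atoms$resname))) {
    stop("PQR output needs residue annotation, which molecule '",
         mol$name, "' does not carry; use the txt format instead")
  }
  n <- nrow(atoms)
  c(sprintf("REMARK   1 charges: %s (%s)", res$method, res$parameter_set),
    sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f %8.4f %7.4f",
            seq_len(n), substr(atoms$name, 1, 4),
            ifelse(is.na(atoms$resname), "UNL", substr(atoms$resname, 1, 4)),
            ifelse(is.na(atoms$resid), 1L, atoms$resid),
            atoms$x, atoms$y, atoms$z, res$charges,
            covalent_radius(atoms$element)),
    "TER", "END")
}
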