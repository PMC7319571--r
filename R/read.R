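# Structure input: SDF (V2000), MOL2, PDB, mmCIF, and zip / tar.gz
# archives of those.  Parsing of the established formats is delegated to
# ChemmineR (SDF) and bio3d (MOL2 / PDB / mmCIF); this module adds the
# validation layer, formal-charge extraction, multi-record splitting and
# distance-based bond perception.

new_report <- function() {
  data.frame(severity = character(), message = character(),
             file = character(), molecule = character())
}

add_issue <- function(report, severity, message, file = NA, molecule = NA) {
  rbind(report, data.frame(severity = severity, message = message,
                           file = as.character(file),
                           molecule = as.character(molecule)))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s, %d issue(s)>\n",
              if (x$ok) "ok" else "FAILED", nrow(x$issues)))
  for (r in seq_len(nrow(x$issues))) {
    cat(sprintf("  [%s] %s (%s%s)\n", x$issues$severity[r],
                x$issues$message[r], basename(x$issues$file[r]),
                if (is.na(x$issues$molecule[r])) ""
                else paste0(", ", x$issues$molecule[r])))
  }
  invisible(x)
}

finish_report <- function(issues) {
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' Read molecular structures with validation
#'
#' Reads one structure file -- SDF (V2000), MOL2 (TRIPOS), PDB or mmCIF,
#' detected by extension and then content sniffing -- or a zip / tar.gz
#' archive of such files (members processed recursively; nested archives
#' are rejected).  PDB and mmCIF inputs without explicit bonds get bonds
#' perceived from covalent radii (see \code{\link{perceive_bonds}}).
#' Parse problems never escape as raw errors: everything is collected
#' into the validation report.
#'
#' @param path input file.
#' @param max_file_size per-file size guard in bytes (default 10 MB).
#' @param perceive perceive bonds for bond-less polymer formats.
#' @return list with \code{molecules} (list of \code{molecule}) and
#'   \code{report} (a \code{validation_report}).
#' @export
read_structures <- function(path, max_file_size = 10e6, perceive = TRUE) {
  issues <- new_report()
  mols <- list()
  if (!file.exists(path)) {
    return(list(molecules = mols,
                report = finish_report(add_issue(issues, "error",
                  "file does not exist", path))))
  }
  fmt <- detect_format(path)
  if (fmt %in% c("zip", "targz")) {
    exdir <- tempfile("atomcharge_archive_")
    dir.create(exdir)
    members <- tryCatch({
      if (fmt == "zip") utils::unzip(path, exdir = exdir)
      else { utils::untar(path, exdir = exdir)
             list.files(exdir, recursive = TRUE, full.names = TRUE) }
    }, error = function(e) e)
    if (inherits(members, "error")) {
      issues <- add_issue(issues, "error",
                          paste("cannot extract archive:",
                                conditionMessage(members)), path)
      return(list(molecules = mols, report = finish_report(issues)))
    }
    for (m in sort(members)) {
      if (detect_format(m) %in% c("zip", "targz")) {
        issues <- add_issue(issues, "error", "nested archives are not supported", m)
        next
      }
      sub <- read_structures(m, max_file_size, perceive)
      mols <- c(mols, sub$molecules)
      issues <- rbind(issues, sub$report$issues)
    }
    return(list(molecules = mols, report = finish_report(issues)))
  }
  if (file.size(path) > max_file_size) {
    issues <- add_issue(issues, "error",
                        sprintf("file exceeds the %d-byte size guard",
                                as.integer(max_file_size)), path)
    return(list(molecules = mols, report = finish_report(issues)))
  }
  if (fmt == "unknown") {
    issues <- add_issue(issues, "error", "unsupported or unrecognized format", path)
    return(list(molecules = mols, report = finish_report(issues)))
  }
  res <- tryCatch(
    switch(fmt,
      sdf = read_sdf_file(path),
      mol2 = read_mol2_file(path),
      pdb = read_pdb_file(path),
      cif = read_cif_file(path)),
    error = function(e) {
      list(molecules = list(),
           issues = add_issue(new_report(), "error",
                              paste("parse failure:", conditionMessage(e)),
                              path))
    })
  issues <- rbind(issues, res$issues)
  mols <- res$molecules
  # polymer post-processing: perceive bonds, warn about absent hydrogens
  if (fmt %in% c("pdb", "cif")) {
    for (k in seq_along(mols)) {
      if (!any(mols[[k]]$atoms$element == "H") && n_atoms(mols[[k]]) > 3) {
        issues <- add_issue(issues, "warning",
          "polymer input contains no hydrogen atoms (they are not added automatically)",
          path, mols[[k]]$name)
      }
      if (perceive && nrow(mols[[k]]$bonds) == 0) {
        pb <- perceive_bonds(mols[[k]])
        mols[[k]] <- pb$molecule
        for (w in pb$warnings) {
          issues <- add_issue(issues, "warning", w, path, mols[[k]]$name)
        }
      }
    }
  }
  if (!length(mols) && !any(issues$severity == "error")) {
    issues <- add_issue(issues, "error", "input contains no molecules", path)
  }
  list(molecules = mols, report = finish_report(issues))
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (grepl("\\.tar\\.gz$|\\.tgz$", tolower(path))) return("targz")
  if (ext == "zip") return("zip")
  if (ext %in% c("sdf", "mol")) return("sdf")
  if (ext == "mol2") return("mol2")
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("cif")
  # content sniffing
  head <- tryCatch(suppressWarnings(readLines(path, n = 50)),
                   error = function(e) character())
  if (any(grepl("^@<TRIPOS>MOLECULE", head))) return("mol2")
  if (any(grepl("^data_", head)) || any(grepl("_atom_site", head))) return("cif")
  if (any(grepl("^(ATOM|HETATM|HEADER)", head))) return("pdb")
  if (any(grepl("V2000|V3000", head))) return("sdf")
  "unknown"
}

# SDF ----------------------------------------------------------------------

read_sdf_file <- function(path) {
  issues <- new_report()
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    return(list(molecules = list(),
                issues = add_issue(issues, "error", "empty input", path)))
  }
  # split records at $$$$ delimiters (last record may omit it)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1, ends + 1)
  ends <- c(ends, length(lines) + 1)
  mols <- list()
  rec <- 0
  for (k in seq_along(starts)) {
    if (starts[k] >= ends[k]) next
    block <- lines[starts[k]:(ends[k] - 1)]
    if (all(!nzchar(trimws(block)))) next
    rec <- rec + 1
    name <- trimws(block[1])
    if (!nzchar(name)) name <- sprintf("%s_%d", basename(path), rec)
    if (length(block) < 4) {
      issues <- add_issue(issues, "error",
        sprintf("record starting at line %d is truncated", starts[k]),
        path, name)
      next
    }
    if (grepl("V3000", block[4])) {
      issues <- add_issue(issues, "error",
        "SDF V3000 connection tables are not supported (V2000 only)",
        path, name)
      next
    }
    mol <- tryCatch(parse_sdf_record(block, name),
                    error = function(e) e)
    if (inherits(mol, "error")) {
      issues <- add_issue(issues, "error",
        sprintf("record starting at line %d: %s", starts[k],
                conditionMessage(mol)), path, name)
    } else {
      mols[[length(mols) + 1]] <- mol
    }
  }
  list(molecules = mols, issues = issues)
}

# One V2000 connection table; the ChemmineR SDF parser supplies the atom
# and bond blocks, the property lines (M  CHG) are scanned here because
# ChemmineR does not surface formal charges.
parse_sdf_record <- function(block, name) {
  sdf <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(block)))[[1]]
  if (!suppressWarnings(ChemmineR::validSDF(ChemmineR::SDFset(list(sdf), "1")))) {
    stop("does not conform to the V2000 connection-table standard")
  }
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- normalize_element(sub("_.*$", "", rownames(ab)))
  natom <- nrow(ab)
  fc <- integer(natom)
  for (ln in grep("^M  CHG", block, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    npairs <- f[1]
    for (p in seq_len(npairs)) {
      fc[f[2 * p]] <- f[2 * p + 1]
    }
  }
  # 2D-only records (dimension flag or all-zero coordinates) carry no
  # usable geometry
  xyz <- ab[, 1:3, drop = FALSE]
  is2d <- grepl("2D", block[2], fixed = TRUE) ||
    all(abs(xyz) < 1e-12)
  atoms <- data.frame(element = el,
                      x = if (is2d) NA_real_ else xyz[, 1],
                      y = if (is2d) NA_real_ else xyz[, 2],
                      z = if (is2d) NA_real_ else xyz[, 3],
                      formal_charge = fc,
                      name = paste0(el, seq_len(natom)))
  bonds <- if (NROW(bb)) {
    ord <- bb[, 3]
    ord[ord == 4] <- 2   # aromatic counts as the double-bond contribution
    data.frame(i = bb[, 1], j = bb[, 2], order = pmin(pmax(ord, 1), 3))
  } else NULL
  molecule(name, atoms, bonds)
}

# MOL2 ---------------------------------------------------------------------

read_mol2_file <- function(path) {
  issues <- new_report()
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("no @<TRIPOS>MOLECULE record found")
  ends <- c(starts[-1] - 1, length(lines))
  mols <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    tmp <- tempfile(fileext = ".mol2")
    writeLines(block, tmp)
    m <- tryCatch(mol2_to_molecule(suppressWarnings(bio3d::read.mol2(tmp))),
                  error = function(e) e)
    unlink(tmp)
    if (inherits(m, "error")) {
      issues <- add_issue(issues, "error",
        sprintf("MOLECULE record %d (line %d): %s", k, starts[k],
                conditionMessage(m)), path)
    } else {
      mols[[length(mols) + 1]] <- m
    }
  }
  list(molecules = mols, issues = issues)
}

# TRIPOS bond types: aromatic bonds count as the highest-order (2)
# contribution for atom typing; amide and unknown types as single.
.mol2_order <- function(type) {
  o <- suppressWarnings(as.integer(type))
  o[type == "ar"] <- 2L
  o[is.na(o)] <- 1L
  pmin(pmax(o, 1L), 3L)
}

mol2_to_molecule <- function(m2) {
  a <- m2$atom
  el <- normalize_element(ifelse(grepl("\\.", a$elety),
                                 sub("\\..*$", "", a$elety),
                                 gsub("[0-9]", "", a$elena)))
  atoms <- data.frame(element = el, x = a$x, y = a$y, z = a$z,
                      formal_charge = 0L, name = a$elena,
                      resname = a$resid, resid = a$resno)
  bonds <- if (NROW(m2$bond)) {
    data.frame(i = m2$bond$origin, j = m2$bond$target,
               order = .mol2_order(m2$bond$type))
  } else NULL
  molecule(if (nzchar(m2$name)) m2$name else "mol2_molecule", atoms, bonds)
}

# PDB / mmCIF --------------------------------------------------------------

# Keep the highest-occupancy alternate location (ties -> first record).
filter_altloc <- function(a) {
  alt <- a$alt
  if (all(is.na(alt) | alt %in% c("", "A"))) {
    return(a[is.na(alt) | alt %in% c("", "A"), , drop = FALSE])
  }
  grp <- paste(a$chain, a$resno, a$elety)
  keep <- unlist(lapply(split(seq_len(nrow(a)), grp), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- a$o[idx]
    occ[is.na(occ)] <- 1
    idx[which.max(occ)]
  }))
  a[sort(keep), , drop = FALSE]
}

pdbatoms_to_molecule <- function(a, name, conect = NULL) {
  a <- filter_altloc(a)
  el <- a$elesy
  bad <- is.na(el) | !nzchar(trimws(el))
  el[bad] <- gsub("[^A-Za-z]", "", substr(a$elety[bad], 1, 2))
  el <- normalize_element(el)
  # two-letter guesses that are not elements fall back to one letter
  el[!is_valid_element(el)] <- substr(el[!is_valid_element(el)], 1, 1)
  fc <- rep(0L, nrow(a))
  if (!is.null(a$charge)) {
    ch <- suppressWarnings(as.integer(a$charge))
    fc[!is.na(ch)] <- ch[!is.na(ch)]
  }
  atoms <- data.frame(element = el, x = a$x, y = a$y, z = a$z,
                      formal_charge = fc, name = a$elety,
                      resname = a$resid, resid = a$resno, chain = a$chain)
  bonds <- NULL
  if (!is.null(conect) && nrow(conect)) {
    idx <- match(conect$i, a$eleno)
    jdx <- match(conect$j, a$eleno)
    ok <- !is.na(idx) & !is.na(jdx) & idx != jdx
    if (any(ok)) {
      pi <- pmin(idx[ok], jdx[ok]); pj <- pmax(idx[ok], jdx[ok])
      dup <- duplicated(paste(pi, pj))
      bonds <- data.frame(i = pi[!dup], j = pj[!dup], order = 1L)
    }
  }
  molecule(name, atoms, bonds)
}

read_pdb_file <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  conect <- parse_conect(readLines(path, warn = FALSE))
  name <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  list(molecules = list(pdbatoms_to_molecule(pdb$atom, name, conect)),
       issues = new_report())
}

parse_conect <- function(lines) {
  cl <- grep("^CONECT", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  out <- do.call(rbind, lapply(cl, function(l) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7)), "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    data.frame(i = f[1], j = f[-1])
  }))
  out
}

read_cif_file <- function(path) {
  cif <- suppressWarnings(bio3d::read.cif(path))
  a <- cif$atom
  # first model only: stop at the first repeated atom serial
  if (anyDuplicated(a$eleno)) {
    a <- a[seq_len(which(duplicated(a$eleno))[1] - 1), , drop = FALSE]
  }
  name <- sub("\\.(cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  list(molecules = list(pdbatoms_to_molecule(a, name)),
       issues = new_report())
}

# Bond perception ----------------------------------------------------------

#' Perceive bonds from interatomic distances
#'
#' Creates a single bond between atoms i and j whenever
#' R_ij <= r_cov(i) + r_cov(j) + 0.4 A and R_ij > 0.4 A, using the
#' bundled covalent radii.  Pairs below 0.4 A are flagged as steric
#' clashes and left unbonded.  Used for PDB/mmCIF inputs that carry no
#' explicit bond list.
#'
#' @param mol a \code{molecule} with coordinates.
#' @return list with \code{molecule} (bonds attached) and
#'   \code{warnings} (character vector, e.g. clash reports).
#' @export
perceive_bonds <- function(mol) {
  xyz <- coords_matrix(mol)
  r <- covalent_radius(mol$atoms$element)
  n <- nrow(xyz)
  warnings <- character()
  maxreach <- 2 * max(r) + 0.4
  nb <- grid_neighbors(xyz, maxreach)
  bi <- integer(); bj <- integer()
  for (i in seq_len(n)) {
    cand <- nb[[i]]
    cand <- cand[cand > i]
    if (!length(cand)) next
    d <- sqrt((xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
              (xyz[cand, 3] - xyz[i, 3])^2)
    cut <- r[i] + r[cand] + 0.4
    clash <- d <= 0.4
    if (any(clash)) {
      warnings <- c(warnings,
        sprintf("atoms %d and %d are %.2f A apart (steric clash); no bond perceived",
                i, cand[clash][1], d[clash][1]))
    }
    hit <- which(d <= cut & !clash)
    bi <- c(bi, rep(i, length(hit)))
    bj <- c(bj, cand[hit])
  }
  bonds <- if (length(bi)) data.frame(i = bi, j = bj, order = 1L) else NULL
  list(molecule = molecule(mol$name, mol$atoms, bonds, mol$total_charge),
       warnings = warnings)
}
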