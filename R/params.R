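# Parameter-set objects, the on-disk JSON dialect, the bundled registry
# and per-molecule applicability / automatic selection.

# Registry of implemented methods.  atom_slots: named per-atom-type
# parameter slots; common_slots: global scalars; bond_slots: per-bond
# parameters (required only where bond_required is TRUE).
.method_registry <- list(
  eem = list(id = "eem", label = "EEM",
             dimensionality = "3D", needs_parameters = TRUE,
             atom_slots = c("A", "B"), common_slots = "kappa",
             bond_slots = character(), bond_required = FALSE,
             needs_bonds = FALSE, supports_cutoff_cover = TRUE,
             citation = "Mortier, Ghosh & Shankar (1986) J Am Chem Soc 108:4315"),
  sfkeem = list(id = "sfkeem", label = "SFKEEM",
                dimensionality = "3D", needs_parameters = TRUE,
                atom_slots = c("A", "B"), common_slots = "sigma",
                bond_slots = character(), bond_required = FALSE,
                needs_bonds = FALSE, supports_cutoff_cover = TRUE,
                citation = "Chaves et al. (2006) J Chem Inf Model 46:1657"),
  qeq = list(id = "qeq", label = "QEq",
             dimensionality = "3D", needs_parameters = TRUE,
             atom_slots = c("chi", "J", "radius"), common_slots = character(),
             bond_slots = character(), bond_required = FALSE,
             needs_bonds = FALSE, supports_cutoff_cover = TRUE,
             citation = "Rappe & Goddard (1991) J Phys Chem 95:3358"),
  eqeq = list(id = "eqeq", label = "EQeq",
              dimensionality = "3D", needs_parameters = TRUE,
              atom_slots = c("chi", "J"), common_slots = "lambda",
              bond_slots = character(), bond_required = FALSE,
              needs_bonds = FALSE, supports_cutoff_cover = TRUE,
              citation = "Wilmer, Kim & Snurr (2012) J Phys Chem Lett 3:2506"),
  eqeqc = list(id = "eqeqc", label = "EQeq+C",
               dimensionality = "3D", needs_parameters = TRUE,
               atom_slots = c("chi", "J"), common_slots = "lambda",
               bond_slots = "c", bond_required = FALSE,
               needs_bonds = TRUE, supports_cutoff_cover = TRUE,
               citation = "Martin-Noble et al. (2015) J Chem Theory Comput 11:3364"),
  gdac = list(id = "gdac", label = "GDAC",
              dimensionality = "3D", needs_parameters = TRUE,
              atom_slots = c("a", "b"), common_slots = character(),
              bond_slots = character(), bond_required = FALSE,
              needs_bonds = TRUE, supports_cutoff_cover = FALSE,
              citation = "Cho et al. (2001) J Phys Chem B 105:3624"),
  peoe = list(id = "peoe", label = "PEOE",
              dimensionality = "2D", needs_parameters = TRUE,
              atom_slots = c("a", "b", "c"), common_slots = character(),
              bond_slots = character(), bond_required = FALSE,
              needs_bonds = TRUE, supports_cutoff_cover = FALSE,
              citation = "Gasteiger & Marsili (1980) Tetrahedron 36:3219"),
  mgc = list(id = "mgc", label = "MGC",
             dimensionality = "2D", needs_parameters = FALSE,
             atom_slots = character(), common_slots = character(),
             bond_slots = character(), bond_required = FALSE,
             needs_bonds = TRUE, supports_cutoff_cover = FALSE,
             citation = "Sanderson-type geometric-mean equalization"),
  delre = list(id = "delre", label = "DelRe",
               dimensionality = "2D", needs_parameters = TRUE,
               atom_slots = "delta0", common_slots = character(),
               bond_slots = c("gamma1", "gamma2", "epsilon"),
               bond_required = TRUE,
               needs_bonds = TRUE, supports_cutoff_cover = FALSE,
               citation = "Del Re (1958) J Chem Soc 4031"),
  veem = list(id = "veem", label = "VEEM",
              dimensionality = "2D", needs_parameters = FALSE,
              atom_slots = character(), common_slots = character(),
              bond_slots = character(), bond_required = FALSE,
              needs_bonds = TRUE, supports_cutoff_cover = FALSE,
              citation = "valence-electron equalization over the bond graph"))

# Automatic-selection priority (most suited first), split by
# dimensionality of the input structures.
.priority_3d <- c("eem", "sfkeem", "qeq", "eqeq", "eqeqc", "gdac")
.priority_2d <- c("peoe", "mgc", "delre", "veem")

#' Describe an implemented charge method
#'
#' @param id method id, e.g. \code{"eem"}.
#' @return a list with fields \code{id}, \code{label},
#'   \code{dimensionality} ("2D"/"3D"), \code{needs_parameters},
#'   \code{atom_slots}, \code{common_slots}, \code{bond_slots},
#'   \code{needs_bonds}, \code{supports_cutoff_cover}, \code{citation}.
#' @export
method_descriptor <- function(id) {
  d <- .method_registry[[tolower(id)]]
  if (is.null(d)) {
    stop("unknown charge method '", id, "'; implemented methods: ",
         paste(names(.method_registry), collapse = ", "))
  }
  d
}

#' Table of implemented charge methods
#'
#' @return data frame with one row per method.
#' @export
method_registry <- function() {
  do.call(rbind, lapply(.method_registry, function(d) {
    data.frame(id = d$id, label = d$label, dimensionality = d$dimensionality,
               needs_parameters = d$needs_parameters,
               supports_cutoff_cover = d$supports_cutoff_cover,
               citation = d$citation)
  })) -> df
  rownames(df) <- NULL
  df
}

# Internal constructor shared by the JSON loader and the toy generator.
new_parameter_set <- function(id, method, citation, scheme, common, atom,
                              bond = NULL, source_file = NA_character_) {
  desc <- method_descriptor(method)
  if (!scheme %in% c("plain", "hbo", "hyb")) {
    stop("parameter set '", id, "': unknown scheme '", scheme, "'")
  }
  common <- if (length(common)) unlist(common) else stats::setNames(numeric(), character())
  missing_common <- setdiff(desc$common_slots, names(common))
  if (length(missing_common)) {
    stop("parameter set '", id, "' (method ", method,
         ") is missing required global slot(s): ",
         paste(missing_common, collapse = ", "))
  }
  if (anyDuplicated(names(atom))) {
    stop("parameter set '", id, "': duplicate atom-type key(s): ",
         paste(unique(names(atom)[duplicated(names(atom))]), collapse = ", "))
  }
  for (k in names(atom)) {
    v <- unlist(atom[[k]])
    missing_slots <- setdiff(desc$atom_slots, names(v))
    if (length(missing_slots)) {
      stop("parameter set '", id, "': atom type '", k,
           "' is missing slot(s): ", paste(missing_slots, collapse = ", "))
    }
    atom[[k]] <- v[desc$atom_slots]
  }
  if (!is.null(bond)) {
    if (anyDuplicated(names(bond))) {
      stop("parameter set '", id, "': duplicate bond-type key(s)")
    }
    bond <- lapply(bond, unlist)
  }
  structure(list(id = id, method = method, citation = citation,
                 scheme = scheme, common = common, atom = atom,
                 bond = bond, source_file = source_file),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set '%s' for %s: %d atom types (%s scheme)%s>\n",
              x$id, x$method, length(x$atom), x$scheme,
              if (length(x$bond)) sprintf(", %d bond types", length(x$bond)) else ""))
  cat("  citation:", x$citation, "\n")
  invisible(x)
}

#' Load a parameter set from its JSON file
#'
#' The on-disk dialect (\code{format_version} "1.0") is a JSON object
#' with fields \code{id}, \code{method}, \code{citation}, \code{scheme}
#' (\code{plain}/\code{hbo}/\code{hyb}), \code{common} (named globals,
#' e.g. \code{kappa}), \code{atom} (array of \code{{element, value,
#' params}}) and optional \code{bond} (array of \code{{elements: [e1,
#' e2], order, params}}).  Electronegativity-like slots are in eV,
#' hardness-like slots in eV per elementary charge and lengths in
#' Angstrom unless the set's own publication fixes a different scaling.
#'
#' @param path path to a JSON file.
#' @return a \code{parameter_set}.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("format_version", "id", "method", "scheme", "atom")) {
    if (is.null(js[[f]])) stop("parameter file ", basename(path),
                               ": missing required field '", f, "'")
  }
  atom <- list()
  for (e in js$atom) {
    key <- paste(e$element, if (is.null(e$value)) "*" else e$value, sep = "|")
    if (key %in% names(atom)) {
      stop("parameter file ", basename(path), ": duplicate atom-type key '",
           key, "'")
    }
    atom[[key]] <- unlist(e$params)
  }
  bond <- NULL
  if (!is.null(js$bond) && length(js$bond)) {
    bond <- list()
    for (e in js$bond) {
      key <- paste(e$elements[[1]], e$elements[[2]], e$order, sep = "|")
      if (key %in% names(bond)) {
        stop("parameter file ", basename(path), ": duplicate bond-type key '",
             key, "'")
      }
      bond[[key]] <- unlist(e$params)
    }
  }
  new_parameter_set(id = js$id, method = js$method,
                    citation = if (is.null(js$citation)) "" else js$citation,
                    scheme = js$scheme, common = js$common, atom = atom,
                    bond = bond, source_file = path)
}

#' The bundled parameter-set registry
#'
#' Scans the package's \code{parameters/} directory (plus any user
#' directories) for parameter JSON files.  Registry order is the
#' lexicographic filename order; bundled files carry numeric prefixes
#' that encode the preference order used to break ties during automatic
#' selection.
#'
#' @param extra_dirs additional directories to scan after the bundled one.
#' @return named list of \code{parameter_set} objects in registry order.
#' @export
parameter_registry <- function(extra_dirs = character()) {
  dirs <- c(system.file("parameters", package = "atomcharge"), extra_dirs)
  files <- unlist(lapply(dirs, function(d) {
    sort(list.files(d, pattern = "\\.json$", full.names = TRUE))
  }))
  sets <- lapply(files, load_parameter_set)
  names(sets) <- vapply(sets, `[[`, character(1), "id")
  sets
}

#' Check whether a parameter set covers a molecule
#'
#' A method can only run on a molecule whose every atom type (under the
#' set's classification scheme) has an entry in the set; methods that do
#' not need per-element parameters cover every molecule.
#'
#' @param ps a \code{parameter_set}, or \code{NULL} for a parameter-free
#'   method.
#' @param mol a \code{molecule}.
#' @return list with \code{ok} (logical) and \code{missing} (character
#'   vector of uncovered atom-type or bond-type keys).
#' @export
applicability <- function(ps, mol) {
  if (is.null(ps)) return(list(ok = TRUE, missing = character()))
  keys <- unique(classify_atom(mol, scheme = ps$scheme))
  missing <- setdiff(keys, names(ps$atom))
  desc <- method_descriptor(ps$method)
  if (desc$bond_required && nrow(mol$bonds)) {
    el <- mol$atoms$element
    bk <- unique(unlist(lapply(seq_len(nrow(mol$bonds)), function(r) {
      a <- el[mol$bonds$i[r]]; b <- el[mol$bonds$j[r]]; o <- mol$bonds$order[r]
      key1 <- paste(a, b, o, sep = "|"); key2 <- paste(b, a, o, sep = "|")
      if (key1 %in% names(ps$bond) || key2 %in% names(ps$bond)) NULL else key1
    })))
    missing <- c(missing, bk)
  }
  list(ok = length(missing) == 0, missing = missing)
}

# Methods structurally usable on a molecule (coordinates / bonds).
method_structurally_ok <- function(desc, mol) {
  if (desc$dimensionality == "3D" && !has_coordinates(mol)) return(FALSE)
  if (desc$needs_bonds && nrow(mol$bonds) == 0 && n_atoms(mol) > 1) return(FALSE)
  TRUE
}

#' Automatic method and parameter-set selection
#'
#' Mirrors a one-click setup: restrict to methods applicable to all
#' input molecules, prefer conformationally dependent (3D) methods in the
#' fixed priority order EEM, SFKEEM, QEq, EQeq, EQeq+C, GDAC when every
#' molecule has coordinates, otherwise the 2D order PEOE, MGC, DelRe,
#' VEEM; among a method's covering parameter sets pick the one with the
#' fewest surplus atom types (ties broken by registry order).  One
#' parameter set serves the whole batch: charges computed under
#' different sets are not comparable.
#'
#' @param mols list of \code{molecule} objects.
#' @param registry parameter registry (default: bundled).
#' @return list with \code{method} (descriptor) and \code{parameters}
#'   (a \code{parameter_set} or \code{NULL} for parameter-free methods).
#' @export
select_automatic <- function(mols, registry = parameter_registry()) {
  if (!length(mols)) stop("select_automatic needs at least one molecule")
  if (inherits(mols, "molecule")) mols <- list(mols)
  all3d <- all(vapply(mols, has_coordinates, logical(1)))
  order <- if (all3d) c(.priority_3d, .priority_2d) else .priority_2d
  for (mid in order) {
    desc <- method_descriptor(mid)
    if (!all(vapply(mols, function(m) method_structurally_ok(desc, m),
                    logical(1)))) next
    if (!desc$needs_parameters) {
      return(list(method = desc, parameters = NULL))
    }
    sets <- Filter(function(ps) ps$method == mid, registry)
    covering <- Filter(function(ps) {
      all(vapply(mols, function(m) applicability(ps, m)$ok, logical(1)))
    }, sets)
    if (!length(covering)) next
    used <- function(ps) {
      length(unique(unlist(lapply(mols, classify_atom, scheme = ps$scheme))))
    }
    surplus <- vapply(covering, function(ps) length(ps$atom) - used(ps),
                      numeric(1))
    return(list(method = desc, parameters = covering[[which.min(surplus)]]))
  }
  stop("no applicable charge method for the given molecules")
}

# Per-atom parameter matrix: one row per atom, one column per slot.
atom_parameter_matrix <- function(ps, mol) {
  desc <- method_descriptor(ps$method)
  keys <- classify_atom(mol, scheme = ps$scheme)
  miss <- setdiff(unique(keys), names(ps$atom))
  if (length(miss)) {
    stop("parameter set '", ps$id, "' does not cover atom type(s): ",
         paste(miss, collapse = ", "))
  }
  m <- do.call(rbind, ps$atom[keys])
  colnames(m) <- desc$atom_slots
  m
}

# Look up a per-bond parameter vector; orientation: 'swap' is TRUE when
# the stored key lists the bond's elements in (j, i) order.
bond_parameter_lookup <- function(ps, el_i, el_j, order) {
  if (is.null(ps$bond)) return(NULL)
  k1 <- paste(el_i, el_j, order, sep = "|")
  if (!is.null(ps$bond[[k1]])) return(list(params = ps$bond[[k1]], swap = FALSE))
  k2 <- paste(el_j, el_i, order, sep = "|")
  if (!is.null(ps$bond[[k2]])) return(list(params = ps$bond[[k2]], swap = TRUE))
  NULL
}
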