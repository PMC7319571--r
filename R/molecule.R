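# In-memory molecular model.  A molecule is a plain list with an atom
# table, a bond table and a total charge; indices are R-style 1-based
# (file formats are converted at the I/O boundary).

#' Construct a molecule
#'
#' The central input unit of the package: an ordered atom table, a bond
#' list and the total molecular charge Q that constrains every
#' charge-equalization scheme.
#'
#' @param name molecule identifier.
#' @param atoms data frame with columns \code{element} (symbol), \code{x},
#'   \code{y}, \code{z} (Angstrom; may be \code{NA} for 2D-only inputs),
#'   \code{formal_charge} (integer), and optionally \code{name},
#'   \code{resname}, \code{resid}, \code{chain} for polymer formats.
#' @param bonds data frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (1, 2 or 3), or \code{NULL} for no bonds.
#' @param total_charge optional integer overriding the sum of formal
#'   charges as the total charge Q.
#' @return an object of class \code{molecule}.
#' @export
#' @examples
#' water <- molecule("water",
#'   atoms = data.frame(element = c("O", "H", "H"),
#'                      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93),
#'                      z = 0, formal_charge = 0L),
#'   bonds = data.frame(i = c(1, 1), j = c(2, 3), order = 1L))
#' n_atoms(water)
molecule <- function(name, atoms, bonds = NULL, total_charge = NULL) {
  stopifnot(is.data.frame(atoms))
  nr <- nrow(atoms)
  for (col in c("x", "y", "z")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(NA_real_, nr)
  }
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- rep(0L, nr)
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$resname)) atoms$resname <- rep(NA_character_, nr)
  if (is.null(atoms$resid)) atoms$resid <- rep(NA_integer_, nr)
  if (is.null(atoms$chain)) atoms$chain <- rep(NA_character_, nr)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order))
  }
  mol <- structure(list(name = as.character(name), atoms = atoms,
                        bonds = bonds, total_charge = total_charge),
                   class = "molecule")
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  atoms <- mol$atoms
  bad <- !is_valid_element(atoms$element)
  if (any(bad)) {
    stop("invalid element symbol(s) at atom(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.na(xyz) & !is.finite(xyz))) {
    stop("non-finite coordinates in molecule '", mol$name, "'")
  }
  b <- mol$bonds
  if (nrow(b)) {
    n <- nrow(atoms)
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n)) {
      stop("bond indices out of range in molecule '", mol$name, "'")
    }
    if (any(b$i == b$j)) stop("self-bond in molecule '", mol$name, "'")
    if (!all(b$order %in% 1:3)) {
      stop("bond orders must be 1, 2 or 3 in molecule '", mol$name, "'")
    }
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) {
      stop("duplicate bond in molecule '", mol$name, "'")
    }
  }
  invisible(mol)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, %d bonds, Q = %+d%s>\n",
              x$name, n_atoms(x), nrow(x$bonds), total_formal_charge(x),
              if (has_coordinates(x)) "" else ", no 3D coordinates"))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a \code{molecule}.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Does the molecule carry 3D coordinates?
#' @param mol a \code{molecule}.
#' @return \code{TRUE} if every atom has finite x, y, z.
#' @export
has_coordinates <- function(mol) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  nrow(xyz) > 0 && !anyNA(xyz)
}

coords_matrix <- function(mol) {
  if (!has_coordinates(mol)) {
    miss <- which(apply(is.na(mol$atoms[, c("x", "y", "z")]), 1, any))
    stop("molecule '", mol$name, "' is missing coordinates for atom(s) ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Interatomic distance matrix
#'
#' Euclidean distances between all atom pairs, in Angstrom.  All
#' conformationally dependent charge methods consume this matrix.
#'
#' @param mol a \code{molecule} with coordinates.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
distance_matrix <- function(mol) {
  xyz <- coords_matrix(mol)
  as.matrix(stats::dist(xyz))
}

#' Total molecular charge
#'
#' Sum of atomic formal charges, unless an explicit total-charge override
#' was recorded on the molecule.  Supplies the constraint Q of the
#' electronegativity-equalization linear systems.
#'
#' @param mol a \code{molecule}.
#' @return integer total charge.
#' @export
total_formal_charge <- function(mol) {
  if (!is.null(mol$total_charge)) return(as.integer(mol$total_charge))
  as.integer(round(sum(mol$atoms$formal_charge)))
}

# Adjacency list: for each atom, data frame of (neighbor, order).
bond_neighbors <- function(mol) {
  n <- n_atoms(mol)
  nb <- rep(list(data.frame(j = integer(), order = integer())), n)
  b <- mol$bonds
  if (!nrow(b)) return(nb)
  edges <- data.frame(i = c(b$i, b$j), j = c(b$j, b$i),
                      order = c(b$order, b$order))
  sp <- split(edges[, c("j", "order")], factor(edges$i, levels = seq_len(n)))
  nb[] <- sp
  nb
}

#' Classify an atom for parameter lookup
#'
#' Parameter sets key their per-atom values by an (element, scheme, value)
#' triple.  Three classifier schemes are supported: \code{plain} (element
#' only), \code{hbo} (highest incident bond order, "1" for isolated
#' atoms) and \code{hyb} (hybridisation from bond orders: any triple bond
#' or two double bonds gives "sp", one double bond "sp2", otherwise
#' "sp3").
#'
#' @param mol a \code{molecule}.
#' @param idx atom index (1-based); omit to classify every atom.
#' @param scheme one of \code{"plain"}, \code{"hbo"}, \code{"hyb"}.
#' @return a character vector of type keys of the form
#'   \code{"element|value"}, e.g. \code{"C|2"} for a carbonyl carbon under
#'   \code{hbo}.
#' @export
classify_atom <- function(mol, idx = NULL, scheme = "plain") {
  if (!scheme %in% c("plain", "hbo", "hyb")) {
    stop("unknown atom-classification scheme: ", scheme)
  }
  el <- mol$atoms$element
  n <- length(el)
  if (n == 0) return(character(0))
  if (scheme == "plain") {
    keys <- paste(el, "*", sep = "|")
  } else {
    maxord <- integer(n)
    ndouble <- integer(n)
    b <- mol$bonds
    if (nrow(b)) {
      for (r in seq_len(nrow(b))) {
        i <- b$i[r]; j <- b$j[r]; o <- b$order[r]
        if (o > maxord[i]) maxord[i] <- o
        if (o > maxord[j]) maxord[j] <- o
        if (o == 2L) { ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L }
      }
    }
    if (scheme == "hbo") {
      val <- as.character(pmax(maxord, 1L))
    } else {
      val <- ifelse(maxord == 3L | ndouble >= 2L, "sp",
                    ifelse(ndouble == 1L, "sp2", "sp3"))
    }
    keys <- paste(el, val, sep = "|")
  }
  if (is.null(idx)) keys else keys[idx]
}

#' Topological symmetry orbits
#'
#' Partitions the atoms into classes of topologically equivalent atoms by
#' iterative Morgan-style neighbourhood-label refinement: atoms start
#' labelled by (element, formal charge) and are repeatedly relabelled by
#' the sorted multiset of (bond order, neighbour label) pairs until the
#' partition stabilises.  Atoms in one orbit must receive identical
#' charges from every charge method, which makes the orbits a convenient
#' correctness probe.
#'
#' @param mol a \code{molecule} with bonds.
#' @return list of integer vectors, one per orbit; their union is
#'   \code{1:n_atoms(mol)}.
#' @export
#' @examples
#' # methane: one carbon orbit, one orbit with all four hydrogens
#' ch4 <- make_fixture("methane")
#' symmetry_orbits(ch4)
symmetry_orbits <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(list())
  nb <- bond_neighbors(mol)
  lab <- match(paste(mol$atoms$element, mol$atoms$formal_charge),
               unique(paste(mol$atoms$element, mol$atoms$formal_charge)))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      e <- nb[[i]]
      if (!nrow(e)) return(paste0(lab[i], "!"))
      parts <- sort(paste0(e$order, ":", lab[e$j]))
      paste0(lab[i], "!", paste(parts, collapse = ","))
    }, character(1))
    new <- match(sig, unique(sig))
    if (identical(as.integer(new), as.integer(lab))) break
    lab <- new
  }
  unname(split(seq_len(n), lab))
}

# Apply a permutation to atom order (perm[k] = old index placed at k).
permute_molecule <- function(mol, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  if (nrow(b)) { b$i <- inv[b$i]; b$j <- inv[b$j] }
  molecule(mol$name, atoms, b, mol$total_charge)
}
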