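# Deterministic generators of synthetic molecules and toy parameter
# sets.  Every charge method and solver strategy in the package can be
# exercised end-to-end with these, without any external structure files.

# Minimal Lehmer pseudo-random stream: a single integer seed drives a
# private generator, so fixture construction never touches R's global
# random state.
lehmer_stream <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483646L) + 1L)
  function(n, min = 0, max = 1) {
    out <- numeric(n)
    for (k in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[k] <- state / 2147483647
    }
    min + out * (max - min)
  }
}

#' Generate a synthetic test molecule
#'
#' Deterministic construction of simple geometries: the same arguments
#' always give bitwise-identical molecules.  Kinds that promise symmetry
#' (\code{methane}, \code{diatomic}) use exactly symmetric coordinates.
#'
#' @param kind one of \code{"diatomic"}, \code{"methane"},
#'   \code{"phenol_like"}, \code{"chain"}, \code{"helix"},
#'   \code{"random_polymer"}.
#' @param n_atoms atom count for \code{chain}, \code{helix} and
#'   \code{random_polymer}; the kinds scale to 1e5+ atoms for strategy
#'   routing tests.
#' @param elements element palette cycled (chain/helix) or sampled
#'   (random_polymer) along the backbone; pass a full-length vector for
#'   explicit per-atom assignment.
#' @param seed integer seed for \code{random_polymer} and for
#'   \code{shuffle_elements}.
#' @param shuffle_elements sample the palette pseudo-randomly (driven by
#'   \code{seed}) instead of cycling it; an exactly periodic composition
#'   can alias with distance windows in solver studies.
#' @param bond_length backbone spacing in Angstrom (chain).
#' @param rise,turn helix rise (Angstrom) and turn (degrees) per atom.
#' @param charge total molecular charge (assigned to the first atom as a
#'   formal charge when nonzero).
#' @return a \code{molecule}.
#' @export
#' @examples
#' make_fixture("methane")
#' make_fixture("helix", n_atoms = 50)
make_fixture <- function(kind = c("diatomic", "methane", "phenol_like",
                                  "chain", "helix", "random_polymer"),
                         n_atoms = 10, elements = c("C", "N"), seed = 1,
                         bond_length = 1.5, rise = 1.5, turn = 100,
                         charge = 0, shuffle_elements = FALSE) {
  kind <- match.arg(kind)
  pick_elements <- function(n) {
    if (shuffle_elements && length(elements) > 1) {
      rng <- lehmer_stream(seed + 101)
      elements[ceiling(rng(n, 0, 1) * length(elements))]
    } else rep_len(elements, n)
  }
  chainify <- function(xyz, el) {
    n <- nrow(xyz)
    fc <- integer(n); fc[1] <- as.integer(charge)
    molecule(paste0(kind, "_", n),
             data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], formal_charge = fc),
             if (n > 1) data.frame(i = 1:(n - 1), j = 2:n, order = 1L))
  }
  switch(kind,
    diatomic = {
      el <- rep_len(elements, 2)
      molecule("diatomic",
               data.frame(element = el, x = 0, y = 0,
                          z = c(0, bond_length),
                          formal_charge = c(as.integer(charge), 0L)),
               data.frame(i = 1, j = 2, order = 1L))
    },
    methane = {
      d <- 1.09 / sqrt(3)
      molecule("methane",
               data.frame(element = c("C", "H", "H", "H", "H"),
                          x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d),
                          z = c(0, d, -d, -d, d), formal_charge = 0L),
               data.frame(i = 1, j = 2:5, order = 1L))
    },
    phenol_like = {
      # exact hexagon, para H's mirror-symmetric; OH in the ring plane
      ang <- (0:5) * pi / 3
      rc <- 1.39
      ring <- cbind(rc * cos(ang), rc * sin(ang), 0)
      hpos <- cbind((rc + 1.09) * cos(ang[-1]), (rc + 1.09) * sin(ang[-1]), 0)
      o <- c(rc + 1.36, 0, 0)
      h_o <- c(rc + 1.36 + 0.6, 0.78, 0)
      xyz <- rbind(ring, o, h_o, hpos)
      el <- c(rep("C", 6), "O", "H", rep("H", 5))
      bonds <- data.frame(
        i = c(1:6, 1, 7, 2:6),
        j = c(2:6, 1, 7, 8, 9:13),
        order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, rep(1L, 5)))
      molecule("phenol_like",
               data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], formal_charge = 0L), bonds)
    },
    chain = {
      i <- seq_len(n_atoms) - 1
      xyz <- cbind(i * bond_length, 0, 0)
      chainify(xyz, pick_elements(n_atoms))
    },
    helix = {
      i <- seq_len(n_atoms) - 1
      th <- i * turn * pi / 180
      xyz <- cbind(2.3 * cos(th), 2.3 * sin(th), i * rise)
      chainify(xyz, pick_elements(n_atoms))
    },
    random_polymer = {
      rng <- lehmer_stream(seed)
      xyz <- matrix(0, n_atoms, 3)
      for (k in seq_len(n_atoms - 1) + 1) {
        # random direction biased forward so the walk self-avoids loosely
        v <- c(rng(1, -1, 1), rng(1, -1, 1), rng(1, 0.5, 1))
        v <- v / sqrt(sum(v^2))
        len <- rng(1, 1.2, 1.6)
        xyz[k, ] <- xyz[k - 1, ] + v * len
      }
      el <- elements[ceiling(rng(n_atoms, 0, 1) * length(elements))]
      chainify(xyz, el)
    })
}

#' Generate a full-coverage toy parameter set
#'
#' Produces a plain-scheme parameter set for one method that covers the
#' given elements, with hardness-like slots bounded away from zero so the
#' equalization systems stay well conditioned.  Reproducible from the
#' seed; different seeds give different values under the same schema.
#' Parameter-free methods (\code{mgc}, \code{veem}) return \code{NULL}.
#'
#' @param method method id (see \code{method_registry()}).
#' @param elements element symbols to cover.
#' @param seed integer seed.
#' @return a \code{parameter_set}, or \code{NULL} for parameter-free
#'   methods.
#' @export
#' @examples
#' make_toy_parameters("eem", c("C", "H", "O"))
make_toy_parameters <- function(method, elements, seed = 1) {
  desc <- method_descriptor(method)
  if (!desc$needs_parameters) return(NULL)
  rng <- lehmer_stream(seed + 7 * match(method, names(.method_registry)))
  ne <- length(elements)
  draw <- function(min, max) round(rng(ne, min, max), 4)
  atom <- switch(method,
    peoe = list(a = draw(6, 16), b = draw(6, 12), c = draw(0.5, 2)),
    gdac = list(a = draw(2, 10), b = draw(6, 14)),
    delre = list(delta0 = draw(0, 0.5)),
    eem = list(A = draw(2, 3.5), B = draw(0.5, 1.5)),
    sfkeem = list(A = draw(2, 3.5), B = draw(0.5, 1.5)),
    # J above the worst bond-distance Coulomb coupling (~8 eV/e at
    # 1.1 A with 0.9 A Gaussian widths) keeps the system positive
    # definite, per this generator's safety contract
    qeq = list(chi = draw(3, 9), J = draw(12, 16), radius = draw(0.9, 1.3)),
    eqeq = list(chi = draw(3, 9), J = draw(8, 15)),
    eqeqc = list(chi = draw(3, 9), J = draw(8, 15)),
    stop("no toy parameter recipe for method: ", method))
  atom_map <- lapply(seq_len(ne), function(k) {
    vapply(atom, `[`, numeric(1), k)
  })
  names(atom_map) <- paste(elements, "*", sep = "|")
  common <- switch(method,
    eem = c(kappa = round(rng(1, 0.2, 0.5), 4)),
    sfkeem = c(sigma = round(rng(1, 0.3, 0.8), 4)),
    eqeq = c(lambda = 1.2),
    eqeqc = c(lambda = 1.2),
    NULL)
  bond_map <- NULL
  if (length(desc$bond_slots)) {
    pairs <- expand.grid(a = elements, b = elements, o = 1:3,
                         stringsAsFactors = FALSE)
    bond_map <- lapply(seq_len(nrow(pairs)), function(r) {
      same <- pairs$a[r] == pairs$b[r]
      if (method == "delre") {
        c(gamma1 = if (same) 0.15 else round(rng(1, 0.05, 0.3), 4),
          gamma2 = if (same) 0.15 else round(rng(1, 0.05, 0.3), 4),
          epsilon = round(rng(1, 0.5, 1.5), 4))
      } else { # eqeqc correction slot; zero for same-element bonds
        c(c = if (same) 0 else round(rng(1, -0.02, 0.02), 4))
      }
    })
    names(bond_map) <- paste(pairs$a, pairs$b, pairs$o, sep = "|")
  }
  new_parameter_set(
    id = sprintf("toy-%s-seed%d", method, as.integer(seed)),
    method = method,
    citation = "synthetic toy parameters (package fixture generator)",
    scheme = "plain", common = common, atom = atom_map, bond = bond_map)
}
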