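# Conformationally independent (2D) charge methods: they see only the
# bond graph, never coordinates.

# Shared result constructor ------------------------------------------------

new_charge_result <- function(mol, method, ps, strategy, charges,
                              chibar = NA_real_, converged = TRUE,
                              iterations = NA_integer_,
                              warnings = character()) {
  structure(list(molecule = mol$name, method = method,
                 parameter_set = if (is.null(ps)) "none" else ps$id,
                 strategy = strategy,
                 charges = stats::setNames(as.numeric(charges),
                                           mol$atoms$name),
                 chibar = chibar, converged = converged,
                 iterations = iterations, warnings = warnings,
                 n_atoms = n_atoms(mol)),
            class = "charge_result")
}

# PEOE ---------------------------------------------------------------------

# Electronegativity of the hydrogen cation in the original scheme; used
# as H's transfer denominator instead of a + b + c.
.peoe_h_cation <- 20.02

# Shared engine for PEOE and GDAC: per-cycle pairwise charge transfer
# along bonds with a per-bond damping factor damp(bond)^k.
peoe_engine <- function(mol, abc, damp, tol, max_iter, method, ps,
                        h_special = TRUE) {
  n <- n_atoms(mol)
  q <- as.numeric(mol$atoms$formal_charge)
  if (n == 1 || nrow(mol$bonds) == 0) {
    return(new_charge_result(mol, method, ps, "iterative", q,
                             iterations = 0L))
  }
  a <- abc[, 1]; b <- abc[, 2]
  cc <- if (ncol(abc) >= 3) abc[, 3] else rep(0, n)
  chiplus <- a + b + cc
  if (h_special) chiplus[mol$atoms$element == "H"] <- .peoe_h_cation
  bi <- mol$bonds$i; bj <- mol$bonds$j
  converged <- FALSE
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    chi <- a + b * q + cc * q^2
    dq <- numeric(n)
    fk <- damp^k
    for (r in seq_along(bi)) {
      i <- bi[r]; j <- bj[r]
      if (chi[i] == chi[j]) next
      # positive charge flows to the less electronegative atom, scaled
      # by the cation electronegativity of that atom
      if (chi[j] > chi[i]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
      d <- (chi[hi] - chi[lo]) / chiplus[lo] * fk[r]
      dq[lo] <- dq[lo] + d
      dq[hi] <- dq[hi] - d
    }
    q <- q + dq
    if (max(abs(dq)) < tol) { converged <- TRUE; break }
  }
  w <- if (converged) character() else
    sprintf("did not converge in %d cycles (last max |dq| = %.2e)",
            max_iter, max(abs(dq)))
  if (length(w)) warning("peoe-type iteration: ", w)
  new_charge_result(mol, method, ps, "iterative", q, converged = converged,
                    iterations = k, warnings = w)
}

#' PEOE (Gasteiger-Marsili) charges
#'
#' Partial equalization of orbital electronegativity: each atom carries a
#' charge-dependent electronegativity chi(q) = a + b q + c q^2; every
#' cycle k, each bond transfers (chi_hi - chi_lo) / chi+_lo * (1/2)^k of
#' positive charge to its less electronegative end, where chi+ is the
#' cation electronegativity a + b + c of that end (20.02 for hydrogen, as
#' in the original scheme).  Transfers are pairwise antisymmetric, so the
#' total charge is conserved exactly.
#'
#' @param mol a \code{molecule} with bonds.
#' @param ps a \code{parameter_set} for method \code{"peoe"} with atom
#'   slots \code{a}, \code{b}, \code{c} (eV-scale polynomial
#'   coefficients).
#' @param tol convergence threshold on the per-cycle charge change, in e.
#' @param max_iter maximum number of cycles.
#' @return a \code{charge_result}.
#' @export
peoe_charges <- function(mol, ps, tol = 1e-6, max_iter = 100) {
  abc <- atom_parameter_matrix(ps, mol)
  damp <- rep(0.5, nrow(mol$bonds))
  peoe_engine(mol, abc, damp, tol, max_iter, "peoe", ps)
}

# MGC ----------------------------------------------------------------------

#' MGC (geometric-mean electronegativity equalization) charges
#'
#' Sanderson-style equalization over the bond graph: within each
#' connected component the equalized molecular electronegativity is the
#' geometric mean of the atomic (Pauling-scale) values, and each atom's
#' raw charge is the deviation of its electronegativity from that mean,
#' normalized by 2.08 sqrt(chi) (the Sanderson charge-response scale).
#' The residual of the total-charge constraint is distributed uniformly,
#' which keeps topologically equivalent atoms at identical charges.
#'
#' @param mol a \code{molecule} with bonds.
#' @param en optional named electronegativity table overriding the
#'   bundled Pauling values.
#' @return a \code{charge_result}.
#' @export
mgc_charges <- function(mol, en = NULL) {
  n <- n_atoms(mol)
  chi <- if (is.null(en)) pauling_electronegativity(mol$atoms$element)
         else unname(en[mol$atoms$element])
  comp <- graph_components(mol)
  q <- numeric(n)
  for (idx in comp) {
    gm <- exp(mean(log(chi[idx])))
    raw <- (gm - chi[idx]) / (2.08 * sqrt(chi[idx]))
    qc <- sum(mol$atoms$formal_charge[idx])
    if (!is.null(mol$total_charge) && length(comp) == 1) {
      qc <- total_formal_charge(mol)
    }
    q[idx] <- raw + (qc - sum(raw)) / length(idx)
  }
  new_charge_result(mol, "mgc", NULL, "iterative", q)
}

# Connected components of the bond graph (list of index vectors).
graph_components <- function(mol) {
  n <- n_atoms(mol)
  nb <- bond_neighbors(mol)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; seen[s] <- TRUE; members <- integer()
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      members <- c(members, v)
      for (w in nb[[v]]$j) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# VEEM ---------------------------------------------------------------------

#' VEEM (valence-electron equalization) charges
#'
#' Parameter-free closed form on the bond graph: each bond of order m
#' holds 2m electrons that split between its two atoms in proportion to
#' their valence-electron counts, so atom i picks up
#' m (v_j - v_i) / (v_i + v_j) of positive charge per bond to j; formal
#' charges are kept as a baseline, which makes the result sum exactly to
#' the total molecular charge.
#'
#' @param mol a \code{molecule} with bonds and orders.
#' @return a \code{charge_result}.
#' @export
veem_charges <- function(mol) {
  v <- valence_electron_count(mol$atoms$element)
  q <- as.numeric(mol$atoms$formal_charge)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]; m <- b$order[r]
    d <- m * (v[j] - v[i]) / (v[i] + v[j])
    q[i] <- q[i] + d
    q[j] <- q[j] - d
  }
  new_charge_result(mol, "veem", NULL, "iterative", q)
}

# Del Re -------------------------------------------------------------------

#' Del Re charges
#'
#' Solves the inductive-parameter linear system delta_i = delta0_i +
#' sum over bonded j of gamma_ij delta_j, then converts each bond to a
#' charge transfer q_ij = (delta_j - delta_i) / (2 epsilon_ij); an atom's
#' charge is the sum over its incident bonds (plus its formal charge),
#' so bond transfers are antisymmetric and neutral inputs stay neutral.
#' Disconnected components are solved independently.
#'
#' @param mol a \code{molecule} with bonds.
#' @param ps a \code{parameter_set} for method \code{"delre"} with atom
#'   slot \code{delta0} and bond slots \code{gamma1}, \code{gamma2},
#'   \code{epsilon} (gamma1 acts on the first element of the stored bond
#'   key).
#' @return a \code{charge_result}.
#' @export
delre_charges <- function(mol, ps) {
  n <- n_atoms(mol)
  ap <- atom_parameter_matrix(ps, mol)
  delta0 <- ap[, "delta0"]
  el <- mol$atoms$element
  b <- mol$bonds
  gam <- matrix(0, n, n)
  eps <- matrix(NA_real_, n, n)
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    bp <- bond_parameter_lookup(ps, el[i], el[j], b$order[r])
    if (is.null(bp)) {
      stop("parameter set '", ps$id, "' has no bond parameters for ",
           el[i], "-", el[j], " (order ", b$order[r], ")")
    }
    g_i <- if (bp$swap) bp$params[["gamma2"]] else bp$params[["gamma1"]]
    g_j <- if (bp$swap) bp$params[["gamma1"]] else bp$params[["gamma2"]]
    gam[i, j] <- g_i   # delta_i responds to delta_j with gamma_i(j)
    gam[j, i] <- g_j
    eps[i, j] <- eps[j, i] <- bp$params[["epsilon"]]
  }
  q <- as.numeric(mol$atoms$formal_charge)
  for (idx in graph_components(mol)) {
    m <- diag(length(idx)) - gam[idx, idx, drop = FALSE]
    if (abs(det(m)) < 1e-12) {
      stop("Del Re system singular for component containing atom ", idx[1])
    }
    delta <- solve(m, delta0[idx])
    full <- numeric(n); full[idx] <- delta
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      if (!(i %in% idx)) next
      tq <- (full[j] - full[i]) / (2 * eps[i, j])
      q[i] <- q[i] + tq
      q[j] <- q[j] - tq
    }
  }
  new_charge_result(mol, "delre", ps, "full", q)
}
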