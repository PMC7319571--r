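# Conformationally dependent (3D) methods.  EEM, SFKEEM, QEq, EQeq and
# EQeq+C share one constrained linear system
#
#   diag_i q_i + sum_{j != i} off(i, j, R_ij) q_j - chibar = rhs_i
#   sum_i q_i = Q
#
# with N + 1 unknowns (the charges plus the equalized molecular
# electronegativity chibar, kept explicit as the last unknown).  GDAC is
# iterative (PEOE-style transfer with geometry-dependent damping).

# Kernels ------------------------------------------------------------------

# A kernel bundles the method-specific matrix entries.  Pi / Pj are
# per-atom parameter matrices for the row and column atoms
# (atom_parameter_matrix); D the (rectangular) distance block in
# Angstrom.  offdiag() must be symmetric in its two atom arguments;
# diag_override lets the QEq outer loop inject charge-dependent
# hardnesses.

make_kernel <- function(method, ps) {
  common <- ps$common
  switch(method,
    eem = list(
      id = "eem",
      diag = function(P) P[, "B"],
      offdiag = function(Pi, Pj, D) common[["kappa"]] / D,
      rhs = function(P) -P[, "A"]),
    sfkeem = list(
      id = "sfkeem",
      diag = function(P) 2 * P[, "B"],
      offdiag = function(Pi, Pj, D) {
        2 * sqrt(outer(Pi[, "B"], Pj[, "B"])) / cosh(common[["sigma"]] * D)
      },
      rhs = function(P) -P[, "A"]),
    qeq = list(
      id = "qeq",
      diag = function(P) P[, "J"],
      offdiag = function(Pi, Pj, D) {
        # Coulomb interaction of spherical Gaussian charge clouds of
        # width 'radius'; tends to k_e / R at large separation
        s2 <- outer(Pi[, "radius"]^2, Pj[, "radius"]^2, "+")
        .k_coulomb * erf_(D / sqrt(2 * s2)) / D
      },
      rhs = function(P) -P[, "chi"]),
    eqeq = ,
    eqeqc = list(
      id = method,
      diag = function(P) P[, "J"],
      offdiag = function(Pi, Pj, D) {
        # orbital-overlap screened Coulomb: exact k_e/R tail, finite at
        # contact; a_ij couples the pair hardnesses to an overlap length
        lam <- common[["lambda"]]
        a <- sqrt(outer(Pi[, "J"], Pj[, "J"])) / .k_coulomb
        lam * .k_coulomb *
          (1 / D + exp(-(a * D)^2) * (2 * a / sqrt(pi) - a^2 * D - 1 / D))
      },
      rhs = function(P) -P[, "chi"]),
    stop("no equalization kernel for method: ", method))
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# System assembly and solving ----------------------------------------------

#' Build the equalization linear system
#'
#' Assembles the (N+1) x (N+1) matrix and right-hand side of an
#' electronegativity-equalization method: the N x N charge block from
#' the method kernel (symmetric), a -1 column for the equalized
#' electronegativity unknown, and the total-charge constraint row
#' (1, ..., 1, 0) with right-hand side Q.
#'
#' @param mol a \code{molecule} with coordinates.
#' @param ps a \code{parameter_set} for the method.
#' @param kernel a kernel as built by the method wrappers; defaults to
#'   the kernel of \code{ps$method}.
#' @param diag_override optional numeric vector replacing the diagonal
#'   (used by the QEq self-consistency loop).
#' @return list with \code{matrix}, \code{rhs}, \code{n}.
#' @export
build_system <- function(mol, ps, kernel = make_kernel(ps$method, ps),
                         diag_override = NULL) {
  n <- n_atoms(mol)
  P <- atom_parameter_matrix(ps, mol)
  Q <- total_formal_charge(mol)
  M <- matrix(0, n + 1, n + 1)
  if (n > 1) {
    D <- distance_matrix(mol)
    too_close <- which(D < 1e-4 & upper.tri(D), arr.ind = TRUE)
    if (nrow(too_close)) {
      stop(sprintf("coincident atoms %d and %d (R = %.2e A) in molecule '%s'",
                   too_close[1, 1], too_close[1, 2],
                   D[too_close[1, 1], too_close[1, 2]], mol$name))
    }
    off <- kernel$offdiag(P, P, D)
    M[1:n, 1:n] <- off
  }
  dg <- if (is.null(diag_override)) kernel$diag(P) else diag_override
  diag(M)[1:n] <- dg
  M[1:n, n + 1] <- -1
  M[n + 1, 1:n] <- 1
  list(matrix = M, rhs = c(unname(kernel$rhs(P)), Q), n = n)
}

#' Solve an equalization system exactly
#'
#' Dense LAPACK solve of the (N+1) system with a condition check and a
#' residual guarantee (infinity norm below 1e-8).
#'
#' @param sys system from \code{\link{build_system}}.
#' @return list with \code{q} (charges), \code{chibar} and
#'   \code{residual}.
#' @export
solve_equalization <- function(sys) {
  rc <- rcond(sys$matrix)
  if (!is.finite(rc) || rc < 1e-12) {
    stop(sprintf("equalization system is singular or ill-conditioned (rcond = %.2e)", rc))
  }
  x <- solve(sys$matrix, sys$rhs)
  res <- max(abs(sys$matrix %*% x - sys$rhs))
  if (res > 1e-8) {
    stop(sprintf("equalization solve residual too large (%.2e)", res))
  }
  list(q = x[seq_len(sys$n)], chibar = x[sys$n + 1], residual = res)
}

# Per-atom effective electronegativity implied by a charge vector; at
# the solution all entries equal chibar.
effective_electronegativity <- function(mol, ps, q,
                                        kernel = make_kernel(ps$method, ps),
                                        diag_override = NULL) {
  n <- n_atoms(mol)
  P <- atom_parameter_matrix(ps, mol)
  dg <- if (is.null(diag_override)) kernel$diag(P) else diag_override
  chi <- dg * q - kernel$rhs(P)
  if (n > 1) {
    off <- kernel$offdiag(P, P, distance_matrix(mol))
    diag(off) <- 0
    chi <- chi + as.numeric(off %*% q)
  }
  chi
}

# Strategy dispatch shared by the equalization wrappers.
equalization_charges <- function(mol, ps, method, strategy = "auto",
                                 radius = 12, diag_override = NULL) {
  kernel <- make_kernel(method, ps)
  strat <- route_strategy(n_atoms(mol), strategy, radius)
  if (strat$kind == "full") {
    sys <- build_system(mol, ps, kernel, diag_override)
    sol <- solve_equalization(sys)
    q <- sol$q; chibar <- sol$chibar
  } else {
    q <- local_solve(mol, ps, kernel, strat, diag_override)
    chibar <- NA_real_
  }
  list(q = q, chibar = chibar, strategy = strat$kind)
}

# Method wrappers ----------------------------------------------------------

#' EEM charges
#'
#' Electronegativity equalization method: atom i obeys
#' A_i + B_i q_i + sum_{j != i} kappa q_j / R_ij = chibar under the
#' constraint sum q_i = Q, with per-type electronegativity A, hardness B
#' and the global Coulomb scaling kappa.  At the solution every atom's
#' effective electronegativity equals the molecular chibar.
#'
#' @param mol a \code{molecule} with coordinates.
#' @param ps a \code{parameter_set} for method \code{"eem"}.
#' @param strategy \code{"auto"} (route by atom count: full below
#'   20 000 atoms, cutoff up to 80 000, cover beyond), or an explicit
#'   \code{"full"}, \code{"cutoff"}, \code{"cover"}.
#' @param radius local-subsystem radius in Angstrom for the cutoff and
#'   cover strategies.
#' @return a \code{charge_result}.
#' @export
eem_charges <- function(mol, ps, strategy = "auto", radius = 12) {
  r <- equalization_charges(mol, ps, "eem", strategy, radius)
  new_charge_result(mol, "eem", ps, r$strategy, r$q, chibar = r$chibar)
}

#' SFKEEM charges
#'
#' Sigmoidal-function kernel variant of EEM: diagonal 2 B_i and
#' off-diagonal 2 sqrt(B_i B_j) sech(sigma R_ij), so the coupling decays
#' smoothly with distance under the global softness sigma.
#'
#' @inheritParams eem_charges
#' @param ps a \code{parameter_set} for method \code{"sfkeem"}.
#' @return a \code{charge_result}.
#' @export
sfkeem_charges <- function(mol, ps, strategy = "auto", radius = 12) {
  r <- equalization_charges(mol, ps, "sfkeem", strategy, radius)
  new_charge_result(mol, "sfkeem", ps, r$strategy, r$q, chibar = r$chibar)
}

#' QEq charges
#'
#' Charge equilibration: per-type electronegativity chi and
#' idempotential J with a Gaussian-shielded Coulomb off-diagonal that
#' recovers k_e / R at large separation.  Hydrogen's hardness is
#' charge-dependent, J_H(q) = J_H (1 + q_H), so the system is re-solved
#' in a damped fixed-point loop (mixing 0.5) until hydrogen charges are
#' self-consistent; molecules without hydrogen converge in one pass.
#'
#' @inheritParams eem_charges
#' @param ps a \code{parameter_set} for method \code{"qeq"} with atom
#'   slots \code{chi} (eV), \code{J} (eV/e) and \code{radius} (Angstrom).
#' @param tol self-consistency threshold on hydrogen charges, in e.
#' @param max_iter maximum outer iterations.
#' @return a \code{charge_result}.
#' @export
qeq_charges <- function(mol, ps, strategy = "auto", radius = 12,
                        tol = 1e-6, max_iter = 200) {
  P <- atom_parameter_matrix(ps, mol)
  J0 <- P[, "J"]
  hyd <- mol$atoms$element == "H"
  q <- numeric(n_atoms(mol))
  converged <- FALSE
  it <- 0L
  last <- NULL
  dg <- J0
  mix <- 0.5
  delta_prev <- Inf
  repeat {
    it <- it + 1L
    dg <- J0
    # hardness grows as the proton is stripped of density; the
    # correction is one-sided (positive charging only): extrapolating
    # the linear softening to anionic hydrogen has no stable solution
    dg[hyd] <- J0[hyd] * pmin(1 + pmax(q[hyd], 0), 3)
    last <- equalization_charges(mol, ps, "qeq", strategy, radius,
                                 diag_override = dg)
    if (!any(hyd)) { q <- last$q; converged <- TRUE; break }
    delta <- max(abs(last$q - q))
    if (delta < tol) {
      # keep the exact solution of the final linear system so the
      # equalization certificate holds to solver precision
      q <- last$q
      converged <- TRUE
      break
    }
    # adaptive damping: shrink the mixing factor whenever the update
    # grows, so oscillating or diverging trajectories are pulled back
    if (delta > delta_prev) mix <- max(mix / 2, 0.02)
    delta_prev <- delta
    q <- q + mix * (last$q - q)
    if (it >= max_iter) break
  }
  w <- if (converged) character() else
    sprintf("QEq hydrogen self-consistency not reached in %d iterations", max_iter)
  if (length(w)) warning(w)
  out <- new_charge_result(mol, "qeq", ps, last$strategy, q,
                           chibar = last$chibar, converged = converged,
                           iterations = it, warnings = w)
  attr(out, "diag_used") <- dg
  out
}

#' EQeq charges
#'
#' Extended charge equilibration: chi = (IP + EA) / 2 and hardness
#' J = IP - EA from experimental ionization data, with an
#' orbital-overlap screened Coulomb off-diagonal (exact k_e / R tail,
#' finite at contact) scaled by the global lambda.
#'
#' @inheritParams eem_charges
#' @param ps a \code{parameter_set} for method \code{"eqeq"}.
#' @return a \code{charge_result}.
#' @export
eqeq_charges <- function(mol, ps, strategy = "auto", radius = 12) {
  r <- equalization_charges(mol, ps, "eqeq", strategy, radius)
  new_charge_result(mol, "eqeq", ps, r$strategy, r$q, chibar = r$chibar)
}

#' EQeq+C charges
#'
#' EQeq charges plus an additive bond-order-dependent correction: each
#' bond moves the per-bond correction parameter c from its second atom
#' to its first (as ordered in the stored bond key), which preserves the
#' total charge exactly.  With all correction slots zero the result is
#' identical to EQeq.
#'
#' @inheritParams eem_charges
#' @param ps a \code{parameter_set} for method \code{"eqeqc"} with
#'   optional per-bond slot \code{c} (missing bond types contribute no
#'   correction).
#' @return a \code{charge_result}.
#' @export
eqeqc_charges <- function(mol, ps, strategy = "auto", radius = 12) {
  if (nrow(mol$bonds) == 0 && n_atoms(mol) > 1) {
    stop("EQeq+C needs bond information for its correction term; ",
         "molecule '", mol$name, "' has no bonds")
  }
  r <- equalization_charges(mol, ps, "eqeqc", strategy, radius)
  q <- r$q
  el <- mol$atoms$element
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    bp <- bond_parameter_lookup(ps, el[b$i[k]], el[b$j[k]], b$order[k])
    if (is.null(bp)) next
    corr <- bp$params[["c"]] * (if (bp$swap) -1 else 1)
    q[b$i[k]] <- q[b$i[k]] + corr
    q[b$j[k]] <- q[b$j[k]] - corr
  }
  new_charge_result(mol, "eqeqc", ps, r$strategy, q, chibar = r$chibar)
}

#' GDAC charges
#'
#' Geometry-dependent atomic charges: iterative PEOE-style transfer
#' where each bond's damping factor depends on its length,
#' f_ij = 0.5 (r_cov_i + r_cov_j) / R_ij clamped to [0.05, 0.95], so
#' compressed bonds equalize more strongly than stretched ones.  Atom
#' electronegativity is linear, chi(q) = a + b q, with the transfer
#' normalized by the cation electronegativity a + b of the donor.
#'
#' @param mol a \code{molecule} with coordinates and bonds.
#' @param ps a \code{parameter_set} for method \code{"gdac"} with atom
#'   slots \code{a}, \code{b} (eV scale).
#' @param tol,max_iter convergence controls as in
#'   \code{\link{peoe_charges}}.
#' @return a \code{charge_result}.
#' @export
gdac_charges <- function(mol, ps, tol = 1e-6, max_iter = 100) {
  ab <- atom_parameter_matrix(ps, mol)
  b <- mol$bonds
  damp <- numeric(nrow(b))
  if (nrow(b)) {
    D <- distance_matrix(mol)
    r <- covalent_radius(mol$atoms$element)
    for (k in seq_len(nrow(b))) {
      r0 <- r[b$i[k]] + r[b$j[k]]
      damp[k] <- min(max(0.5 * r0 / D[b$i[k], b$j[k]], 0.05), 0.95)
    }
  }
  peoe_engine(mol, ab, damp, tol, max_iter, "gdac", ps, h_special = FALSE)
}
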