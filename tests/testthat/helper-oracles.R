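# Independent oracles used across the suite.  These are deliberately
# naive straight-line transcriptions that share no code with the
# production paths they check.

# Naive Gauss-Jordan elimination with partial pivoting.
naive_gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n)) {
    p <- which.max(abs(M[k:n, k])) + k - 1
    if (abs(M[p, k]) < 1e-14) stop("oracle: singular matrix")
    if (p != k) M[c(k, p), ] <- M[c(p, k), ]
    for (r in seq_len(n)) {
      if (r == k) next
      M[r, ] <- M[r, ] - M[r, k] / M[k, k] * M[k, ]
    }
  }
  M[, n + 1] / diag(M[, seq_len(n), drop = FALSE])
}

# Hand-assembled EEM matrix for a molecule + plain-keyed parameters;
# written independently of build_system().
oracle_eem_system <- function(xyz, A, B, kappa, Q) {
  n <- nrow(xyz)
  M <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        M[i, i] <- B[i]
      } else {
        M[i, j] <- kappa / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      }
    }
    M[i, n + 1] <- -1
    M[n + 1, i] <- 1
  }
  list(M = M, rhs = c(-A, Q))
}

# Two damped PEOE cycles iterated by hand for a single A-B bond.
oracle_peoe_two_cycles <- function(a, b, c) {
  q <- c(0, 0)
  for (k in 1:2) {
    chi <- a + b * q + c * q^2
    lo <- which.min(chi); hi <- which.max(chi)
    d <- (chi[hi] - chi[lo]) / (a[lo] + b[lo] + c[lo]) * 0.5^k
    q[lo] <- q[lo] + d
    q[hi] <- q[hi] - d
  }
  q
}

# Rigid rotation + translation of a molecule's coordinates.
rigid_transform <- function(mol, angle = 0.7, axis = c(1, 2, 2),
                            shift = c(3, -1, 5)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  mol$atoms$x <- xyz[, 1] + shift[1]
  mol$atoms$y <- xyz[, 2] + shift[2]
  mol$atoms$z <- xyz[, 3] + shift[3]
  mol
}

# Charges for a molecule under every implemented method, using toy
# parameter sets; returns a named list of charge_result.
all_method_charges <- function(mol, seed = 1) {
  els <- unique(mol$atoms$element)
  has3d <- has_coordinates(mol)
  out <- list()
  for (mid in method_registry()$id) {
    desc <- method_descriptor(mid)
    if (desc$dimensionality == "3D" && !has3d) next
    ps <- make_toy_parameters(mid, els, seed)
    out[[mid]] <- calculate_charges(mol, method = mid, parameters =
                                      if (is.null(ps)) "auto" else ps)
  }
  out
}

expect_orbit_equal <- function(result, mol, tol = 1e-8) {
  q <- unname(result$charges)
  for (orb in symmetry_orbits(mol)) {
    if (length(orb) > 1) {
      expect_lt(max(q[orb]) - min(q[orb]), tol)
    }
  }
}
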