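toy3 <- function(method, seed = 1) {
  make_toy_parameters(method, c("C", "N", "O"), seed)
}

# three heteroatoms in a scalene triangle: no accidental symmetry
tri_mol <- function() {
  simple_molecule(c("C", "N", "O"),
                  rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.5, 1.9, 0.3)),
                  data.frame(i = c(1, 2), j = c(2, 3), order = 1L),
                  name = "triangle")
}

test_that("the equalization system has the documented shape", {
  ps <- toy3("eem")
  mol <- tri_mol()
  sys <- build_system(mol, ps)
  n <- 3
  expect_equal(dim(sys$matrix), c(n + 1, n + 1))
  expect_equal(sys$matrix[n + 1, ], c(1, 1, 1, 0))       # constraint row
  expect_equal(sys$matrix[1:n, n + 1], rep(-1, n))       # chibar column
  expect_equal(sys$rhs[n + 1], total_formal_charge(mol))
  blk <- sys$matrix[1:n, 1:n]
  expect_equal(blk, t(blk))                              # symmetric block

  # EEM entries by direct substitution: off-diagonal kappa / R
  two <- simple_molecule(c("C", "N"), rbind(c(0, 0, 0), c(1, 0, 0)),
                         name = "pair")
  s2 <- build_system(two, ps)
  kappa <- ps$common[["kappa"]]
  expect_equal(s2$matrix[1, 2], kappa)
  expect_equal(s2$matrix[1, 1], unname(ps$atom[["C|*"]]["B"]))
  expect_equal(s2$rhs[1], -unname(ps$atom[["C|*"]]["A"]))

  # single atom: constraint row forces q = Q
  one <- molecule("ion", data.frame(element = "C", x = 0, y = 0, z = 0,
                                    formal_charge = 1L))
  r <- eem_charges(one, ps)
  expect_equal(unname(r$charges), 1)

  # coincident atoms are an error naming the pair
  bad <- simple_molecule(c("C", "N"), rbind(c(0, 0, 0), c(0, 0, 1e-6)))
  expect_error(build_system(bad, ps), "coincident")
})

test_that("production solves match the naive Gaussian-elimination oracle", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(2:6, 1)
    xyz <- matrix(stats::runif(3 * n, 0, 4), n, 3)
    if (min(dist(xyz)) < 0.5) next
    A <- stats::runif(n, 2, 4); B <- stats::runif(n, 0.5, 1.5)
    kappa <- stats::runif(1, 0.2, 0.5)
    Q <- sample(-1:1, 1)
    els <- c("C", "N", "O", "S", "F", "P")[1:n]
    ps <- atomcharge:::new_parameter_set(
      "oracle-eem", "eem", "test", "plain", list(kappa = kappa),
      stats::setNames(lapply(1:n, function(k) c(A = A[k], B = B[k])),
                      paste0(els, "|*")))
    mol <- simple_molecule(els, xyz, fc = c(Q, rep(0, n - 1)))
    sys <- build_system(mol, ps)
    x_prod <- solve_equalization(sys)
    o <- oracle_eem_system(xyz, A, B, kappa, Q)
    x_oracle <- naive_gauss_solve(o$M, o$rhs)
    expect_lt(max(abs(c(x_prod$q, x_prod$chibar) - x_oracle)), 1e-10)
  }
})

test_that("solver rejects singular systems", {
  sys <- list(matrix = matrix(c(1, 1, 0, 1, 1, 0, 1, 1, 0), 3, 3),
              rhs = c(1, 1, 0), n = 2)
  expect_error(solve_equalization(sys), "singular|ill-conditioned")
})

test_that("EEM satisfies the equalization certificate and geometry invariance", {
  ps <- toy3("eem")
  mol <- tri_mol()
  r <- eem_charges(mol, ps)
  chi_eff <- atomcharge:::effective_electronegativity(mol, ps,
                                                      unname(r$charges))
  expect_lt(max(abs(chi_eff - r$chibar)), 1e-6)

  rot <- rigid_transform(mol)
  r2 <- eem_charges(rot, ps)
  expect_lt(max(abs(unname(r2$charges) - unname(r$charges))), 1e-10)
})

test_that("phenol-like fixture puts the most positive hydrogen on the hydroxyl", {
  mol <- make_fixture("phenol_like")
  r <- eem_charges(mol, parameter_registry()[["eem-2015-hf-aim"]])
  q <- unname(r$charges)
  hs <- which(mol$atoms$element == "H")
  expect_equal(hydroxyl_h_index(mol), hs[which.max(q[hs])])
})

test_that("SFKEEM: symmetry and the large-sigma diagonal limit", {
  ps <- toy3("sfkeem")
  aa <- simple_molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                        fc = c(1L, 1L))
  r <- sfkeem_charges(aa, ps)
  expect_equal(unname(r$charges), c(1, 1))  # Q/2 each

  # sigma -> large: off-diagonals vanish; closed-form diagonal solution
  mol <- tri_mol()
  psb <- ps
  psb$common[["sigma"]] <- 60
  r2 <- sfkeem_charges(mol, psb)
  P <- atomcharge:::atom_parameter_matrix(psb, mol)
  # solve diag-only system by hand: 2 B_i q_i - chibar = -A_i, sum q = Q
  B2 <- 2 * P[, "B"]; A <- P[, "A"]
  chibar <- (0 + sum(A / B2)) / sum(1 / B2)
  qd <- (chibar - A) / B2
  expect_equal(unname(r2$charges), unname(qd), tolerance = 1e-8)

  # 3-atom system vs brute-force oracle on the assembled matrix
  sys <- build_system(mol, ps)
  x <- naive_gauss_solve(sys$matrix, sys$rhs)
  r3 <- sfkeem_charges(mol, ps)
  expect_lt(max(abs(unname(r3$charges) - x[1:3])), 1e-10)
})

test_that("QEq: hydrogen self-consistency and chi-gap monotonicity", {
  ps <- toy3("qeq")
  # no hydrogen: single outer iteration
  r <- qeq_charges(tri_mol(), ps)
  expect_identical(r$iterations, 1L)
  expect_true(r$converged)

  # symmetric H2 at Q = 0
  h2 <- simple_molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)),
                        name = "H2")
  psh <- make_toy_parameters("qeq", "H")
  rh <- qeq_charges(h2, psh)
  expect_equal(unname(rh$charges), c(0, 0), tolerance = 1e-10)

  # the certificate holds with the converged hydrogen hardnesses
  wat <- water_molecule()
  psw <- make_toy_parameters("qeq", c("O", "H"))
  rw <- qeq_charges(wat, psw)
  chi_eff <- atomcharge:::effective_electronegativity(
    wat, psw, unname(rw$charges), diag_override = attr(rw, "diag_used"))
  expect_lt(max(abs(chi_eff - rw$chibar)), 1e-6)

  # widening the electronegativity gap increases the transferred charge
  gaps <- seq(0, 4, by = 1)
  qs <- vapply(gaps, function(g) {
    ps2 <- atomcharge:::new_parameter_set(
      "scan", "qeq", "test", "plain", NULL,
      list(`C|*` = c(chi = 5, J = 10, radius = 1),
           `O|*` = c(chi = 5 + g, J = 12, radius = 0.9)))
    mol <- simple_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
    unname(qeq_charges(mol, ps2)$charges)[1]
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_equal(qs[1], 0, tolerance = 1e-10)
})

test_that("QEq off-diagonal recovers the Coulomb tail at large separation", {
  ps <- toy3("qeq")
  P <- atomcharge:::atom_parameter_matrix(ps, tri_mol())
  kern <- atomcharge:::make_kernel("qeq", ps)
  for (R in c(20, 50, 100)) {
    D <- matrix(c(0, R, R, 0), 2)
    off <- kern$offdiag(P[1:2, , drop = FALSE], P[1:2, , drop = FALSE],
                        D)[1, 2]
    expect_equal(off, 14.399645 / R, tolerance = 1e-8)
  }
})

test_that("EQeq: symmetry, oracle agreement and the EQeq+C identity", {
  ps <- toy3("eqeq")
  aa <- simple_molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1)),
                        fc = c(1L, 1L))
  expect_equal(unname(eqeq_charges(aa, ps)$charges), c(1, 1))

  mol <- tri_mol()
  sys <- build_system(mol, ps)
  x <- naive_gauss_solve(sys$matrix, sys$rhs)
  r <- eqeq_charges(mol, ps)
  expect_lt(max(abs(unname(r$charges) - x[1:3])), 1e-10)

  # certificate
  chi_eff <- atomcharge:::effective_electronegativity(mol, ps,
                                                      unname(r$charges))
  expect_lt(max(abs(chi_eff - r$chibar)), 1e-6)

  # EQeq+C with zero corrections is exactly EQeq
  psc <- atomcharge:::new_parameter_set(
    "zeroC", "eqeqc", "test", "plain", list(lambda = 1.2),
    ps$atom, bond = NULL)
  rc <- eqeqc_charges(mol, psc)
  expect_equal(unname(rc$charges), unname(r$charges), tolerance = 1e-12)

  # nonzero corrections shift along bonds but preserve the total
  psc2 <- atomcharge:::new_parameter_set(
    "withC", "eqeqc", "test", "plain", list(lambda = 1.2),
    ps$atom, bond = list(`C|N|1` = c(c = 0.05), `N|O|1` = c(c = -0.02)))
  rc2 <- eqeqc_charges(mol, psc2)
  expect_equal(sum(rc2$charges), sum(r$charges), tolerance = 1e-12)
  expect_equal(unname(rc2$charges)[1], unname(r$charges)[1] + 0.05)

  # EQeq+C without bonds is an error
  nob <- simple_molecule(c("C", "N"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(eqeqc_charges(nob, psc), "bond")

  # EQeq tail is Coulombic (scaled by lambda)
  kern <- atomcharge:::make_kernel("eqeq", ps)
  P <- atomcharge:::atom_parameter_matrix(ps, mol)
  D <- matrix(c(0, 60, 60, 0), 2)
  off <- kern$offdiag(P[1:2, , drop = FALSE], P[1:2, , drop = FALSE],
                      D)[1, 2]
  expect_equal(off, 1.2 * 14.399645 / 60, tolerance = 1e-6)
})

test_that("GDAC: symmetry, conservation and bond-compression response", {
  ps <- toy3("gdac")
  aa <- make_fixture("diatomic", elements = c("C", "C"))
  expect_equal(unname(gdac_charges(aa, ps)$charges), c(0, 0))

  # shrinking the bond strengthens equalization monotonically
  ps2 <- make_toy_parameters("gdac", c("C", "O"))
  qs <- vapply(c(1.6, 1.4, 1.2, 1.0), function(L) {
    mol <- simple_molecule(c("C", "O"), rbind(c(0, 0, 0), c(L, 0, 0)),
                           bonds = data.frame(i = 1, j = 2, order = 1L))
    abs(unname(gdac_charges(mol, ps2)$charges)[1])
  }, numeric(1))
  expect_true(all(diff(qs) > 0))

  wat <- water_molecule()
  psw <- make_toy_parameters("gdac", c("O", "H"))
  rw <- gdac_charges(wat, psw)
  expect_lt(abs(sum(rw$charges)), 1e-8)
  expect_orbit_equal(rw, wat)
})

test_that("3D methods are equivariant under rotation and reordering", {
  mol <- make_fixture("helix", n_atoms = 8, elements = c("C", "N", "O"))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  pmol <- atomcharge:::permute_molecule(mol, perm)
  rmol <- rigid_transform(mol)
  for (mid in c("eem", "sfkeem", "qeq", "eqeq", "gdac")) {
    ps <- toy3(mid)
    q <- unname(calculate_charges(mol, method = mid, parameters = ps)$charges)
    qp <- unname(calculate_charges(pmol, method = mid, parameters = ps)$charges)
    qr <- unname(calculate_charges(rmol, method = mid, parameters = ps)$charges)
    expect_equal(qp, q[perm], tolerance = 1e-9,
                 label = paste(mid, "permutation"))
    expect_equal(qr, q, tolerance = 1e-9, label = paste(mid, "rotation"))
  }
})

test_that("an apolar uniform region carries near-zero charges", {
  # identical elements on a uniform helix: nothing drives polarization
  mol <- make_fixture("helix", n_atoms = 40, elements = "C")
  r <- eem_charges(mol, make_toy_parameters("eem", "C"))
  expect_lt(max(abs(r$charges)), 1e-8)
})
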