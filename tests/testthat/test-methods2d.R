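test_that("PEOE: symmetry, conservation and hand-iterated transfers", {
  # homonuclear diatomic with identical parameters stays neutral
  aa <- make_fixture("diatomic", elements = c("C", "C"))
  ps <- make_toy_parameters("peoe", "C")
  r <- peoe_charges(aa, ps)
  expect_equal(unname(r$charges), c(0, 0))

  # methane: four equal hydrogens balancing the carbon
  ch4 <- make_fixture("methane")
  ps4 <- parameter_registry()[["peoe-gasteiger1980"]]
  r4 <- peoe_charges(ch4, ps4)
  q <- unname(r4$charges)
  expect_lt(max(q[2:5]) - min(q[2:5]), 1e-10)
  expect_equal(q[1], -4 * q[2], tolerance = 1e-8)
  expect_lt(abs(sum(q)), 1e-8)

  # two damped cycles on an A-B bond, against a hand iteration
  ab <- molecule("ab", data.frame(element = c("C", "O"), formal_charge = 0L),
                 data.frame(i = 1, j = 2, order = 1L))
  toy <- atomcharge:::new_parameter_set(
    "peoe-2atom", "peoe", "test", "plain", NULL,
    list(`C|*` = c(a = 8, b = 9, c = 1.5), `O|*` = c(a = 14, b = 13, c = 1.2)))
  r2 <- suppressWarnings(peoe_charges(ab, toy, tol = 0, max_iter = 2))
  expect_equal(unname(r2$charges), oracle_peoe_two_cycles(c(8, 14), c(9, 13),
                                                          c(1.5, 1.2)),
               tolerance = 1e-12)
})

test_that("PEOE matches an independent reference implementation on methanol", {
  # frozen expected charges computed with RDKit's Gasteiger implementation
  # (ComputeGasteigerCharges, converged) on the same geometry and the same
  # published coefficient table
  meoh <- molecule("methanol",
                   data.frame(element = c("C", "O", "H", "H", "H", "H"),
                              formal_charge = 0L),
                   data.frame(i = c(1, 1, 1, 1, 2), j = c(2, 3, 4, 5, 6),
                              order = 1L))
  ref <- c(0.03192, -0.39965, 0.05270, 0.05270, 0.05270, 0.20964)
  r <- peoe_charges(meoh, parameter_registry()[["peoe-gasteiger1980"]])
  expect_equal(unname(r$charges), ref, tolerance = 2e-4)
})

test_that("PEOE transfers decay geometrically after the first cycles", {
  prop <- read_structures(file.path(phenols_dir(),
                                    "propofol_gen3d.sdf"))$molecules[[1]]
  ps <- parameter_registry()[["peoe-gasteiger1980"]]
  # re-run with increasing cycle caps; the per-cycle movement must shrink
  qs <- lapply(2:6, function(k)
    unname(suppressWarnings(
      peoe_charges(prop, ps, tol = 0, max_iter = k))$charges))
  deltas <- vapply(seq_len(length(qs) - 1),
                   function(k) max(abs(qs[[k + 1]] - qs[[k]])), numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("MGC: equalization limits, signs and antisymmetry", {
  # single atom: the whole charge sits on it
  ion <- molecule("ion", data.frame(element = "O", formal_charge = -1L))
  expect_equal(unname(mgc_charges(ion)$charges), -1)

  # homonuclear chain at Q = 0: all zero
  chain <- make_fixture("chain", n_atoms = 6, elements = "C")
  expect_equal(unname(mgc_charges(chain)$charges), rep(0, 6))

  # heteronuclear diatomic: less electronegative atom positive,
  # charges antisymmetric
  hb <- molecule("HO", data.frame(element = c("H", "O"), formal_charge = 0L),
                 data.frame(i = 1, j = 2, order = 1L))
  q <- unname(mgc_charges(hb)$charges)
  expect_gt(q[1], 0)
  expect_lt(q[2], 0)
  expect_equal(q[1], -q[2], tolerance = 1e-10)
})

test_that("VEEM: closed-form valence-electron split", {
  aa <- make_fixture("diatomic", elements = c("N", "N"))
  expect_equal(unname(veem_charges(aa)$charges), c(0, 0))

  wat <- water_molecule()
  q <- unname(veem_charges(wat)$charges)
  expect_lt(abs(sum(q)), 1e-10)
  expect_gt(q[2], 0)               # H positive
  expect_equal(q[2], q[3])         # orbit symmetry
  expect_equal(q[1], -2 * q[2])    # conservation

  # bond order enters the split: N2 triple bond vs single bond in a
  # C-N pair
  cn1 <- molecule("cn1", data.frame(element = c("C", "N"), formal_charge = 0L),
                  data.frame(i = 1, j = 2, order = 1L))
  cn3 <- molecule("cn3", data.frame(element = c("C", "N"), formal_charge = 0L),
                  data.frame(i = 1, j = 2, order = 3L))
  expect_equal(unname(veem_charges(cn3)$charges)[1],
               3 * unname(veem_charges(cn1)$charges)[1])

  expect_error(veem_charges(molecule("u", data.frame(element = "U",
                                                     formal_charge = 0L))),
               "valence-electron")
})

test_that("Del Re: linear system against a brute-force matrix oracle", {
  ps <- parameter_registry()[["delre-organic-synthetic"]]

  # homonuclear diatomic with symmetric parameters
  cc <- molecule("cc", data.frame(element = c("C", "C"), formal_charge = 0L),
                 data.frame(i = 1, j = 2, order = 1L))
  expect_equal(unname(delre_charges(cc, ps)$charges), c(0, 0))

  # three-atom H-C-O chain: explicit 3x3 solve as the oracle
  hco <- molecule("hco", data.frame(element = c("H", "C", "O"),
                                    formal_charge = 0L),
                  data.frame(i = c(1, 2), j = c(2, 3), order = 1L))
  d0 <- c(0.00, 0.07, 0.40)
  # gamma matrix rows: delta_i = d0_i + sum_j gamma[i,j] delta_j
  G <- matrix(0, 3, 3)
  G[1, 2] <- 0.40; G[2, 1] <- 0.30          # C-H: gamma1 = C, gamma2 = H
  G[2, 3] <- 0.10; G[3, 2] <- 0.30          # C-O: gamma1 = C, gamma2 = O
  delta <- naive_gauss_solve(diag(3) - G, d0)
  eps <- c(1.00, 0.95)
  qo <- c(0, 0, 0)
  t1 <- (delta[2] - delta[1]) / (2 * eps[1]); qo[1] <- qo[1] + t1; qo[2] <- qo[2] - t1
  t2 <- (delta[3] - delta[2]) / (2 * eps[2]); qo[2] <- qo[2] + t2; qo[3] <- qo[3] - t2
  r <- delre_charges(hco, ps)
  expect_equal(unname(r$charges), qo, tolerance = 1e-10)
  expect_lt(abs(sum(r$charges)), 1e-10)

  # missing bond parameters are a structured error
  fs <- molecule("sulfide", data.frame(element = c("S", "S"),
                                       formal_charge = 0L),
                 data.frame(i = 1, j = 2, order = 1L))
  expect_error(delre_charges(fs, ps), "no bond parameters")
})

test_that("2D methods conserve charge and respect orbits on mixed fixtures", {
  mols <- list(make_fixture("phenol_like"), ethanol_graph(),
               make_fixture("chain", n_atoms = 9, elements = c("C", "N", "O")))
  for (mol in mols) {
    els <- unique(mol$atoms$element)
    for (mid in c("peoe", "mgc", "veem")) {
      ps <- make_toy_parameters(mid, els)
      r <- if (is.null(ps)) calculate_charges(mol, method = mid)
           else calculate_charges(mol, method = mid, parameters = ps)
      expect_lt(abs(sum(r$charges) - total_formal_charge(mol)), 1e-8,
                label = paste(mid, mol$name, "conservation"))
      expect_orbit_equal(r, mol)
    }
  }
})

test_that("2D methods are equivariant under atom reordering", {
  mol <- make_fixture("chain", n_atoms = 7, elements = c("C", "N"))
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  pmol <- atomcharge:::permute_molecule(mol, perm)
  for (mid in c("peoe", "mgc", "veem", "delre")) {
    ps <- if (mid == "delre") parameter_registry()[["delre-organic-synthetic"]]
          else make_toy_parameters(mid, c("C", "N"))
    args <- if (is.null(ps)) list(mol, method = mid)
            else list(mol, method = mid, parameters = ps)
    q <- unname(do.call(calculate_charges, args)$charges)
    args[[1]] <- pmol
    qp <- unname(do.call(calculate_charges, args)$charges)
    expect_equal(qp, q[perm], tolerance = 1e-10,
                 label = paste(mid, "permutation equivariance"))
  }
})
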