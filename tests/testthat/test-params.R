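test_that("bundled parameter sets load with the slots their methods declare", {
  reg <- parameter_registry()
  expect_gte(length(reg), 8)
  eem <- reg[["eem-2015-hf-aim"]]
  expect_s3_class(eem, "parameter_set")
  expect_equal(eem$method, "eem")
  expect_true("kappa" %in% names(eem$common))
  expect_true(all(c("H|1", "C|2", "O|1") %in% names(eem$atom)))
  expect_named(eem$atom[["H|1"]], c("A", "B"))

  qeq <- reg[["qeq-rappe-goddard1991"]]
  expect_named(qeq$atom[["H|*"]], c("chi", "J", "radius"))
  expect_equal(unname(qeq$atom[["H|*"]]["chi"]), 4.528)
})

test_that("schema violations are reported with the offending slot or key", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format_version = "1.0", id = "x", method = "eem",
                            scheme = "plain", common = list(),
                            atom = list(list(element = "C", value = "*",
                                             params = list(A = 1, B = 2)))),
                       tmp, auto_unbox = TRUE)
  expect_error(load_parameter_set(tmp), "kappa")

  jsonlite::write_json(list(format_version = "1.0", id = "x", method = "eem",
                            scheme = "plain", common = list(kappa = 0.4),
                            atom = list(
                              list(element = "C", value = "*",
                                   params = list(A = 1, B = 2)),
                              list(element = "C", value = "*",
                                   params = list(A = 3, B = 4)))),
                       tmp, auto_unbox = TRUE)
  expect_error(load_parameter_set(tmp), "duplicate atom-type")

  jsonlite::write_json(list(format_version = "1.0", id = "x",
                            method = "made-up", scheme = "plain",
                            common = list(), atom = list()),
                       tmp, auto_unbox = TRUE)
  expect_error(load_parameter_set(tmp), "unknown charge method")

  jsonlite::write_json(list(format_version = "1.0", id = "x", method = "eem",
                            scheme = "plain", common = list(kappa = 0.4),
                            atom = list(list(element = "C", value = "*",
                                             params = list(A = 1)))),
                       tmp, auto_unbox = TRUE)
  expect_error(load_parameter_set(tmp), "missing slot.*B")
})

test_that("applicability lists missing atom types and is monotone", {
  ps <- make_toy_parameters("eem", c("C", "H", "O"))
  withN <- molecule("amine", data.frame(element = c("C", "N", "H"),
                                        x = c(0, 1.5, 2.5), y = 0, z = 0,
                                        formal_charge = 0L),
                    data.frame(i = c(1, 2), j = c(2, 3), order = 1L))
  app <- applicability(ps, withN)
  expect_false(app$ok)
  expect_equal(app$missing, "N|*")

  # parameter-free methods cover everything
  expect_true(applicability(NULL, withN)$ok)

  # vacuously true on the empty molecule
  empty <- molecule("empty", data.frame(element = character(),
                                        formal_charge = integer()))
  expect_true(applicability(ps, empty)$ok)

  # monotone: adding the missing entry never flips true -> false
  ps2 <- make_toy_parameters("eem", c("C", "H", "O", "N"))
  expect_true(applicability(ps2, withN)$ok)
  for (extra in c("S", "F", "Cl")) {
    ps3 <- make_toy_parameters("eem", c("C", "H", "O", "N", extra))
    expect_true(applicability(ps3, withN)$ok)
  }
})

test_that("automatic selection prefers EEM for drug-like 3D input", {
  prop <- read_structures(file.path(phenols_dir(),
                                    "propofol_gen3d.sdf"))$molecules[[1]]
  sel <- select_automatic(list(prop))
  expect_equal(sel$method$id, "eem")
  expect_equal(sel$parameters$id, "eem-2015-hf-aim")
})

test_that("inputs without coordinates fall back to a 2D method", {
  graph <- ethanol_graph()
  sel <- select_automatic(list(graph))
  expect_equal(sel$method$dimensionality, "2D")
  expect_equal(sel$method$id, "peoe")
})

test_that("an element no set covers routes to a parameter-free method", {
  # a bond-graph-only dimer of an element outside every bundled 2D set
  exotic <- molecule("zinc_dimer",
                     data.frame(element = c("Zn", "Zn"), formal_charge = 0L),
                     data.frame(i = 1, j = 2, order = 1L))
  sel <- select_automatic(list(exotic))
  expect_false(sel$method$needs_parameters)
  r <- calculate_charges(exotic, method = sel$method$id)
  expect_equal(unname(r$charges), c(0, 0))
})

test_that("selection is invariant to molecule ordering", {
  d <- phenols_dir()
  mols <- lapply(c("propofol_gen3d.sdf", "cresol_m_gen3d.sdf",
                   "chlorophenol_2_gen3d.sdf"),
                 function(f) read_structures(file.path(d, f))$molecules[[1]])
  s1 <- select_automatic(mols)
  s2 <- select_automatic(rev(mols))
  expect_equal(s1$method$id, s2$method$id)
  expect_equal(s1$parameters$id, s2$parameters$id)
})
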