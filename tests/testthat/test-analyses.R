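# Concentration response ---------------------------------------------------

test_that("the knockdown grid has 101 points and starts at the exact baseline", {
  fx <- dyrk1a_fixture()
  curve <- dyrk1a_curve()
  expect_length(curve$fractions, 101)
  expect_equal(curve$fractions[2] - curve$fractions[1], 0.01)
  expect_identical(unname(curve$activities[, 1]), unname(fx$baseline$state))
  expect_true(all(curve$converged))
  expect_error(concentration_response(fx$model, step = 0.03), "divide 1 evenly")
})

test_that("normalized responses span exactly [0, 1] for responding nodes", {
  curve <- dyrk1a_curve()
  resp <- rownames(curve$normalized)[curve$responding]
  expect_true("DNA_replication" %in% resp && "pLIN52" %in% resp)
  expect_equal(unname(curve$normalized[resp, 1]), rep(0, length(resp)))
  expect_equal(unname(curve$normalized[resp, 101]), rep(1, length(resp)))
  # the input held constant by its own source rule does not respond
  expect_false(curve$responding[["BMyb"]])
  expect_true(is.na(curve$half_max[["BMyb"]]))
})

test_that("DNA replication increases monotonically with DYRK1A knockdown", {
  curve <- dyrk1a_curve()
  expect_false(is.unsorted(curve$activities["DNA_replication", ]))
  expect_false(is.unsorted(rev(curve$activities["pLIN52", ])))
})

test_that("half-max extraction interpolates the first 0.5 crossing linearly", {
  # synthetic curve: normalized 0.45 at k = 0.20 and 0.55 at k = 0.21
  k <- seq(0, 1, by = 0.01)
  v <- approx(x = c(0, 0.20, 0.21, 1), y = c(0, 0.45, 0.55, 1), xout = k)$y
  curve <- structure(
    list(target = "X", fractions = k,
         normalized = matrix(v, nrow = 1, dimnames = list("node", NULL)),
         responding = c(node = TRUE), converged = rep(TRUE, length(k))),
    class = "dose_response_curve"
  )
  expect_equal(estimate_half_max(curve, "node"), 0.205, tolerance = 1e-12)
  expect_error(estimate_half_max(curve, "missing"), "unknown node")
})

test_that("half-max estimates are stable under grid refinement", {
  curve1 <- dyrk1a_curve()
  curve2 <- concentration_response(dyrk1a_fixture()$model, step = 0.005)
  for (id in c("DNA_replication", "CycD", "pLIN52", "DREAM")) {
    expect_lt(abs(curve1$half_max[[id]] - curve2$half_max[[id]]), 0.005)
  }
})

test_that("non-converged grid points suppress half-max estimates", {
  curve <- dyrk1a_curve()
  curve$converged[50] <- FALSE
  expect_true(is.na(estimate_half_max(curve, "DNA_replication")))
})

# Knockdown screen ----------------------------------------------------------

test_that("the screen's context row is zero and it agrees with the curve at 100%", {
  fx <- dyrk1a_fixture()
  screen <- knockdown_screen(fx$model)
  expect_true(all(screen$converged))
  expect_lt(max(abs(screen$delta["DYRK1A", ])), 1e-5)
  # reference column equals the concentration response at fraction 1.0
  curve <- dyrk1a_curve()
  expect_equal(unname(screen$reference), unname(curve$activities[, 101]),
               tolerance = 1e-6)
})

test_that("E2F knockouts attenuate the replication rise; cyclin arms are redundant", {
  fx <- dyrk1a_fixture()
  screen <- knockdown_screen(fx$model)
  rise <- screen$reference[["DNA_replication"]] -
    fx$baseline$state[["DNA_replication"]]
  expect_gt(rise, 0.5)
  for (id in c("E2F1", "E2F2", "E2F3")) {
    expect_lte(screen$delta[id, "DNA_replication"], -0.1 * rise)
  }
  for (id in c("CycD", "CycE_CDK2")) {
    expect_lt(abs(screen$delta[id, "DNA_replication"]), 0.1 * rise)
  }
})

# Dose simulation -----------------------------------------------------------

test_that("inhibitor doses produce strictly increasing replication and cyclin D", {
  fx <- dyrk1a_fixture()
  ds <- dose_simulation(fx$model)
  expect_equal(ds$dose, c(0, 0.15, 0.30, 0.45))
  expect_equal(ds$DNA_replication[1], fx$baseline$state[["DNA_replication"]])
  expect_true(all(diff(ds$DNA_replication) > 0))
  expect_true(all(diff(ds$CycD) > 0))
})

# Determinism ---------------------------------------------------------------

test_that("analysis outputs are byte-identical across repeated runs", {
  fx <- dyrk1a_fixture()
  c1 <- concentration_response(fx$model, step = 0.1)
  c2 <- concentration_response(fx$model, step = 0.1)
  expect_identical(c1$activities, c2$activities)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dose_response(c1, f1); write_dose_response(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s1 <- knockdown_screen(fx$model, context = list())
  s2 <- knockdown_screen(fx$model, context = list())
  expect_identical(s1$delta, s2$delta)
  unlink(c(f1, f2))
})
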