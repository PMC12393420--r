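# Gate algebra -----------------------------------------------------------

test_that("rule_flux implements clamped AND gating", {
  # source rule: constant flux w
  expect_equal(rule_flux(reaction_rule("X"), c(X = 0)), 1)
  expect_equal(rule_flux(reaction_rule("X", w = 0.4), c(X = 0)), 0.4)
  # single inhibitor at activity 0: w * (1 - f(0)) = 1
  expect_equal(rule_flux(reaction_rule("Y", "!X"), c(X = 0)), 1)
  # AND = product: with n=1, ec50=0.25, f(1/3) = 0.6 and f(0.25) = 0.5
  r <- reaction_rule("C", c("A", "B"), n = 1, ec50 = 0.25)
  expect_equal(rule_flux(r, c(A = 1 / 3, B = 0.25)), 0.3, tolerance = 1e-12)
  # overexpressed regulator (activity 10): f clamps to 1
  expect_equal(rule_flux(reaction_rule("Y", "X"), c(X = 10)), 1)
  expect_equal(rule_flux(reaction_rule("Y", "!X"), c(X = 10)), 0)
})

test_that("node_input OR-combines rule fluxes", {
  st <- c(A = 0.5, B = 0.5, C = 0)
  rules <- list(reaction_rule("C", "A"), reaction_rule("C", "B"))
  # f(0.5) = 0.5 at defaults, OR(0.5, 0.5) = 0.75
  expect_equal(node_input("C", rules, st), 0.75, tolerance = 1e-12)
  # single rule passes through unchanged
  expect_equal(node_input("C", rules[1], st), 0.5, tolerance = 1e-12)
  # 1 is absorbing
  rules2 <- list(reaction_rule("C", "A"), reaction_rule("C", "B"))
  expect_equal(node_input("C", rules2, c(A = 1, B = 0.37)), 1)
  # no rules -> 0
  expect_equal(node_input("Z", rules, st), 0)
})

test_that("network_rhs is the relaxation towards y_max * gate", {
  # isolated species (no rules): dY/dt = -Y / tau
  iso <- network_model(species("A", y_init = 0.3), list(), check = FALSE)
  expect_equal(network_rhs(iso, c(A = 0.3)), c(A = -0.3))
  # input at its source fixed point: dY/dt = 0
  inp <- network_model(species("A", role = "input", y_max = 0.9),
                       list(reaction_rule("A")))
  expect_equal(network_rhs(inp, c(A = 0.9)), c(A = 0))
})

test_that("derivatives point inward at the faces of the [0, y_max] box", {
  for (seed in 1:10) {
    m <- generate_random_network(6, 8, seed = seed, kind = "random")
    ids <- m$species$id
    at_zero <- setNames(rep(0, length(ids)), ids)
    expect_true(all(network_rhs(m, at_zero) >= 0))
    at_max <- setNames(m$species$y_max, ids)
    expect_true(all(network_rhs(m, at_max) <= 1e-12))
  }
})

# Integration -------------------------------------------------------------

test_that("a fixed-point initial condition yields a constant trajectory", {
  m <- two_node_cascade(0.9)
  fp <- fixed_point_state(m)
  sim <- simulate_network(m, t_end = 10, y0 = fp)
  expect_equal(sim$activities[1, ], fp, tolerance = 1e-10)
  expect_lt(max(abs(sweep(sim$activities, 2, fp))), 1e-6)
})

test_that("trajectories start at y_init and cascades converge to f-compositions", {
  m1 <- two_node_cascade(1)
  sim1 <- simulate_network(m1, t_end = 40)
  expect_equal(unname(sim1$activities[1, ]), c(1, 1) * 0)  # y_init = 0
  expect_equal(unname(sim1$final), c(1, 1), tolerance = 1e-6)

  m9 <- two_node_cascade(0.9)
  sim9 <- simulate_network(m9, t_end = 60)
  expect_equal(sim9$final[["B"]], oracle_hill(0.9, 1.4, 0.5), tolerance = 1e-6)
  expect_equal(sim9$final[["B"]], 0.9116, tolerance = 1e-4)
})

test_that("halving the integrator tolerance leaves activities unchanged to 1e-6", {
  fx <- dyrk1a_fixture()
  s1 <- simulate_network(fx$model, t_end = 20, rtol = 1e-8, atol = 1e-10)
  s2 <- simulate_network(fx$model, t_end = 20, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(s1$activities - s2$activities)), 1e-6)
})

test_that("trajectories stay inside [0, y_max] on random networks", {
  for (seed in 1:15) {
    m <- generate_random_network(5, 7, seed = seed,
                                 kind = if (seed %% 2) "random_acyclic" else "random")
    sim <- simulate_network(m, t_end = 30)
    upper <- rep(m$species$y_max, each = nrow(sim$activities))
    expect_true(all(sim$activities >= -1e-9))
    expect_true(all(sim$activities <= upper + 1e-9))
  }
})

# Steady-state detection ---------------------------------------------------

test_that("a fixed-point start converges at the first check window", {
  m <- two_node_cascade(0.9)
  ss <- run_to_steady_state(m, y0 = fixed_point_state(m))
  expect_true(ss$converged)
  expect_equal(ss$t_reached, 1)
  expect_lt(ss$max_rel_change, 5e-4)
})

test_that("acyclic steady states match the topological fixed point", {
  for (seed in 1:20) {
    m <- generate_random_network(6, 8, seed = seed, kind = "random_acyclic")
    ss <- ss_tight(m)
    expect_true(ss$converged)
    expect_lt(max(abs(ss$state - oracle_fixed_point(m))), 1e-6)
  }
})

test_that("truncated integration reports non-convergence with the state", {
  slow <- network_model(
    rbind(species("A", role = "input", tau = 50)),
    list(reaction_rule("A")))
  ss <- run_to_steady_state(slow, max_time = 5)
  expect_false(ss$converged)
  expect_equal(ss$t_reached, 5)
  expect_equal(ss$state[["A"]], 1 - exp(-5 / 50), tolerance = 1e-4)
})

test_that("a steep repressor ring oscillates and never converges", {
  ss <- run_to_steady_state(repressor_ring(), max_time = 150)
  expect_false(ss$converged)
  expect_gt(ss$max_rel_change, 5e-4)
  # confirm genuine oscillation: activity keeps swinging late in the run
  sim <- simulate_network(repressor_ring(), t_end = 60)
  late <- sim$activities[sim$time >= 40, "A"]
  expect_gt(diff(range(late)), 0.3)
})

test_that("increasing an activating input never lowers downstream steady states", {
  for (levels in list(c(0.3, 0.5), c(0.5, 0.8), c(0.2, 0.9))) {
    cas <- generate_cascade(3, input_level = levels[1])
    lo <- run_to_steady_state(cas$model)
    hi_model <- cas$model
    hi_model$species$y_max[1] <- levels[2]
    hi <- run_to_steady_state(hi_model)
    expect_true(all(hi$state >= lo$state - 1e-9))
  }
})

test_that("trajectory and steady-state writers emit stable plain-text output", {
  m <- two_node_cascade(0.9)
  sim <- simulate_network(m, t_end = 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sim, f1)
  df <- read.csv(f1)
  expect_identical(names(df), c("time", "A", "B"))
  expect_equal(nrow(df), length(sim$time))

  ss <- run_to_steady_state(m)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_steady_state(ss, f2)
  obj <- jsonlite::read_json(f2)
  expect_true(obj$converged)
  expect_equal(obj$A, 0.9, tolerance = 1e-3)
})
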