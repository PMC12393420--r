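# Independent oracles, written from scratch against the model definition
# (not through the package's engine code paths).

# Normalized Hill via the alternative algebraic route: from f(1) = 1 follows
# B = K^n + 1; substituting into f(ec50) = 0.5 and solving for u = K^n gives
# u = 0.5 * ec50^n / (0.5 - ec50^n).
oracle_hill <- function(x, n, ec50) {
  e <- ec50^n
  u <- 0.5 * e / (0.5 - e)
  (u + 1) * x^n / (u + x^n)
}

# Gate input of one species, evaluated directly from the rule list.
oracle_gate <- function(model, id, state) {
  g <- 0
  for (r in model$rules) {
    if (r$product != id) next
    flux <- r$w
    if (nrow(r$regulators)) {
      f <- oracle_hill(state[r$regulators$id], r$n, r$ec50)
      f <- pmin(pmax(f, 0), 1)
      term <- ifelse(r$regulators$sign == "inhibiting", 1 - f, f)
      flux <- flux * prod(term)
    }
    g <- g + flux - g * flux
  }
  g
}

# Brute-force fixed point by repeated synchronous sweeps; for an acyclic
# network this settles exactly after at most n_species sweeps.
oracle_fixed_point <- function(model, sweeps = 2 * nrow(model$species)) {
  ids <- model$species$id
  state <- stats::setNames(rep(0, length(ids)), ids)
  for (k in seq_len(sweeps)) {
    state <- stats::setNames(vapply(seq_along(ids), function(i) {
      model$species$y_max[i] * oracle_gate(model, ids[i], state)
    }, numeric(1)), ids)
  }
  state
}

# Steady state at solver-grade accuracy: the default stopping rule (0.05%
# change per time unit) deliberately halts within ~1e-4 of the fixed point;
# oracle-correspondence tests tighten it so the comparison is meaningful.
ss_tight <- function(model, ...) {
  run_to_steady_state(model, rel_tol = 1e-7, abs_tol = 1e-10,
                      abs_level = 1e-6, rtol = 1e-10, atol = 1e-12, ...)
}

# Simple shared fixtures -----------------------------------------------------

two_node_cascade <- function(input_y_max = 0.9) {
  network_model(
    rbind(species("A", role = "input", y_max = input_y_max),
          species("B", role = "output")),
    list(reaction_rule("A"), reaction_rule("B", "A"))
  )
}

# A steep 3-node repressor ring: sustained oscillations, never converges.
repressor_ring <- function() {
  network_model(
    rbind(species("A", y_init = 0.9), species("B", y_init = 0.1),
          species("C", y_init = 0.5)),
    list(reaction_rule("A", "!C", n = 6, ec50 = 0.45),
         reaction_rule("B", "!A", n = 6, ec50 = 0.45),
         reaction_rule("C", "!B", n = 6, ec50 = 0.45))
  )
}

# The shipped model and its baseline are reused across files; cache them.
.fixture_cache <- new.env(parent = emptyenv())

dyrk1a_fixture <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- build_dyrk1a_model()
    .fixture_cache$baseline <- run_to_steady_state(.fixture_cache$model)
  }
  list(model = .fixture_cache$model, baseline = .fixture_cache$baseline)
}

dyrk1a_curve <- function() {
  if (is.null(.fixture_cache$curve)) {
    .fixture_cache$curve <- concentration_response(dyrk1a_fixture()$model,
                                                   step = 0.01)
  }
  .fixture_cache$curve
}
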