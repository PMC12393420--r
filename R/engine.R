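# The logic-based ODE core.
#
# Each species relaxes towards y_max times its gated input:
#   dY_i/dt = (Ymax_i * g_i(Y) - Y_i) / tau_i
# where g_i OR-combines the fluxes of all rules producing species i. Gate
# terms are clamped to [0, 1] before combination so that overexpression
# clamps (activities above 1, where f exceeds 1) cannot push the OR algebra
# out of range; states therefore stay non-negative and, absent clamped
# initial conditions, inside [0, y_max].

# Precompute per-rule regulator indices and Hill constants once per model.
compile_model <- function(model) {
  ids <- model$species$id
  rules <- lapply(model$rules, function(rule) {
    p <- hill_constants(rule$n, rule$ec50)
    list(prod = match(rule$product, ids),
         reg = match(rule$regulators$id, ids),
         inhib = rule$regulators$sign == "inhibiting",
         w = rule$w, n = rule$n, Kn = p$K^p$n, B = p$B)
  })
  by_product <- lapply(seq_along(ids), function(i) {
    rules[vapply(rules, function(r) r$prod == i, logical(1))]
  })
  list(ids = ids, y_max = model$species$y_max, tau = model$species$tau,
       y_init = stats::setNames(model$species$y_init, ids),
       by_product = by_product)
}

compiled_flux <- function(crule, state) {
  flux <- crule$w
  if (length(crule$reg)) {
    x <- pmax(state[crule$reg], 0)
    f <- pmin(pmax(crule$B * x^crule$n / (crule$Kn + x^crule$n), 0), 1)
    term <- ifelse(crule$inhib, 1 - f, f)
    flux <- flux * prod(term)
  }
  flux
}

compiled_gate <- function(crules, state) {
  g <- 0
  for (crule in crules) {
    a <- compiled_flux(crule, state)
    g <- g + a - g * a  # inclusive OR, left fold in declaration order
  }
  g
}

compiled_rhs <- function(cm, state) {
  g <- vapply(cm$by_product, compiled_gate, numeric(1), state = state)
  (cm$y_max * g - state) / cm$tau
}

#' Flux of a single reaction rule
#'
#' Computes `w * prod(terms)` where each activating regulator contributes
#' `clamp(f(x), 0, 1)` and each inhibiting regulator `1 - clamp(f(x), 0, 1)`
#' (AND = product). A source rule (no regulators) has constant flux `w`.
#'
#' @param rule A [reaction_rule()].
#' @param state Named numeric vector of species activities.
#' @return Flux in `[0, w]`.
#' @export
rule_flux <- function(rule, state) {
  stopifnot(inherits(rule, "reaction_rule"))
  flux <- rule$w
  if (nrow(rule$regulators)) {
    p <- hill_constants(rule$n, rule$ec50)
    x <- state[rule$regulators$id]
    if (anyNA(x)) {
      stop("state is missing regulator(s): ",
           paste(setdiff(rule$regulators$id, names(state)), collapse = ", "),
           call. = FALSE)
    }
    f <- pmin(pmax(hill_activation(pmax(x, 0), p), 0), 1)
    term <- ifelse(rule$regulators$sign == "inhibiting", 1 - f, f)
    flux <- flux * prod(term)
  }
  unname(flux)
}

#' Gated input of one species
#'
#' OR-combines the fluxes of all rules producing `product` with the
#' inclusive-or algebra `OR(a, b) = a + b - a*b`, folded left in rule
#' declaration order (the result is order-independent). A species with no
#' rules has gate output 0.
#'
#' @param product Species id.
#' @param rules List of [reaction_rule()] objects (e.g. `model$rules`).
#' @param state Named numeric vector of activities.
#' @return Gate output in `[0, 1]`.
#' @export
node_input <- function(product, rules, state) {
  g <- 0
  for (rule in rules) {
    if (rule$product != product) next
    a <- rule_flux(rule, state)
    g <- g + a - g * a
  }
  g
}

#' Right-hand side of the network ODE
#'
#' For each species `i`: `dY_i/dt = (Ymax_i * g_i(state) - Y_i) / tau_i`
#' with `g_i` the OR-combined gate input of [node_input()].
#'
#' @param model A `network_model`.
#' @param state Named numeric vector of activities (one per species, in any
#'   order; matched by name).
#' @return Named derivative vector in species declaration order.
#' @export
network_rhs <- function(model, state) {
  state <- state[model$species$id]
  cm <- compile_model(model)
  stats::setNames(compiled_rhs(cm, state), model$species$id)
}

#' Simulate a network model
#'
#' Integrates the logic-based ODE from the model's initial activities (or a
#' supplied state) with a stiff-capable adaptive integrator
#' (`deSolve::lsoda`, rtol 1e-8, atol 1e-10 by default; the tau spread of
#' overexpression clamps, up to 1e9, makes the system stiff).
#'
#' @param model A `network_model`.
#' @param t_end End time (> 0), in the model's time units.
#' @param step Reporting step for the output grid (default 0.1).
#' @param y0 Optional named initial state; defaults to the species `y_init`.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `network_simulation`: list with `time`,
#'   `activities` (matrix, time x species) and `final` (named vector).
#' @examples
#' m <- network_model(
#'   rbind(species("A", role = "input", y_max = 0.9), species("B")),
#'   list(reaction_rule("A"), reaction_rule("B", "A"))
#' )
#' sim <- simulate_network(m, t_end = 30)
#' tail(sim$activities, 1)
#' @export
simulate_network <- function(model, t_end, step = 0.1, y0 = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, step > 0)
  cm <- compile_model(model)
  y0 <- resolve_state(cm, y0)
  times <- seq(0, t_end, by = step)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  out <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms) list(compiled_rhs(cm, y)),
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed at t = ", max(out[, "time"]),
         "; last valid state: ",
         paste(sprintf("%s=%.4g", cm$ids, out[nrow(out), -1]), collapse = ", "),
         call. = FALSE)
  }
  act <- out[, -1, drop = FALSE]
  colnames(act) <- cm$ids
  structure(list(time = out[, "time"], activities = act,
                 final = stats::setNames(act[nrow(act), ], cm$ids)),
            class = "network_simulation")
}

resolve_state <- function(cm, y0) {
  if (is.null(y0)) return(cm$y_init)
  if (is.null(names(y0)) && length(y0) == length(cm$ids)) {
    return(stats::setNames(as.numeric(y0), cm$ids))
  }
  missing <- setdiff(cm$ids, names(y0))
  if (length(missing)) {
    stop("initial state missing species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.numeric(y0[cm$ids]), cm$ids)
}

#' Integrate to steady state
#'
#' Integrates until, over a check window of `window` time units, every
#' species' relative activity change is below `rel_tol` (default 5e-4, i.e.
#' <0.05% change in activity for all nodes). For species with activity below
#' `abs_level` the relative criterion is ill-posed and an absolute change
#' below `abs_tol` is required instead.
#'
#' @param model A `network_model`.
#' @param y0 Optional named initial state (defaults to `y_init`).
#' @param max_time Give up (with `converged = FALSE`) after this time.
#' @param window Width of the convergence check window (time units).
#' @param rel_tol Relative-change threshold (default 5e-4 = 0.05%).
#' @param abs_tol Absolute-change threshold used below `abs_level`.
#' @param abs_level Activity below which the absolute criterion applies.
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `steady_state`: list with `state` (named
#'   activities), `converged`, `t_reached` and `max_rel_change` (largest
#'   per-species change measure over the last check window).
#' @examples
#' ss <- run_to_steady_state(build_dyrk1a_model())
#' ss$converged
#' @export
run_to_steady_state <- function(model, y0 = NULL, max_time = 1000,
                                window = 1, rel_tol = 5e-4, abs_tol = 5e-7,
                                abs_level = 1e-3, rtol = 1e-8, atol = 1e-10) {
  stopifnot(max_time > 0, window > 0)
  cm <- compile_model(model)
  state <- resolve_state(cm, y0)
  func <- function(t, y, parms) list(compiled_rhs(cm, y))
  t_now <- 0
  chunk <- 32 * window
  measure <- rep(Inf, length(state))
  while (t_now < max_time) {
    t_to <- min(t_now + chunk, max_time)
    times <- seq(t_now, t_to, by = window)
    if (times[length(times)] < t_to) times <- c(times, t_to)
    out <- deSolve::ode(y = state, times = times, func = func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      stop("ODE integration failed at t = ", max(out[, "time"]), call. = FALSE)
    }
    act <- out[, -1, drop = FALSE]
    for (i in 2:nrow(act)) {
      prev <- act[i - 1, ]
      cur <- act[i, ]
      d <- abs(cur - prev)
      measure <- ifelse(abs(prev) < abs_level, d, d / abs(prev))
      ok <- ifelse(abs(prev) < abs_level, d < abs_tol, d / abs(prev) < rel_tol)
      if (all(ok)) {
        return(structure(list(state = stats::setNames(cur, cm$ids),
                              converged = TRUE, t_reached = unname(out[i, "time"]),
                              max_rel_change = max(measure)),
                         class = "steady_state"))
      }
    }
    state <- stats::setNames(act[nrow(act), ], cm$ids)
    t_now <- t_to
  }
  structure(list(state = state, converged = FALSE, t_reached = max_time,
                 max_rel_change = max(measure)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s at t = %g, max change %.3g):\n",
              if (x$converged) "converged" else "NOT converged",
              x$t_reached, x$max_rel_change))
  print(round(x$state, 4))
  invisible(x)
}

#' @export
print.network_simulation <- function(x, ...) {
  cat(sprintf("network simulation: %d time points over [0, %g], %d species\n",
              length(x$time), max(x$time), ncol(x$activities)))
  cat("final state:\n")
  print(round(x$final, 4))
  invisible(x)
}

#' Write a simulated trajectory as CSV
#'
#' First column `time`, one column per species id.
#'
#' @param sim A `network_simulation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "network_simulation"))
  df <- data.frame(time = sim$time, sim$activities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a steady state as JSON
#'
#' Emits `{<species>: activity, ..., converged, t_reached, max_rel_change}`.
#'
#' @param ss A `steady_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(ss, path) {
  stopifnot(inherits(ss, "steady_state"))
  obj <- c(as.list(ss$state),
           list(converged = ss$converged, t_reached = ss$t_reached,
                max_rel_change = ss$max_rel_change))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
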