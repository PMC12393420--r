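# In-silico analyses: knockdown concentration response with EC50/IC50
# extraction, the single-node knockdown screen, and the low/medium/high
# inhibitor-dose simulation. All analyses follow the perturb-after-steady-
# state protocol: every perturbed run restarts from its context's steady
# state (continuation), not from y_init.

#' Knockdown concentration response
#'
#' Applies a graded knockdown of `target` over the fraction grid
#' `0, step, ..., 1`, re-running the model to steady state from the
#' baseline steady state at every grid point, and records all node
#' activities. Node responses are min-max normalized between each node's
#' 0%-knockdown and 100%-knockdown activities, and the half-max knockdown
#' fraction (EC50 for rising nodes, IC50 for falling nodes) is the first
#' 0.5-crossing of the normalized activity, linearly interpolated.
#'
#' @param model A `network_model`.
#' @param target Species to knock down (default `"DYRK1A"`).
#' @param step Grid increment; must divide 1 evenly (default 0.01, i.e.
#'   1% increments, 101 grid points).
#' @param response_delta Minimal absolute activity change between the grid
#'   ends for a node to count as responding (default 1e-3).
#' @param ... Passed on to [run_to_steady_state()].
#' @return Object of class `dose_response_curve`: list with `target`,
#'   `fractions`, `activities` (matrix node x grid), `normalized` (same
#'   shape; `NA` rows for non-responding nodes), `half_max` (named vector,
#'   `NA` where undefined), `responding`, and `converged` (per grid point).
#' @export
concentration_response <- function(model, target = "DYRK1A", step = 0.01,
                                   response_delta = 1e-3, ...) {
  stopifnot(step > 0, step <= 1)
  n_steps <- round(1 / step)
  if (abs(n_steps * step - 1) > 1e-9) {
    stop("step must divide 1 evenly, got ", step, call. = FALSE)
  }
  species_index(model, target, "knockdown target")
  fractions <- seq(0, 1, length.out = n_steps + 1)
  baseline <- run_to_steady_state(model, ...)
  ids <- model$species$id
  activities <- matrix(NA_real_, nrow = length(ids), ncol = length(fractions),
                       dimnames = list(ids, NULL))
  converged <- logical(length(fractions))
  activities[, 1] <- baseline$state
  converged[1] <- baseline$converged
  for (j in seq_along(fractions)[-1]) {
    km <- apply_knockdown(model, target, fractions[j])
    ss <- run_to_steady_state(km, y0 = baseline$state, ...)
    activities[, j] <- ss$state
    converged[j] <- ss$converged
  }
  a0 <- activities[, 1]
  a1 <- activities[, ncol(activities)]
  responding <- abs(a1 - a0) > response_delta
  normalized <- (activities - a0) / (a1 - a0)
  normalized[!responding, ] <- NA_real_
  curve <- structure(
    list(target = target, fractions = fractions, activities = activities,
         normalized = normalized, responding = responding,
         converged = converged, baseline = baseline),
    class = "dose_response_curve"
  )
  curve$half_max <- stats::setNames(
    vapply(ids, function(id) estimate_half_max(curve, id), numeric(1)), ids)
  curve
}

#' Half-max knockdown fraction of a node
#'
#' The smallest grid crossing of the node's min-max-normalized activity
#' through 0.5, linearly interpolated between the bracketing grid points.
#' This is the EC50 of rising nodes and the IC50 of falling nodes (both
#' rise from 0 to 1 after signed normalization). Undefined (`NA`) for
#' non-responding nodes and suppressed when any grid point failed to
#' converge.
#'
#' @param curve A `dose_response_curve`.
#' @param node Species id.
#' @return Knockdown fraction in `(0, 1)`, or `NA` if undefined.
#' @export
estimate_half_max <- function(curve, node) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (!node %in% rownames(curve$normalized)) {
    stop("unknown node: '", node, "'", call. = FALSE)
  }
  if (!curve$responding[[node]] || any(!curve$converged)) return(NA_real_)
  v <- curve$normalized[node, ]
  k <- curve$fractions
  for (i in seq_len(length(v) - 1L)) {
    lo <- v[i] - 0.5
    hi <- v[i + 1] - 0.5
    if (lo == 0) return(k[i])
    if (lo * hi <= 0 && lo != hi) {
      return(k[i] + (k[i + 1] - k[i]) * (0.5 - v[i]) / (v[i + 1] - v[i]))
    }
  }
  if (v[length(v)] == 0.5) return(k[length(k)])
  NA_real_
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("concentration response: %s knockdown, %d grid points%s\n",
              x$target, length(x$fractions),
              if (all(x$converged)) "" else " [non-converged points!]"))
  hm <- x$half_max[x$responding]
  dir <- ifelse(x$activities[names(hm), ncol(x$activities)] >
                  x$activities[names(hm), 1], "EC50", "IC50")
  for (i in seq_along(hm)) {
    cat(sprintf("  %-16s %s = %.3f\n", names(hm)[i], dir[i], hm[i]))
  }
  invisible(x)
}

#' Write a dose-response curve as CSV
#'
#' Columns: `fraction`, then one column of steady-state activity per node.
#'
#' @param curve A `dose_response_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  df <- data.frame(fraction = curve$fractions, t(curve$activities),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Single-node knockdown screen
#'
#' Computes the steady state under `context` (the reference; by default a
#' 100% DYRK1A knockdown), then for every species a 100% knockout on top of
#' the context, restarting from the context steady state. Entries are the
#' steady-state activity change of each readout relative to the reference;
#' rows for species already fully knocked down by the context are ~0.
#'
#' @param model A `network_model`.
#' @param context List of [perturbation()] objects defining the reference
#'   condition (default: full DYRK1A knockdown).
#' @param ... Passed on to [run_to_steady_state()].
#' @return Object of class `screen_matrix`: list with `delta` (matrix,
#'   knocked-down node x readout), `reference` (named state under context),
#'   `baseline` (unperturbed steady state), `context` and `converged`
#'   (named flags per screen row).
#' @export
knockdown_screen <- function(model,
                             context = list(perturbation("DYRK1A", "knockdown", 1)),
                             ...) {
  baseline <- run_to_steady_state(model, ...)
  reference <- if (length(context)) {
    perturbed_steady_state(model, context, baseline = baseline, ...)
  } else baseline
  cm <- apply_perturbations(model, context)
  ids <- model$species$id
  delta <- matrix(NA_real_, nrow = length(ids), ncol = length(ids),
                  dimnames = list(knockdown = ids, readout = ids))
  converged <- stats::setNames(logical(length(ids)), ids)
  for (s in ids) {
    km <- apply_knockdown(cm, s, 1)
    ss <- run_to_steady_state(km, y0 = reference$state, ...)
    delta[s, ] <- ss$state - reference$state
    converged[s] <- ss$converged
  }
  structure(list(delta = delta, reference = reference$state,
                 baseline = baseline$state, context = context,
                 converged = converged),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  ctx <- if (length(x$context)) {
    paste(vapply(x$context, format, character(1)), collapse = ", ")
  } else "none"
  cat("knockdown screen (context:", ctx, ")\n")
  print(round(x$delta, 3))
  invisible(x)
}

#' Write a screen matrix as CSV
#'
#' Rows are the knocked-down node, columns the readouts.
#'
#' @param screen A `screen_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  stopifnot(inherits(screen, "screen_matrix"))
  df <- data.frame(knockdown = rownames(screen$delta), screen$delta,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inhibitor dose simulation
#'
#' Simulates graded knockdowns of `target` at the given dose fractions
#' (plus dose 0, the baseline) and reports the steady-state activities of
#' the readout nodes. The defaults reproduce the low/medium/high inhibitor
#' concentrations modeled as 15%, 30% and 45% DYRK1A knockdown.
#'
#' @param model A `network_model`.
#' @param doses Knockdown fractions (default `c(0.15, 0.30, 0.45)`).
#' @param target Species to knock down (default `"DYRK1A"`).
#' @param readouts Readout species (default DNA replication and cyclin D).
#' @param ... Passed on to [run_to_steady_state()].
#' @return A `data.frame` with column `dose` and one column per readout.
#' @export
dose_simulation <- function(model, doses = c(0.15, 0.30, 0.45),
                            target = "DYRK1A",
                            readouts = c("DNA_replication", "CycD"), ...) {
  stopifnot(all(doses >= 0 & doses <= 1))
  species_index(model, c(target, readouts), "species")
  baseline <- run_to_steady_state(model, ...)
  doses <- sort(unique(c(0, doses)))
  rows <- lapply(doses, function(d) {
    st <- if (d == 0) baseline$state else {
      run_to_steady_state(apply_knockdown(model, target, d),
                          y0 = baseline$state, ...)$state
    }
    as.data.frame(c(list(dose = d), as.list(st[readouts])))
  })
  do.call(rbind, rows)
}
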