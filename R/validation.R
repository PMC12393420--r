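# Literature direction-validation harness.
#
# Each curated experiment perturbs one or more nodes, reads out a single
# node, and records the direction of change reported in the primary
# literature. The harness reproduces the protocol in silico (perturb after
# steady state), classifies the predicted direction, and scores accuracy
# per biological context as matches/total in integer percent.

#' Classify a direction of change
#'
#' `increase` if `perturbed - baseline > delta_threshold`, `decrease` if
#' below `-delta_threshold`, otherwise `no_change`. The threshold is an
#' absolute activity difference; 0.01 by default.
#'
#' @param baseline_value,perturbed_value Steady-state activities.
#' @param delta_threshold Absolute activity threshold.
#' @return One of `"increase"`, `"decrease"`, `"no_change"`.
#' @export
classify_direction <- function(baseline_value, perturbed_value,
                               delta_threshold = 0.01) {
  stopifnot(is.finite(baseline_value), is.finite(perturbed_value))
  d <- perturbed_value - baseline_value
  if (d > delta_threshold) "increase"
  else if (d < -delta_threshold) "decrease"
  else "no_change"
}

round_half_up <- function(x) floor(x + 0.5)

#' Run a validation suite against a model
#'
#' For each experiment: bring the model to steady state, apply the
#' experiment's perturbations, re-run to steady state from the baseline
#' state, classify the readout's direction of change, and compare with the
#' literature direction. Accuracy per context is
#' `100 * matches / total`, rounded half-up to integer percent.
#' Experiments whose species are not in the model are marked as errors,
#' excluded from the denominator, and reported with a warning.
#'
#' @param model A `network_model`.
#' @param suite A `validation_suite` (see [parse_validation_suite()]).
#' @param delta_threshold Direction threshold, see [classify_direction()].
#' @param ... Passed on to [run_to_steady_state()].
#' @return Object of class `validation_report`: list with `results` (one
#'   row per experiment), `context_accuracy` (matches, total, accuracy_pct
#'   per context), and `overall` (the same over all scorable experiments).
#' @examples
#' report <- run_validation(build_dyrk1a_model(), cardiomyocyte_suite())
#' report$overall$accuracy_pct
#' @export
run_validation <- function(model, suite, delta_threshold = 0.01, ...) {
  stopifnot(inherits(suite, "validation_suite"), nrow(suite) >= 1)
  baseline <- run_to_steady_state(model, ...)
  results <- do.call(rbind, lapply(seq_len(nrow(suite)), function(i) {
    perts <- suite$perturbations[[i]]
    readout <- suite$readout[i]
    row <- data.frame(id = suite$id[i], readout = readout,
                      context = suite$context[i],
                      expected = suite$expected_direction[i],
                      predicted = NA_character_, delta = NA_real_,
                      match = NA, error = NA_character_,
                      stringsAsFactors = FALSE)
    bad <- setdiff(c(vapply(perts, `[[`, character(1), "target"), readout),
                   model$species$id)
    if (length(bad)) {
      row$error <- paste0("unknown species: ", paste(bad, collapse = ", "))
      warning("experiment '", suite$id[i], "' skipped (", row$error, ")",
              call. = FALSE)
      return(row)
    }
    ss <- perturbed_steady_state(model, perts, baseline = baseline, ...)
    row$delta <- ss$state[[readout]] - baseline$state[[readout]]
    row$predicted <- classify_direction(baseline$state[[readout]],
                                        ss$state[[readout]], delta_threshold)
    row$match <- row$predicted == row$expected
    row
  }))
  scored <- results[is.na(results$error), , drop = FALSE]
  per_ctx <- do.call(rbind, lapply(split(scored, scored$context), function(d) {
    data.frame(context = d$context[1], matches = sum(d$match),
               total = nrow(d),
               accuracy_pct = round_half_up(100 * sum(d$match) / nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_ctx) <- NULL
  overall <- data.frame(matches = sum(scored$match), total = nrow(scored),
                        accuracy_pct = round_half_up(100 * sum(scored$match) /
                                                       max(nrow(scored), 1)))
  structure(list(results = results, context_accuracy = per_ctx,
                 overall = overall),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report:", x$overall$matches, "/", x$overall$total,
      "matches (", x$overall$accuracy_pct, "%)\n")
  for (i in seq_len(nrow(x$context_accuracy))) {
    r <- x$context_accuracy[i, ]
    cat(sprintf("  %-16s %d/%d (%d%%)\n", r$context, r$matches, r$total,
                r$accuracy_pct))
  }
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(
    list(results = report$results, context_accuracy = report$context_accuracy,
         overall = report$overall),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
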