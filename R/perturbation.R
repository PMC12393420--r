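# In-silico perturbation protocols.
#
# Knockdown scales a node's y_max by (1 - fraction); fraction 1 is the full
# knockout (y_max = 0). Overexpression sets y_max = 10 for input nodes, or
# clamps an intermediate/output near 10 by setting y_init = 10 with
# tau = 1e9. Both are pure transformations: the input model is never
# mutated.

#' Construct a perturbation
#'
#' @param target Species id.
#' @param kind `"knockdown"` or `"overexpression"`.
#' @param fraction Knockdown fraction in `[0, 1]` (1 = full knockout;
#'   ignored for overexpression).
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(target, kind = c("knockdown", "overexpression"),
                         fraction = 1) {
  kind <- match.arg(kind)
  assert_species_id(target, "perturbation target")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("knockdown fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(target = target, kind = kind, fraction = as.numeric(fraction)),
            class = "perturbation")
}

#' @export
format.perturbation <- function(x, ...) {
  if (x$kind == "overexpression") paste0("OE:", x$target)
  else paste0("KO:", x$target, ":", x$fraction)
}

#' @export
print.perturbation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Graded knockdown of a node
#'
#' Returns a copy of the model with the target's `y_max` scaled by
#' `(1 - fraction)`; `fraction = 1` reproduces the full knockout
#' (`y_max = 0`). Everything else, including `y_init`, is unchanged: when
#' re-simulated from a steady state the knocked-down node decays from its
#' pre-perturbation activity under the reduced ceiling.
#'
#' @param model A `network_model`.
#' @param target Species id.
#' @param fraction Knockdown fraction in `[0, 1]`.
#' @return A new `network_model`.
#' @export
apply_knockdown <- function(model, target, fraction = 1) {
  i <- species_index(model, target, "knockdown target")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("knockdown fraction must be in [0, 1]", call. = FALSE)
  }
  model$species$y_max[i] <- model$species$y_max[i] * (1 - fraction)
  model
}

#' Overexpression of a node
#'
#' Input nodes: `y_max` is set to 10 (the source rule then drives the node
#' to 10). Intermediate/output nodes: `y_init` is set to 10 and `tau` to
#' 1e9, clamping the node near 10 for the simulated horizon. Applying the
#' protocol twice is idempotent.
#'
#' @param model A `network_model`.
#' @param target Species id.
#' @return A new `network_model`.
#' @export
apply_overexpression <- function(model, target) {
  i <- species_index(model, target, "overexpression target")
  if (model$species$role[i] == "input") {
    model$species$y_max[i] <- 10
  } else {
    model$species$y_init[i] <- 10
    model$species$tau[i] <- 1e9
  }
  model
}

#' Apply a list of perturbations
#'
#' Applies perturbations left to right; the result is order-independent
#' when targets are distinct. A target that appears twice with conflicting
#' kinds is an error.
#'
#' @param model A `network_model`.
#' @param perturbations List of [perturbation()] objects.
#' @return A new `network_model`.
#' @export
apply_perturbations <- function(model, perturbations) {
  if (!length(perturbations)) return(model)
  stopifnot(all(vapply(perturbations, inherits, logical(1), "perturbation")))
  targets <- vapply(perturbations, `[[`, character(1), "target")
  kinds <- vapply(perturbations, `[[`, character(1), "kind")
  for (tg in unique(targets)) {
    if (length(unique(kinds[targets == tg])) > 1L) {
      stop("conflicting perturbation kinds for target '", tg, "'", call. = FALSE)
    }
  }
  for (p in perturbations) {
    model <- switch(p$kind,
                    knockdown = apply_knockdown(model, p$target, p$fraction),
                    overexpression = apply_overexpression(model, p$target))
  }
  model
}

#' Steady state after perturbation
#'
#' Implements the perturb-after-steady-state protocol: the unperturbed
#' model is first brought to steady state (or a precomputed baseline is
#' supplied), the perturbations are applied to the model, and the system is
#' re-integrated from the baseline state (overexpressed intermediate nodes
#' start at their clamp value 10).
#'
#' @param model A `network_model` (unperturbed).
#' @param perturbations List of [perturbation()] objects.
#' @param baseline Optional `steady_state` of the unperturbed model; computed
#'   with [run_to_steady_state()] when omitted.
#' @param ... Passed on to [run_to_steady_state()].
#' @return A `steady_state` of the perturbed model.
#' @export
perturbed_steady_state <- function(model, perturbations, baseline = NULL, ...) {
  if (is.null(baseline)) baseline <- run_to_steady_state(model, ...)
  stopifnot(inherits(baseline, "steady_state"))
  pm <- apply_perturbations(model, perturbations)
  y0 <- baseline$state
  for (p in perturbations) {
    i <- species_index(model, p$target, "perturbation target")
    if (p$kind == "overexpression" && model$species$role[i] != "input") {
      y0[p$target] <- 10
    }
  }
  run_to_steady_state(pm, y0 = y0, ...)
}
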