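# Synthetic networks with known ground truth.
#
# These generators produce small logic-ODE models whose steady states are
# known analytically (cascades, acyclic networks evaluated by fixed-point
# composition), so the ODE engine, the file format and the validation
# harness are all testable without any external input.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixed-point steady state of an acyclic network
#'
#' Evaluates species in topological order: each node's steady-state
#' activity is `y_max` times its OR-combined gate input at the already
#' fixed upstream activities. For acyclic networks this is the unique
#' steady state the ODE relaxes to, computed without any integration.
#'
#' @param model An acyclic `network_model`.
#' @return Named vector of steady-state activities.
#' @export
fixed_point_state <- function(model) {
  ids <- model$species$id
  n <- length(ids)
  deps <- lapply(ids, function(id) {
    unique(unlist(lapply(model$rules, function(r) {
      if (r$product == id) r$regulators$id else character()
    })))
  })
  state <- stats::setNames(rep(NA_real_, n), ids)
  remaining <- rep(TRUE, n)
  for (pass in seq_len(n)) {
    ready <- which(remaining & vapply(deps, function(d) {
      !anyNA(state[d])
    }, logical(1)))
    if (!length(ready)) break
    for (i in ready) {
      g <- node_input(ids[i], model$rules, state)
      state[i] <- model$species$y_max[i] * g
      remaining[i] <- FALSE
    }
    if (!any(remaining)) break
  }
  if (any(remaining)) {
    stop("network is not acyclic (unresolvable: ",
         paste(ids[remaining], collapse = ", "), ")", call. = FALSE)
  }
  state
}

#' Generate a linear cascade with known steady state
#'
#' Builds the chain `=> A0`, `A0 => A1`, ..., `A(depth-1) => A(depth)` with
#' default reaction parameters, and returns the closed-form steady state
#' obtained by composing the normalized Hill activation (independent of the
#' ODE solver): `A0 = input_level`, `A(i+1) = f(A(i))`.
#'
#' @param depth Number of downstream nodes (>= 1).
#' @param input_level The input node's `y_max` (its steady-state activity).
#' @param w,n,ec50 Reaction parameters shared by all links.
#' @return List with elements `model` and `steady_state` (named vector).
#' @examples
#' cas <- generate_cascade(1, input_level = 0.9)
#' cas$steady_state  # A1 ~ 0.9116
#' @export
generate_cascade <- function(depth, input_level = 1, w = 1, n = 1.4, ec50 = 0.5) {
  stopifnot(depth >= 1, input_level >= 0)
  ids <- paste0("A", 0:depth)
  sp <- do.call(rbind, c(
    list(species(ids[1], role = "input", y_max = input_level)),
    lapply(ids[-1][-depth], species),
    list(species(ids[depth + 1], role = "output"))
  ))
  rules <- c(list(reaction_rule(ids[1], w = w, n = n, ec50 = ec50)),
             lapply(seq_len(depth), function(i) {
               reaction_rule(ids[i + 1], ids[i], w = w, n = n, ec50 = ec50)
             }))
  p <- hill_constants(n, ec50)
  ss <- numeric(depth + 1)
  ss[1] <- input_level * w
  for (i in seq_len(depth)) {
    ss[i + 1] <- w * min(max(hill_activation(ss[i], p), 0), 1)
  }
  list(model = network_model(sp, rules),
       steady_state = stats::setNames(ss, ids))
}

sample_rule_params <- function() {
  n <- stats::runif(1, 1, 4)
  list(w = stats::runif(1, 0.2, 1), n = n,
       ec50 = stats::runif(1, 0.1, 0.9 * 0.5^(1 / n)))
}

#' Generate a random network model
#'
#' Reproducible (same seed, same model) generator for structurally valid
#' models of several topology kinds:
#' * `random_acyclic` — nodes in topological order, regulators drawn from
#'   strictly earlier nodes;
#' * `random` — regulators drawn from any node (cycles allowed);
#' * `cascade` — a linear chain with random parameters;
#' * `fan_in` — all inputs converge on one output through a single AND rule;
#' * `feedback` — a 2-4 node ring containing one inhibiting link.
#'
#' Reaction parameters are sampled as `w` in (0.2, 1], `n` in [1, 4] and
#' `ec50` in (0.1, 0.9 * 0.5^(1/n)), spanning the admissible region while
#' avoiding near-singular gains.
#'
#' @param n_species Number of species.
#' @param n_rules Total number of rules; must be at least `n_species` for
#'   the random kinds (one rule per node). Ignored for `cascade`, `fan_in`
#'   and `feedback`.
#' @param seed Integer seed; fully determines the output.
#' @param kind Topology kind, see above.
#' @param p_inhibit Probability that a regulator is inhibiting.
#' @return A validated `network_model`.
#' @export
generate_random_network <- function(n_species, n_rules = n_species, seed = 1,
                                    kind = c("random_acyclic", "random",
                                             "cascade", "fan_in", "feedback"),
                                    p_inhibit = 0.3) {
  kind <- match.arg(kind)
  stopifnot(n_species >= 2)
  with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(n_species))
    if (kind == "cascade") {
      pr <- sample_rule_params()
      return(generate_cascade(n_species - 1,
                              input_level = stats::runif(1, 0.2, 1),
                              w = pr$w, n = pr$n, ec50 = pr$ec50)$model)
    }
    if (kind == "fan_in") {
      sp <- do.call(rbind, c(
        lapply(ids[-n_species], function(id) {
          species(id, role = "input", y_max = stats::runif(1, 0.2, 1))
        }),
        list(species(ids[n_species], role = "output"))
      ))
      pr <- sample_rule_params()
      regs <- paste0(ifelse(stats::runif(n_species - 1) < p_inhibit, "!", ""),
                     ids[-n_species])
      rules <- c(lapply(ids[-n_species], reaction_rule),
                 list(reaction_rule(ids[n_species], regs, w = pr$w, n = pr$n,
                                    ec50 = pr$ec50)))
      return(network_model(sp, rules))
    }
    if (kind == "feedback") {
      n_species <- max(2, min(4, n_species))
      ids <- ids[seq_len(n_species)]
      sp <- do.call(rbind, lapply(ids, function(id) {
        species(id, y_init = stats::runif(1), tau = stats::runif(1, 0.2, 2))
      }))
      rules <- lapply(seq_len(n_species), function(i) {
        upstream <- ids[if (i == 1) n_species else i - 1]
        pr <- sample_rule_params()
        reaction_rule(ids[i], paste0(if (i == 1) "!" else "", upstream),
                      w = pr$w, n = pr$n, ec50 = pr$ec50)
      })
      return(network_model(sp, rules))
    }
    # random / random_acyclic
    n_inputs <- max(1L, round(n_species / 4))
    if (n_rules < n_species) {
      stop("infeasible: n_rules must be >= n_species (one rule per node)",
           call. = FALSE)
    }
    roles <- c(rep("input", n_inputs),
               rep("intermediate", n_species - n_inputs - 1L), "output")
    sp <- do.call(rbind, lapply(seq_len(n_species), function(i) {
      species(ids[i], role = roles[i],
              y_max = if (roles[i] == "input") stats::runif(1, 0.2, 1) else 1,
              tau = stats::runif(1, 0.5, 2))
    }))
    pick_regs <- function(i) {
      pool <- if (kind == "random_acyclic") ids[seq_len(i - 1)] else ids
      k <- sample(seq_len(min(3, length(pool))), 1)
      regs <- sample(pool, k)
      paste0(ifelse(stats::runif(k) < p_inhibit, "!", ""), regs)
    }
    rules <- lapply(seq_len(n_species), function(i) {
      if (roles[i] == "input") return(reaction_rule(ids[i]))
      pr <- sample_rule_params()
      reaction_rule(ids[i], pick_regs(i), w = pr$w, n = pr$n, ec50 = pr$ec50)
    })
    extra <- n_rules - n_species
    if (extra > 0) {
      for (k in seq_len(extra)) {
        i <- sample((n_inputs + 1L):n_species, 1)
        pr <- sample_rule_params()
        rules[[length(rules) + 1L]] <-
          reaction_rule(ids[i], pick_regs(i), w = pr$w, n = pr$n, ec50 = pr$ec50)
      }
    }
    network_model(sp, rules)
  })
}

#' Generate a validation suite with known accuracy
#'
#' Simulates single-node full-knockout experiments on the model, labels
#' `n_match` of them with the direction the model actually predicts and
#' `n_mismatch` with a contradicting direction, so the ground-truth
#' accuracy of the suite is exactly `100 * n_match / (n_match + n_mismatch)`.
#'
#' @param model A `network_model`.
#' @param n_match Number of experiments labeled with the predicted direction.
#' @param n_mismatch Number labeled with a contradicting direction.
#' @param seed Integer seed for the (target, readout) sampling.
#' @param context Context label written into the suite.
#' @param delta_threshold Direction-classification threshold (see
#'   [classify_direction()]).
#' @return A `validation_suite` data frame of `n_match + n_mismatch` rows.
#' @export
generate_validation_suite <- function(model, n_match, n_mismatch, seed = 1,
                                      context = "synthetic",
                                      delta_threshold = 0.01) {
  total <- n_match + n_mismatch
  stopifnot(n_match >= 0, n_mismatch >= 0, total >= 1)
  ids <- model$species$id
  pairs <- expand.grid(target = ids, readout = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target != pairs$readout, ]
  if (nrow(pairs) < total) {
    stop("cannot realize ", total, " experiments: only ", nrow(pairs),
         " distinct (target, readout) pairs", call. = FALSE)
  }
  baseline <- run_to_steady_state(model)
  with_seed(seed, {
    pairs <- pairs[sample.int(nrow(pairs)), ]
    rows <- vector("list", total)
    got <- 0L
    for (j in seq_len(nrow(pairs))) {
      if (got == total) break
      tg <- pairs$target[j]; ro <- pairs$readout[j]
      ss <- perturbed_steady_state(model, list(perturbation(tg, "knockdown", 1)),
                                   baseline = baseline)
      predicted <- classify_direction(baseline$state[[ro]], ss$state[[ro]],
                                      delta_threshold)
      got <- got + 1L
      expected <- if (got <= n_match) predicted else {
        setdiff(c("increase", "decrease"), predicted)[1]
      }
      rows[[got]] <- list(id = sprintf("syn%02d", got),
                          perturbations = list(perturbation(tg, "knockdown", 1)),
                          readout = ro, expected_direction = expected,
                          context = context, source = "synthetic")
    }
    if (got < total) {
      stop("cannot realize requested counts: ran out of candidate experiments",
           call. = FALSE)
    }
    suite <- data.frame(
      id = vapply(rows, `[[`, character(1), "id"),
      readout = vapply(rows, `[[`, character(1), "readout"),
      expected_direction = vapply(rows, `[[`, character(1), "expected_direction"),
      context = vapply(rows, `[[`, character(1), "context"),
      source = vapply(rows, `[[`, character(1), "source"),
      stringsAsFactors = FALSE
    )
    suite$perturbations <- lapply(rows, `[[`, "perturbations")
    class(suite) <- c("validation_suite", "data.frame")
    suite
  })
}
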