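# Data structures for logic-based ODE network models.
#
# A model is a list of species (nodes) and reaction rules (gated edges).
# Species carry the node parameters y_init, y_max and tau; rules carry the
# reaction parameters w, n and ec50 of the normalized Hill activation.

RESERVED_CHARS <- "!&=>,#"

#' Species roles
#'
#' @keywords internal
SPECIES_ROLES <- c("input", "intermediate", "output")

assert_species_id <- function(id, what = "species id") {
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  if (grepl("[[:space:]]", id) || grepl("[!&=>,#]", id)) {
    stop(what, " '", id, "' contains whitespace or a reserved character (",
         RESERVED_CHARS, ")", call. = FALSE)
  }
  invisible(id)
}

#' Create a species table row
#'
#' A species (node) is a molecule or process with a dimensionless activity
#' that relaxes towards `y_max` times its gated input with time constant
#' `tau`. Defaults follow the standard parameterization of logic-based ODE
#' network models: `y_init = 0`, `y_max = 1`, `tau = 1`.
#'
#' @param id Short unique token naming the node. No whitespace and none of
#'   the reserved characters `!&=>,#`.
#' @param name Free-text description (defaults to `id`).
#' @param role One of `"input"`, `"intermediate"`, `"output"`. Input nodes
#'   are driven by a constant source rule; the distinction also selects the
#'   overexpression protocol (see [apply_overexpression()]).
#' @param y_init Initial activity (dimensionless, >= 0).
#' @param y_max Maximal activity (dimensionless, >= 0; 0 encodes a full
#'   knockdown).
#' @param tau Time constant (arbitrary time units, > 0).
#' @return A one-row `data.frame` suitable for [network_model()].
#' @examples
#' species("DYRK1A", role = "input", y_max = 0.9)
#' @export
species <- function(id, name = id, role = "intermediate",
                    y_init = 0, y_max = 1, tau = 1) {
  assert_species_id(id)
  role <- match.arg(role, SPECIES_ROLES)
  if (!is.numeric(y_init) || y_init < 0) stop("y_init must be >= 0", call. = FALSE)
  if (!is.numeric(y_max) || y_max < 0) stop("y_max must be >= 0", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  data.frame(id = id, name = name, role = role,
             y_init = as.numeric(y_init), y_max = as.numeric(y_max),
             tau = as.numeric(tau), stringsAsFactors = FALSE)
}

#' Create a reaction rule
#'
#' A rule contributes flux `w * prod(terms)` to its product node, where each
#' regulator contributes `f(x)` (activating) or `1 - f(x)` (inhibiting) with
#' `f` the normalized Hill activation clamped to `[0, 1]`. Regulators within
#' one rule combine by AND (product); several rules sharing a product
#' combine by OR. An empty regulator list is a constant source rule with
#' flux `w` (the input-node convention).
#'
#' @param product Species id receiving the flux.
#' @param regulators Character vector of regulator species ids; prefix `!`
#'   marks an inhibiting regulator. May be empty (source rule).
#' @param w Reaction weight in `(0, 1]`.
#' @param n Hill coefficient (> 0).
#' @param ec50 Half-maximal input activity; must satisfy `ec50^n < 0.5` for
#'   the normalized Hill gain to be positive.
#' @return An object of class `reaction_rule`.
#' @examples
#' reaction_rule("CycD", "!DYRK1A")
#' reaction_rule("DREAM", c("pLIN52", "!BMyb"))
#' reaction_rule("DYRK1A", character())  # source rule
#' @export
reaction_rule <- function(product, regulators = character(),
                          w = 1, n = 1.4, ec50 = 0.5) {
  assert_species_id(product, "rule product")
  regulators <- as.character(regulators)
  sign <- ifelse(startsWith(regulators, "!"), "inhibiting", "activating")
  ids <- sub("^!", "", regulators)
  for (rid in ids) assert_species_id(rid, "regulator id")
  if (!is.numeric(w) || w <= 0 || w > 1) {
    stop("reaction weight w must be in (0, 1], got ", w, call. = FALSE)
  }
  if (!is.numeric(n) || n <= 0) stop("Hill coefficient n must be > 0", call. = FALSE)
  if (!is.numeric(ec50) || ec50 <= 0 || ec50^n >= 0.5) {
    stop("ec50 must satisfy 0 < ec50 and ec50^n < 0.5 (got ec50 = ", ec50,
         ", n = ", n, ")", call. = FALSE)
  }
  structure(
    list(regulators = data.frame(id = ids, sign = sign, stringsAsFactors = FALSE),
         product = product, w = as.numeric(w), n = as.numeric(n),
         ec50 = as.numeric(ec50)),
    class = "reaction_rule"
  )
}

#' Assemble a network model
#'
#' @param species A `data.frame` of species rows (rbind of [species()]
#'   calls, or an equivalent table with columns `id`, `name`, `role`,
#'   `y_init`, `y_max`, `tau`).
#' @param rules A list of [reaction_rule()] objects.
#' @param check If `TRUE` (default), enforce the full set of structural
#'   invariants via [validate_network_model()]; set to `FALSE` only for
#'   deliberately irregular models (e.g. isolated nodes in engine tests).
#' @return An object of class `network_model`.
#' @seealso [parse_model()], [write_model()], [build_dyrk1a_model()]
#' @export
network_model <- function(species, rules, check = TRUE) {
  stopifnot(is.data.frame(species), is.list(rules))
  rownames(species) <- NULL
  model <- structure(list(species = species, rules = rules),
                     class = "network_model")
  if (check) validate_network_model(model)
  model
}

#' Validate a network model
#'
#' Checks every structural invariant: unique species ids, parameter ranges,
#' that every rule product and regulator is a declared species, that input
#' nodes have exactly one constant source rule, and that every intermediate
#' or output node has at least one rule with at least one regulator.
#'
#' @param model A `network_model`.
#' @return The model, invisibly; otherwise an error describing every
#'   violation found.
#' @export
validate_network_model <- function(model) {
  sp <- model$species
  errs <- character()
  if (anyDuplicated(sp$id)) {
    errs <- c(errs, paste0("duplicate species id: ",
                           paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  }
  if (any(sp$tau <= 0)) errs <- c(errs, "tau must be > 0 for all species")
  if (any(sp$y_max < 0)) errs <- c(errs, "y_max must be >= 0 for all species")
  if (any(sp$y_init < 0)) errs <- c(errs, "y_init must be >= 0 for all species")
  if (!all(sp$role %in% SPECIES_ROLES)) {
    errs <- c(errs, "species role must be one of input/intermediate/output")
  }
  for (i in seq_along(model$rules)) {
    rule <- model$rules[[i]]
    if (!inherits(rule, "reaction_rule")) {
      errs <- c(errs, paste0("rule ", i, " is not a reaction_rule"))
      next
    }
    if (!rule$product %in% sp$id) {
      errs <- c(errs, paste0("rule ", i, " ('", format(rule), "'): undeclared product '",
                             rule$product, "'"))
    }
    missing <- setdiff(rule$regulators$id, sp$id)
    if (length(missing)) {
      errs <- c(errs, paste0("rule ", i, " ('", format(rule), "'): undeclared regulator '",
                             paste(missing, collapse = "', '"), "'"))
    }
  }
  products <- vapply(model$rules, function(r) r$product, character(1))
  n_regs <- vapply(model$rules, function(r) nrow(r$regulators), integer(1))
  for (i in seq_len(nrow(sp))) {
    id <- sp$id[i]
    own <- which(products == id)
    if (sp$role[i] == "input") {
      if (length(own) != 1L || n_regs[own] != 0L) {
        errs <- c(errs, paste0("input species '", id,
                               "' must have exactly one source rule (empty regulator list)"))
      }
    } else {
      if (length(own) == 0L || all(n_regs[own] == 0L)) {
        errs <- c(errs, paste0("non-input species '", id,
                               "' must have at least one rule with a regulator"))
      }
    }
  }
  if (length(errs)) {
    stop("invalid network model:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
format.reaction_rule <- function(x, ...) {
  lhs <- paste(ifelse(x$regulators$sign == "inhibiting",
                      paste0("!", x$regulators$id), x$regulators$id),
               collapse = " & ")
  trimws(paste(lhs, "=>", x$product))
}

#' @export
print.reaction_rule <- function(x, ...) {
  cat(format(x), sprintf("  [w=%g, n=%g, ec50=%g]\n", x$w, x$n, x$ec50))
  invisible(x)
}

#' @export
print.network_model <- function(x, ...) {
  cat("Logic-based ODE network model:", nrow(x$species), "species,",
      length(x$rules), "rules\n")
  roles <- table(factor(x$species$role, levels = SPECIES_ROLES))
  cat(sprintf("  %d input, %d intermediate, %d output\n",
              roles[["input"]], roles[["intermediate"]], roles[["output"]]))
  cat("  rules:\n")
  for (r in x$rules) cat("    ", format(r), "\n", sep = "")
  invisible(x)
}

species_index <- function(model, id, context = "species") {
  idx <- match(id, model$species$id)
  if (anyNA(idx)) {
    stop("unknown ", context, ": '", paste(id[is.na(idx)], collapse = "', '"),
         "'", call. = FALSE)
  }
  idx
}
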