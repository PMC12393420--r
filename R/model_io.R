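# Plain-text model and validation-suite files.
#
# Model file: TSV with two sections introduced by the marker lines
# `#species` and `#rules`, each followed by a header row. Other `#` lines
# and blank lines are comments. Rule syntax follows the usual convention of
# logic-based network tools: `!X & Y => Z` (`!` inhibiting regulator, `&`
# AND within a rule, one product per rule; several rules with the same
# product OR-combine). Ids are case-sensitive. Empty numeric cells take the
# documented defaults (y_init=0, y_max=1, tau=1; w=1, n=1.4, ec50=0.5).

SPECIES_HEADER <- c("id", "name", "role", "y_init", "y_max", "tau")
RULES_HEADER <- c("rule", "w", "n", "ec50")

#' Parse a network model from text
#'
#' @param text Model-file content: a single string or a character vector of
#'   lines (see the package vignette for the dialect).
#' @return A validated `network_model`.
#' @examples
#' m <- parse_model(c(
#'   "#species",
#'   "id\tname\trole\ty_init\ty_max\ttau",
#'   "A\tA\tinput\t0\t0.9\t1",
#'   "B\tB\tintermediate\t\t\t",
#'   "#rules",
#'   "rule\tw\tn\tec50",
#'   "=> A\t\t\t",
#'   "A => B\t\t\t"
#' ))
#' @seealso [read_model()], [write_model()]
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- data.frame(no = seq_along(text), raw = text, stringsAsFactors = FALSE)
  section <- NA_character_
  sp_rows <- list()
  rule_rows <- list()
  expect_header <- FALSE
  for (k in seq_len(nrow(lines))) {
    raw <- lines$raw[k]
    if (grepl("^#[[:space:]]*species[[:space:]]*$", raw)) {
      section <- "species"; expect_header <- TRUE; next
    }
    if (grepl("^#[[:space:]]*rules[[:space:]]*$", raw)) {
      section <- "rules"; expect_header <- TRUE; next
    }
    line <- sub("#.*$", "", raw)
    if (!nzchar(trimws(line))) next
    if (is.na(section)) {
      stop("line ", k, ": content before the first section marker (#species/#rules)",
           call. = FALSE)
    }
    fields <- trimws(strsplit(line, "\t", fixed = TRUE)[[1]])
    if (expect_header) {
      want <- if (section == "species") SPECIES_HEADER else RULES_HEADER
      got <- fields[nzchar(fields)]
      if (!identical(got[seq_along(want)], want)) {
        stop("line ", k, ": expected header '", paste(want, collapse = "\t"),
             "' for section #", section, call. = FALSE)
      }
      expect_header <- FALSE
      next
    }
    if (section == "species") sp_rows[[length(sp_rows) + 1L]] <- list(no = k, fields = fields)
    else rule_rows[[length(rule_rows) + 1L]] <- list(no = k, fields = fields)
  }
  if (!length(sp_rows)) stop("model file declares no species", call. = FALSE)

  num_or <- function(x, default) {
    if (length(x) == 0L || is.na(x) || !nzchar(x)) return(default)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("not a number: '", x, "'", call. = FALSE)
    v
  }
  sp <- do.call(rbind, lapply(sp_rows, function(row) {
    f <- row$fields
    tryCatch(
      species(id = f[1],
              name = if (length(f) >= 2 && nzchar(f[2])) f[2] else f[1],
              role = if (length(f) >= 3 && nzchar(f[3])) f[3] else "intermediate",
              y_init = num_or(f[4], 0), y_max = num_or(f[5], 1),
              tau = num_or(f[6], 1)),
      error = function(e) stop("line ", row$no, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }))
  rules <- lapply(rule_rows, function(row) {
    f <- row$fields
    tryCatch({
      parsed <- parse_rule_text(f[1])
      reaction_rule(product = parsed$product, regulators = parsed$regulators,
                    w = num_or(f[2], 1), n = num_or(f[3], 1.4),
                    ec50 = num_or(f[4], 0.5))
    }, error = function(e) stop("line ", row$no, ": ", conditionMessage(e),
                                call. = FALSE))
  })
  # name undeclared ids with their line numbers before full validation
  declared <- sp$id
  for (i in seq_along(rules)) {
    bad <- setdiff(c(rules[[i]]$product, rules[[i]]$regulators$id), declared)
    if (length(bad)) {
      stop("line ", rule_rows[[i]]$no, ": rule '", format(rules[[i]]),
           "' references undeclared species '", paste(bad, collapse = "', '"),
           "'", call. = FALSE)
    }
  }
  network_model(sp, rules)
}

parse_rule_text <- function(txt) {
  if (is.na(txt) || !grepl("=>", txt, fixed = TRUE)) {
    stop("malformed rule '", txt, "': expected '[!X [& !Y ...]] => Z'",
         call. = FALSE)
  }
  parts <- strsplit(txt, "=>", fixed = TRUE)[[1]]
  if (length(parts) > 2L) stop("malformed rule '", txt, "': multiple '=>'", call. = FALSE)
  product <- trimws(parts[2])
  lhs <- trimws(parts[1])
  regulators <- character()
  if (nzchar(lhs)) {
    regulators <- trimws(strsplit(lhs, "&", fixed = TRUE)[[1]])
    if (any(!nzchar(regulators))) {
      stop("malformed rule '", txt, "': empty regulator term", call. = FALSE)
    }
  }
  list(product = product, regulators = regulators)
}

#' Read a network model from a file
#'
#' @param path Path to a model file in the dialect of [parse_model()].
#' @return A validated `network_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  parse_model(readLines(path, warn = FALSE))
}

# shortest decimal representation that round-trips exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

#' Serialize a network model
#'
#' Output is deterministic (species then rules, in declaration order) and
#' parses back to an identical model with [parse_model()].
#'
#' @param model A `network_model`.
#' @param path Optional output file path.
#' @return The serialized lines as a character vector (invisibly when
#'   `path` is given).
#' @export
write_model <- function(model, path = NULL) {
  validate_network_model(model)
  sp <- model$species
  lines <- c(
    "#species",
    paste(SPECIES_HEADER, collapse = "\t"),
    sprintf("%s\t%s\t%s\t%s\t%s\t%s", sp$id, sp$name, sp$role,
            fmt_num(sp$y_init), fmt_num(sp$y_max), fmt_num(sp$tau)),
    "#rules",
    paste(RULES_HEADER, collapse = "\t"),
    vapply(model$rules, function(r) {
      sprintf("%s\t%s\t%s\t%s", format(r), fmt_num(r$w), fmt_num(r$n),
              fmt_num(r$ec50))
    }, character(1))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

VALIDATION_HEADER <- c("id", "perturbation", "readout", "expected_direction",
                       "context", "source")
DIRECTIONS <- c("increase", "decrease", "no_change")

#' Parse a perturbation specification string
#'
#' Grammar: `KO:<species>[:<fraction>]` (fraction defaults to 1, a full
#' knockdown) or `OE:<species>`; several perturbations separated by `;`.
#'
#' @param spec A single specification string.
#' @return A list of perturbation objects (see [perturbation()]).
#' @examples
#' parse_perturbation_spec("KO:DYRK1A:0.3; OE:CDK2")
#' @export
parse_perturbation_spec <- function(spec) {
  parts <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  lapply(parts, function(p) {
    tok <- trimws(strsplit(p, ":", fixed = TRUE)[[1]])
    if (length(tok) < 2L || !tok[1] %in% c("KO", "OE")) {
      stop("malformed perturbation spec '", p,
           "': expected 'KO:<species>[:<fraction>]' or 'OE:<species>'",
           call. = FALSE)
    }
    if (tok[1] == "OE") {
      if (length(tok) != 2L) {
        stop("malformed perturbation spec '", p, "': OE takes no fraction",
             call. = FALSE)
      }
      perturbation(tok[2], "overexpression")
    } else {
      frac <- if (length(tok) >= 3L) suppressWarnings(as.numeric(tok[3])) else 1
      if (is.na(frac) || frac < 0 || frac > 1) {
        stop("malformed perturbation spec '", p,
             "': knockdown fraction must be in [0, 1]", call. = FALSE)
      }
      perturbation(tok[2], "knockdown", frac)
    }
  })
}

#' Parse a validation suite from text
#'
#' A suite is a TSV table with header
#' `id  perturbation  readout  expected_direction  context  source`; each
#' row is one literature experiment: apply the perturbations, read out one
#' node, and compare the predicted direction of change against
#' `expected_direction` (one of `increase`, `decrease`, `no_change`).
#'
#' @param text File content (single string or vector of lines).
#' @return A `data.frame` of class `validation_suite` with a list-column
#'   `perturbations`; zero rows for an empty file.
#' @seealso [run_validation()], [read_validation_suite()]
#' @export
parse_validation_suite <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  empty <- structure(
    data.frame(id = character(), readout = character(),
               expected_direction = character(), context = character(),
               source = character(), stringsAsFactors = FALSE),
    class = c("validation_suite", "data.frame")
  )
  empty$perturbations <- list()
  keep <- !grepl("^[[:space:]]*(#|$)", text)
  text <- text[keep]
  linenos <- which(keep)
  if (!length(text)) return(empty)
  header <- trimws(strsplit(text[1], "\t", fixed = TRUE)[[1]])
  if (!identical(header[seq_along(VALIDATION_HEADER)], VALIDATION_HEADER)) {
    stop("validation suite: expected header '",
         paste(VALIDATION_HEADER, collapse = "\t"), "'", call. = FALSE)
  }
  if (length(text) == 1L) return(empty)
  rows <- lapply(seq.int(2L, length(text)), function(k) {
    f <- trimws(strsplit(text[k], "\t", fixed = TRUE)[[1]])
    length(f) <- 6L
    f[is.na(f)] <- ""
    if (!f[4] %in% DIRECTIONS) {
      stop("line ", linenos[k], ": unknown direction '", f[4], "' (expected ",
           paste(DIRECTIONS, collapse = "/"), ")", call. = FALSE)
    }
    perts <- tryCatch(parse_perturbation_spec(f[2]),
                      error = function(e) stop("line ", linenos[k], ": ",
                                               conditionMessage(e), call. = FALSE))
    list(id = f[1], perturbations = perts, readout = f[3],
         expected_direction = f[4], context = f[5], source = f[6])
  })
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
}

#' Read a validation suite from a file
#'
#' @param path Path to a suite TSV (see [parse_validation_suite()]).
#' @return A `validation_suite` data frame.
#' @export
read_validation_suite <- function(path) {
  if (!file.exists(path)) stop("validation suite not found: ", path, call. = FALSE)
  parse_validation_suite(readLines(path, warn = FALSE))
}

#' Serialize a validation suite
#'
#' @param suite A `validation_suite` data frame.
#' @param path Optional output file path.
#' @return The serialized lines (invisibly when `path` is given).
#' @export
write_validation_suite <- function(suite, path = NULL) {
  fmt_pert <- function(perts) {
    paste(vapply(perts, function(p) {
      if (p$kind == "overexpression") paste0("OE:", p$target)
      else if (p$fraction == 1) paste0("KO:", p$target)
      else paste0("KO:", p$target, ":", fmt_num(p$fraction))
    }, character(1)), collapse = ";")
  }
  lines <- c(paste(VALIDATION_HEADER, collapse = "\t"),
             if (nrow(suite)) sprintf("%s\t%s\t%s\t%s\t%s\t%s", suite$id,
                                      vapply(suite$perturbations, fmt_pert, character(1)),
                                      suite$readout, suite$expected_direction,
                                      suite$context, suite$source))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
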