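# The shipped DYRK1A cell-cycle network.
#
# The network is installed as a plain-text model file so it can be diffed,
# edited or replaced without code changes. It encodes the curated
# mechanisms of DYRK1A-mediated quiescence: DYRK1A phosphorylates LIN52
# (S28), nucleating DREAM complex assembly (with B-Myb competing for the
# MuvB core); DYRK1A directly destabilizes cyclin D; DREAM represses the
# activator E2Fs; E2Fs transactivate cyclin E; cyclin E/CDK2 and cyclin D
# redundantly inactivate RB1; and hypophosphorylated RB1 blocks E2F-driven
# transcription of the DNA-replication program.

#' Path to the packaged DYRK1A cell-cycle model file
#'
#' @return Path to `models/dyrk1a_cellcycle.tsv` inside the installed
#'   package.
#' @export
dyrk1a_model_path <- function() {
  system.file("models", "dyrk1a_cellcycle.tsv", package = "dyrknet",
              mustWork = TRUE)
}

#' The curated DYRK1A cell-cycle network
#'
#' Reads the packaged model asset. All reactions use the default
#' parameters (w = 1 unless noted, n = 1.4, ec50 = 0.5) and all nodes the
#' default y_init = 0, y_max = 1, tau = 1, except the input activities
#' calibrated to give a responsive quiescent baseline: DYRK1A y_max = 0.9,
#' B-Myb y_max = 0.1, CDK2 y_max = 0.9.
#'
#' @return A `network_model` with 13 species.
#' @examples
#' m <- build_dyrk1a_model()
#' run_to_steady_state(m)
#' @export
build_dyrk1a_model <- function() {
  read_model(dyrk1a_model_path())
}

#' Baseline steady state of the DYRK1A network
#'
#' Integrates the shipped model from y_init = 0 until every node changes by
#' less than 0.05% per time unit. The baseline is the quiescent
#' cardiomyocyte state: DREAM and RB1 high, cyclins, E2Fs and DNA
#' replication low.
#'
#' @param model The model (defaults to [build_dyrk1a_model()]).
#' @param ... Passed on to [run_to_steady_state()].
#' @return A converged `steady_state`; an error if convergence fails.
#' @export
baseline_steady_state <- function(model = build_dyrk1a_model(), ...) {
  ss <- run_to_steady_state(model, ...)
  if (!ss$converged) {
    stop("baseline did not converge within max_time (max change ",
         signif(ss$max_rel_change, 3), ")", call. = FALSE)
  }
  ss
}

#' The packaged cardiomyocyte validation suite
#'
#' Five literature-anchored direction experiments in cardiomyocytes:
#' DYRK1A knockout increases DNA replication and cyclin D; DYRK1A
#' overexpression decreases DNA replication and E2F1; CDK2 overexpression
#' increases DNA replication.
#'
#' @return A `validation_suite` data frame (5 rows).
#' @seealso [run_validation()]
#' @export
cardiomyocyte_suite <- function() {
  read_validation_suite(system.file("validation", "cardiomyocyte_suite.tsv",
                                    package = "dyrknet", mustWork = TRUE))
}

#' Path to the cancer validation-suite template
#'
#' A header-only template documenting the suite file format, intended for
#' transcribing cancer-literature perturbation experiments so they can be
#' scored with [run_validation()] alongside the cardiomyocyte suite.
#'
#' @return Path to `validation/cancer_suite_template.tsv`.
#' @export
cancer_suite_template_path <- function() {
  system.file("validation", "cancer_suite_template.tsv", package = "dyrknet",
              mustWork = TRUE)
}
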