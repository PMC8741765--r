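#' Published reference values of the original clinical study
#'
#' The original tongue-imaging study reports classifier performance on its
#' private 2,675-participant cohort; those printed values cannot be
#' recomputed from data but serve as inputs for arithmetic consistency
#' checks (metric identities, model-vs-model deltas, cohort accounting).
#' `published_performance()` returns the printed comparison-table rows
#' (accuracy, precision, sensitivity, specificity, F1, error rate per
#' model); `acquisition_phases()` the four seasonal data-collection phases
#' with their DM / non-DM participant counts.
#'
#' @return A data.frame.
#' @rdname published
#' @export
published_performance <- function() {
  utils::read.csv(system.file("extdata", "published_performance.csv",
                              package = "tonguenet"),
                  stringsAsFactors = FALSE)
}

#' @rdname published
#' @export
acquisition_phases <- function() {
  utils::read.csv(system.file("extdata", "acquisition_phases.csv",
                              package = "tonguenet"),
                  stringsAsFactors = FALSE)
}
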