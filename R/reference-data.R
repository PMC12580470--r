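# Published reference estimates shipped with the package.

#' Published RAI and trail-index reference estimates
#'
#' Pooled RAI (events per 100 trap-days) and trail-index point estimates
#' for five mammal species by hunting-effort stratum, from a published
#' 122-camera paired trail/forest survey in the Bavarian Forest. Used in
#' worked examples and as the input for desk-scale reproduction of the
#' trail-index arithmetic.
#'
#' @return Data frame: `species`, `effort`, `rai_trail`, `rai_forest`,
#'   `trail_index` (printed values, 2 dp).
#' @export
reference_rai_estimates <- function() {
  utils::read.csv(
    system.file("extdata", "reference_rai_estimates.csv",
      package = "dielshift", mustWork = TRUE
    ),
    comment.char = "#", stringsAsFactors = FALSE
  )
}

#' Published independent-event count reference table
#'
#' Stratum event sums over the 61 trail and 61 forest cameras and the
#' printed per-camera means for the same survey.
#'
#' @return Data frame: `species`, `effort`, `placement`, `sum_events`,
#'   `mean_events`.
#' @export
reference_event_counts <- function() {
  utils::read.csv(
    system.file("extdata", "reference_event_counts.csv",
      package = "dielshift", mustWork = TRUE
    ),
    comment.char = "#", stringsAsFactors = FALSE
  )
}
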