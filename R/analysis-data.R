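#' Assemble the individual-success analysis table
#'
#' Joins per-fish migration outcomes with the two individual covariates —
#' body condition (pooled log-mass residual) and tag burden — restricted to
#' fish with complete biometrics that entered the study. This is the input
#' for [fit_individual_success()].
#'
#' @param detections Filtered detections, or a `smolt_sim` object (then
#'   `fish` and `receivers` are taken from it and the raw detections are
#'   filtered first).
#' @param fish Fish records (ignored when a `smolt_sim` is given).
#' @param receivers Receiver deployments (ignored when a `smolt_sim` is
#'   given).
#' @return Data frame: `fish_id`, `river`, `year`, `succeeded`, `condition`,
#'   `tag_burden`.
#' @examples
#' sim <- simulate_study(sim_config(n_rivers = 2, n_fish_per_river = 25))
#' head(individual_success_data(sim))
#' @export
individual_success_data <- function(detections, fish = NULL, receivers = NULL) {
  if (inherits(detections, "smolt_sim")) {
    sim <- detections
    fish <- sim$fish
    receivers <- sim$receivers
    detections <- filter_detections(sim$detections, fish)$detections
  }
  fishc <- drop_incomplete_biometrics(fish)
  fishc$condition <- body_condition(fishc)$residuals
  fishc$tag_burden <- tag_burden(fishc)
  out <- classify_outcomes(detections, fish, receivers)
  dat <- merge(out[out$entered, c("fish_id", "river", "year", "succeeded")],
               fishc[, c("fish_id", "condition", "tag_burden")],
               by = "fish_id")
  dat[order(dat$fish_id), , drop = FALSE]
}
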