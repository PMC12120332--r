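#' Packaged study summary tables
#'
#' Transcriptions of the published per-cohort summary tables of a
#' multi-river acoustic-telemetry study of Atlantic salmon smolt migration
#' across 22 rivers in Scotland, England, Ireland and Northern Ireland
#' (2019-2022), shipped with the package as worked-example inputs.
#'
#' `tagging_summary()` holds, per river-year cohort: release coordinates,
#' tag type, number tagged, tagging dates, and the cohort means and SDs of
#' fork length (mm), mass (g), body condition (pooled log-mass residual) and
#' tag burden (percent).
#'
#' `migration_success_table()` holds, per river-year: population migration
#' success, the rate of migration success (proportion per km) and the mean
#' and SD of migration speed (km per day).
#'
#' @return A data frame.
#' @examples
#' t2 <- migration_success_table()
#' t2[which.max(t2$migration_success), ]
#' @name study_tables
NULL

study_file <- function(name) {
  path <- system.file("extdata", name, package = "smoltrak")
  if (path == "") stop("packaged table ", name, " not found", call. = FALSE)
  path
}

#' @rdname study_tables
#' @export
tagging_summary <- function() {
  read.csv(study_file("tagging_summary.csv"), stringsAsFactors = FALSE,
           check.names = TRUE)
}

#' @rdname study_tables
#' @export
migration_success_table <- function() {
  read.csv(study_file("migration_success.csv"), stringsAsFactors = FALSE)
}
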