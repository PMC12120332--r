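#' Classify per-fish migration outcomes
#'
#' For every tagged fish: whether it was detected at the first (below-release)
#' receiver, whether it was detected at the last (river mouth) receiver, and
#' the derived study entry and success states. A fish detected at the last
#' receiver but never at the first demonstrably passed the first receiver
#' undetected and is counted as both entered and succeeded. Migration
#' duration is the time from the last detection at the first receiver to the
#' first detection at the last receiver; speed is the receiver-to-receiver
#' river distance divided by duration. A fish whose last-receiver detection
#' precedes its first-receiver detection is flagged `inconsistent`: it keeps
#' its success state but contributes no duration or speed.
#'
#' @param detections Filtered detection data frame.
#' @param fish Fish-record data frame (one row per tagged fish).
#' @param receivers Receiver-deployment data frame (one first and one last
#'   receiver per river-year).
#' @return A data frame with one row per fish: `fish_id`, `river`, `year`,
#'   `detected_first`, `detected_last`, `entered`, `succeeded`,
#'   `duration_days`, `speed_km_per_day`, `inconsistent`.
#' @export
classify_outcomes <- function(detections, fish, receivers) {
  validate_receivers(receivers)
  stopifnot(all(c("tag_code", "receiver_id", "timestamp") %in% names(detections)))

  rec_key <- paste(receivers$river, receivers$year)
  first_id <- setNames(receivers$receiver_id[receivers$role == "first"],
                       rec_key[receivers$role == "first"])
  last_id <- setNames(receivers$receiver_id[receivers$role == "last"],
                      rec_key[receivers$role == "last"])
  dist_first <- setNames(receivers$river_km[receivers$role == "first"],
                         rec_key[receivers$role == "first"])
  dist_last <- setNames(receivers$river_km[receivers$role == "last"],
                        rec_key[receivers$role == "last"])

  out <- fish[, c("fish_id", "tag_code", "river", "year")]
  fkey <- paste(out$river, out$year)
  if (!all(fkey %in% names(first_id)))
    stop("fish present for river-years with no receiver deployment", call. = FALSE)

  d_by_tag <- split(detections[, c("receiver_id", "timestamp")], detections$tag_code)

  n <- nrow(out)
  detected_first <- logical(n); detected_last <- logical(n)
  t_first_last <- rep(as.POSIXct(NA, tz = "UTC"), n)
  t_last_first <- rep(as.POSIXct(NA, tz = "UTC"), n)
  for (i in seq_len(n)) {
    d <- d_by_tag[[out$tag_code[i]]]
    if (is.null(d)) next
    at_first <- d$timestamp[d$receiver_id == first_id[[fkey[i]]]]
    at_last <- d$timestamp[d$receiver_id == last_id[[fkey[i]]]]
    if (length(at_first)) {
      detected_first[i] <- TRUE
      t_first_last[i] <- max(at_first)
    }
    if (length(at_last)) {
      detected_last[i] <- TRUE
      t_last_first[i] <- min(at_last)
    }
  }
  duration <- as.numeric(difftime(t_last_first, t_first_last, units = "days"))
  inconsistent <- detected_first & detected_last & !is.na(duration) & duration <= 0
  duration[!detected_first | !detected_last | inconsistent] <- NA_real_
  reach <- dist_last[fkey] - dist_first[fkey]
  speed <- unname(reach) / duration

  data.frame(fish_id = out$fish_id, river = out$river, year = out$year,
             detected_first = detected_first, detected_last = detected_last,
             entered = detected_first | detected_last,
             succeeded = detected_last,
             duration_days = duration, speed_km_per_day = speed,
             inconsistent = inconsistent, stringsAsFactors = FALSE)
}

#' Release-site fallback for low first-receiver efficiency
#'
#' When the first receiver of a river-year performed too poorly to audit
#' study entry (efficiency below `threshold`), every released fish of that
#' river-year is deemed to have entered the study at the release site, so the
#' success denominator becomes the number released.
#'
#' @param outcomes Outcome table from [classify_outcomes()] (one row per
#'   released fish).
#' @param de_first First-receiver detection efficiency for this group.
#' @param threshold Efficiency below which the fallback applies (default 0.5).
#' @return `outcomes`, with `entered` set to `TRUE` for all rows when the
#'   fallback applies; unchanged otherwise.
#' @export
release_fallback <- function(outcomes, de_first, threshold = 0.5) {
  if (is.na(de_first) || de_first >= threshold) return(outcomes)
  outcomes$entered <- TRUE
  outcomes
}

#' First-receiver detection efficiency
#'
#' The number of fish detected at the first receiver divided by the number
#' known to have passed it. Passage is certified by the downstream audit:
#' the estimator is computed over the fish detected at the last receiver
#' (every one of which must have passed the first), as the fraction of them
#' the first receiver detected. Restricting to the audited subset keeps the
#' estimator unbiased even when the audit receiver itself misses fish; a
#' fish detected only at the first receiver certifies its own passage and
#' carries no information about the miss rate. The estimate is still a
#' minimum-information one: fish passing undetected at both receivers are
#' invisible.
#'
#' @param outcomes Outcome table from [classify_outcomes()] for one
#'   river-year.
#' @return A proportion in \[0, 1\], or `NA` (with a warning) when no fish's
#'   passage was audited downstream.
#' @export
detection_efficiency_first <- function(outcomes) {
  audited <- outcomes$detected_last
  if (!any(audited)) {
    warning("no fish known to have passed the first receiver")
    return(NA_real_)
  }
  sum(outcomes$detected_first & audited) / sum(audited)
}

#' Last-receiver detection efficiency from a marine audit
#'
#' Same minimum-estimate construction as
#' [detection_efficiency_first()], with marine receivers seaward of the river
#' mouth acting as the downstream audit: among fish detected at sea (all of
#' which must have passed the river mouth), the fraction the last river
#' receiver detected.
#'
#' @param outcomes Outcome table for one river-year.
#' @param marine_detections Detection data frame from marine receivers, or
#'   `NULL` when no marine array exists (returns `NA`).
#' @param fish Fish-record table used to map marine tag codes to fish ids.
#' @return A proportion in \[0, 1\], or `NA` when unavailable.
#' @export
detection_efficiency_last <- function(outcomes, marine_detections, fish) {
  if (is.null(marine_detections) || nrow(marine_detections) == 0)
    return(NA_real_)
  marine_ids <- unique(fish$fish_id[fish$tag_code %in% marine_detections$tag_code])
  at_sea <- outcomes$fish_id %in% marine_ids
  if (!any(at_sea)) return(NA_real_)
  sum(outcomes$detected_last & at_sea) / sum(at_sea)
}

#' Detection-corrected migration success
#'
#' The raw population success — fish detected leaving the river as a
#' proportion of fish detected entering the study — is a minimum estimate:
#' with imperfect receivers it underestimates true survival. When both
#' receiver efficiencies have been measured, the mark-recapture correction
#' divides each count by its receiver's efficiency:
#' `(n_last / de_last) / (n_first / de_first)`, a consistent estimator of
#' the true proportion surviving the reach.
#'
#' @param outcomes Outcome table for one river-year (needs `detected_first`
#'   and `detected_last`).
#' @param de_first,de_last Measured detection efficiencies of the two
#'   receivers, in (0, 1].
#' @return Corrected success proportion (may exceed 1 by sampling noise in
#'   small cohorts; capped at 1).
#' @export
corrected_migration_success <- function(outcomes, de_first, de_last) {
  if (is.na(de_first) || is.na(de_last) || de_first <= 0 || de_last <= 0)
    return(NA_real_)
  n_first <- sum(outcomes$detected_first)
  n_last <- sum(outcomes$detected_last)
  if (n_first == 0) return(NA_real_)
  min(1, (n_last / de_last) / (n_first / de_first))
}

#' Rate of migration success (per-kilometre survival)
#'
#' The distance-standardized success statistic: the geometric mean, per river
#' kilometre, of the proportion surviving each kilometre, computed as
#' `success^(1/distance)` (proportion per km). A success of exactly 0 maps to
#' rate 0 (the limiting value).
#'
#' @param success Population migration success, in \[0, 1\].
#' @param distance_km River distance between first and last receivers, > 0.
#' @return Rate of migration success, proportion per km.
#' @examples
#' rate_of_migration_success(0.729, 3) # 0.9
#' @export
rate_of_migration_success <- function(success, distance_km) {
  if (any(distance_km <= 0)) stop("distance_km must be > 0", call. = FALSE)
  if (any(success < 0 | success > 1, na.rm = TRUE))
    stop("success must lie in [0, 1]", call. = FALSE)
  ifelse(success == 0, 0, success^(1 / distance_km))
}

#' Standardize a per-km rate to a common river distance
#'
#' Projects the per-km survival rate over a common reference distance,
#' `rate^standard_km`, so rivers of different lengths are comparable. The
#' emulated study's mean river distance is 31.52 km as used for its
#' standardized figures; 31.54 km is also quoted in its methods, and either
#' may be passed.
#'
#' @param rate_per_km Rate of migration success, in \[0, 1\].
#' @param standard_km Reference distance, default 31.52 km.
#' @return Standardized success proportion over `standard_km`.
#' @examples
#' standardize_rate(0.98, 31.52)
#' @export
standardize_rate <- function(rate_per_km, standard_km = 31.52) {
  if (any(rate_per_km < 0 | rate_per_km > 1, na.rm = TRUE))
    stop("rate_per_km must lie in [0, 1]", call. = FALSE)
  if (any(standard_km <= 0)) stop("standard_km must be > 0", call. = FALSE)
  rate_per_km^standard_km
}

#' Summarize one river-year
#'
#' Population migration success (`n_succeeded / n_entered`), the per-km rate
#' of migration success, and the mean and SD of migration speed over fish
#' with defined durations.
#'
#' @param outcomes Outcome table for one river-year.
#' @param receivers Receiver table (used for the river distance).
#' @param de_first,de_last Optional detection efficiencies to carry through.
#' @return One-row data frame: `river`, `year`, `n_released`, `n_entered`,
#'   `n_succeeded`, `success`, `distance_km`, `rate_per_km`, `de_first`,
#'   `de_last`, `mean_speed`, `sd_speed`.
#' @export
summarize_river_year <- function(outcomes, receivers,
                                 de_first = NA_real_, de_last = NA_real_) {
  river <- unique(outcomes$river); year <- unique(outcomes$year)
  stopifnot(length(river) == 1, length(year) == 1)
  sub <- receivers[receivers$river == river & receivers$year == year, ]
  dist <- sub$river_km[sub$role == "last"] - sub$river_km[sub$role == "first"]
  n_entered <- sum(outcomes$entered)
  n_succ <- sum(outcomes$succeeded)
  if (n_entered == 0) {
    warning("river-year ", river, "-", year, ": no fish entered the study")
    success <- NA_real_; rate <- NA_real_
  } else {
    success <- n_succ / n_entered
    rate <- rate_of_migration_success(success, dist)
  }
  sp <- outcomes$speed_km_per_day[!is.na(outcomes$speed_km_per_day)]
  data.frame(river = river, year = year,
             n_released = nrow(outcomes), n_entered = n_entered,
             n_succeeded = n_succ, success = success,
             distance_km = dist, rate_per_km = rate,
             de_first = de_first, de_last = de_last,
             mean_speed = if (length(sp)) mean(sp) else NA_real_,
             sd_speed = if (length(sp) > 1) sd(sp) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Full per-river-year migration summary
#'
#' Runs outcome classification, detection-efficiency estimation, the
#' release-site fallback for river-years whose first receiver performed below
#' `fallback_threshold`, and per-river-year summarization, in one call.
#'
#' @param detections Filtered detections.
#' @param fish Fish records.
#' @param receivers Receiver deployments.
#' @param marine_detections Optional marine-receiver detections for
#'   last-receiver efficiency.
#' @param fallback_threshold See [release_fallback()].
#' @return A data frame with one row per river-year (see
#'   [summarize_river_year()]).
#' @examples
#' sim <- simulate_study(sim_config(n_rivers = 2, n_fish_per_river = 30))
#' flt <- filter_detections(sim$detections, sim$fish)
#' summarize_migration(flt$detections, sim$fish, sim$receivers)
#' @export
summarize_migration <- function(detections, fish, receivers,
                                marine_detections = NULL,
                                fallback_threshold = 0.5) {
  outcomes <- classify_outcomes(detections, fish, receivers)
  groups <- split(outcomes, paste(outcomes$river, outcomes$year, sep = "\r"))
  rows <- lapply(groups, function(g) {
    de1 <- suppressWarnings(detection_efficiency_first(g))
    de2 <- detection_efficiency_last(g, marine_detections, fish)
    g <- release_fallback(g, de1, fallback_threshold)
    summarize_river_year(g, receivers, de_first = de1, de_last = de2)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$river, out$year), ]
  rownames(out) <- NULL
  out
}
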