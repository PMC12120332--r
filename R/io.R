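#' Read the five input tables of a smolt telemetry study
#'
#' Comma-separated files with a header row and ISO-8601 timestamps (parsed as
#' UTC). A `columns` mapping (named character vector, `standard = local`)
#' absorbs local column-name dialects. Each reader validates the schema and
#' basic invariants of its table.
#'
#' Schemas:
#' * detections: `tag_code`, `receiver_id`, `timestamp`
#' * fish: `fish_id`, `tag_code`, `river`, `year`, `release_datetime`,
#'   `fork_length_mm`, `mass_g`, `tag_mass_g`, `release_site_km`
#' * receivers: `river`, `year`, `role` (first/last), `receiver_id`,
#'   `river_km`, `elevation_m`
#' * discharge: `river`, `year`, `date`, `discharge_m3s`
#' * catchments: `river`, `grassland`, `woodland`, `wetland`, `urban`,
#'   `agricultural`, `peat`, `bedrock`, `area_km2`, `gradient`, `barriers`
#'
#' @param path Path to a CSV file.
#' @param columns Optional named character vector mapping standard names to
#'   the file's column names.
#' @return A validated data frame.
#' @name telemetry_io
NULL

read_mapped_csv <- function(path, required, columns = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      loc <- columns[[std]]
      if (!loc %in% names(x))
        stop("mapped column '", loc, "' not found in ", path, call. = FALSE)
      names(x)[names(x) == loc] <- std
    }
  }
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

parse_utc <- function(x, what) {
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(x[idx], format = fmt, tz = "UTC")
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("unparseable ", what, " timestamp at row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  out
}

#' @rdname telemetry_io
#' @export
read_detections <- function(path, columns = NULL) {
  x <- read_mapped_csv(path, c("tag_code", "receiver_id", "timestamp"), columns)
  x$timestamp <- parse_utc(x$timestamp, "detection")
  x
}

#' @rdname telemetry_io
#' @export
read_fish_records <- function(path, columns = NULL) {
  x <- read_mapped_csv(path, c("fish_id", "tag_code", "river", "year",
                               "release_datetime"), columns)
  x$release_datetime <- parse_utc(x$release_datetime, "release")
  for (col in c("fork_length_mm", "mass_g", "tag_mass_g", "release_site_km"))
    if (col %in% names(x)) x[[col]] <- as.numeric(x[[col]])
  dup <- x[!is.na(x$tag_code), c("tag_code", "year")]
  if (anyDuplicated(dup))
    stop("tag codes must be unique within a year", call. = FALSE)
  x
}

#' @rdname telemetry_io
#' @export
read_receivers <- function(path, columns = NULL) {
  x <- read_mapped_csv(path, c("river", "year", "role", "receiver_id",
                               "river_km"), columns)
  validate_receivers(x)
}

#' Validate a receiver-deployment table
#'
#' Checks that every river-year has exactly one `first` and one `last`
#' receiver and that the last receiver lies downstream of the first.
#'
#' @param x Receiver data frame.
#' @return `x`, invisibly validated (returned visibly).
#' @export
validate_receivers <- function(x) {
  if (!all(x$role %in% c("first", "last")))
    stop("receiver role must be 'first' or 'last'", call. = FALSE)
  key <- interaction(x$river, x$year, drop = TRUE)
  for (k in levels(key)) {
    sub <- x[key == k, ]
    if (sum(sub$role == "first") != 1 || sum(sub$role == "last") != 1)
      stop("river-year ", k, " must have exactly one first and one last receiver",
           call. = FALSE)
    if (sub$river_km[sub$role == "last"] <= sub$river_km[sub$role == "first"])
      stop("river-year ", k, ": last receiver must be downstream of the first",
           call. = FALSE)
  }
  x
}

#' @rdname telemetry_io
#' @export
read_discharge_series <- function(path, columns = NULL) {
  x <- read_mapped_csv(path, c("river", "year", "date", "discharge_m3s"), columns)
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable discharge dates", call. = FALSE)
  if (any(x$discharge_m3s < 0, na.rm = TRUE))
    stop("discharge must be non-negative", call. = FALSE)
  x
}

#' @rdname telemetry_io
#' @export
read_catchments <- function(path, columns = NULL) {
  x <- read_mapped_csv(path, c("river", "grassland", "woodland", "wetland",
                               "urban", "agricultural", "peat", "bedrock"),
                       columns)
  covers <- c("grassland", "woodland", "wetland", "urban", "agricultural", "peat")
  for (col in covers) {
    if (any(x[[col]] < 0 | x[[col]] > 1, na.rm = TRUE))
      stop("cover proportion '", col, "' outside [0, 1]", call. = FALSE)
  }
  x
}

#' Filter raw acoustic detections
#'
#' Removes, in order of attribution: exact duplicate records (identical
#' tag code, receiver and timestamp), records outside the study window, and
#' records whose transmitter code does not belong to a tagged fish. The
#' relative order of surviving records is preserved, and a per-class removal
#' report is returned. Filtering is idempotent.
#'
#' @param raw Detection data frame (`tag_code`, `receiver_id`, `timestamp`).
#' @param fish Fish-record data frame (defines the valid tag codes).
#' @param window Length-2 vector (POSIXct or coercible) of the study window
#'   `[start, end]`, closed on both ends. Defaults to
#'   `[min(release), max(raw timestamp)]`.
#' @return A list of class `smolt_filter`: `detections` (the clean table) and
#'   `report` (counts: `duplicates`, `out_of_window`, `unknown_tag`,
#'   `removed`, `retained`).
#' @examples
#' sim <- simulate_study(sim_config(n_rivers = 2, n_fish_per_river = 10))
#' flt <- filter_detections(sim$detections, sim$fish)
#' flt$report
#' @export
filter_detections <- function(raw, fish, window = NULL) {
  need <- c("tag_code", "receiver_id", "timestamp")
  stopifnot(all(need %in% names(raw)))
  if (nrow(raw) == 0) {
    rep0 <- list(duplicates = 0L, out_of_window = 0L, unknown_tag = 0L,
                 removed = 0L, retained = 0L)
    return(structure(list(detections = raw, report = rep0),
                     class = "smolt_filter"))
  }
  if (!inherits(raw$timestamp, "POSIXct"))
    raw$timestamp <- parse_utc(raw$timestamp, "detection")
  if (is.null(window))
    window <- c(min(fish$release_datetime), max(raw$timestamp))
  window <- as.POSIXct(window, tz = "UTC")
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be [start, end] with start < end", call. = FALSE)

  key <- paste(raw$tag_code, raw$receiver_id, format(raw$timestamp, "%Y-%m-%d %H:%M:%OS6"))
  is_dup <- duplicated(key)
  in_window <- raw$timestamp >= window[1] & raw$timestamp <= window[2]
  known <- raw$tag_code %in% fish$tag_code

  # attribute each removed row to the first failing class
  cls_dup <- is_dup
  cls_oow <- !is_dup & !in_window
  cls_unk <- !is_dup & in_window & !known
  keep <- !is_dup & in_window & known

  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(duplicates = sum(cls_dup), out_of_window = sum(cls_oow),
                 unknown_tag = sum(cls_unk), removed = sum(!keep),
                 retained = sum(keep))
  structure(list(detections = out, report = report), class = "smolt_filter")
}

#' @export
print.smolt_filter <- function(x, ...) {
  r <- x$report
  cat("<filtered detections> retained ", r$retained, " of ",
      r$retained + r$removed, " (duplicates ", r$duplicates,
      ", out-of-window ", r$out_of_window, ", unknown tags ", r$unknown_tag,
      ")\n", sep = "")
  invisible(x)
}

#' Write a detection filter report as JSON
#'
#' @param x A `smolt_filter` (or its `report` element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  rep <- if (inherits(x, "smolt_filter")) x$report else x
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Drop fish with incomplete biometrics
#'
#' Removes fish whose fork length or mass was not recorded. Intended for the
#' individual-success analysis path only: population-level summaries retain
#' every tagged fish.
#'
#' @param fish Fish-record data frame.
#' @return The subset with complete length and mass.
#' @export
drop_incomplete_biometrics <- function(fish) {
  keep <- !is.na(fish$fork_length_mm) & !is.na(fish$mass_g)
  out <- fish[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
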