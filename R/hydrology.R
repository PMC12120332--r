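#' Build a flow duration curve
#'
#' The flow duration curve relates a daily mean discharge to the percentage
#' of days on which that discharge is exceeded. Empirical exceedance uses the
#' Weibull plotting position: the r-th largest of n daily flows is assigned
#' exceedance `100 * r / (n + 1)`, avoiding the 0% and 100% endpoints. A
#' shape-preserving (monotone) cubic spline interpolates between the
#' empirical points in both directions (flow to exceedance and back), so that
#' root-finding on the curve is well-posed.
#'
#' @param daily_discharge Numeric vector of daily mean discharges
#'   (m^3 s^-1), at least 30 values, all non-negative. Ties are pooled (a
#'   tied flow receives the mean exceedance of its tie group).
#' @return An object of class `fdc`: `support` (sorted unique flows),
#'   `exceedance` (matching percentages), and monotone interpolants in both
#'   directions.
#' @examples
#' fdc <- build_fdc(rlnorm(365, 2, 0.5))
#' exceedance_for_discharge(fdc, median(fdc$support))
#' @export
build_fdc <- function(daily_discharge) {
  q <- daily_discharge[!is.na(daily_discharge)]
  if (length(q) < 30)
    stop("need at least 30 daily discharge values", call. = FALSE)
  if (any(q < 0)) stop("discharge must be non-negative", call. = FALSE)
  if (length(unique(q)) < 2)
    stop("constant discharge series: flow duration curve is degenerate",
         call. = FALSE)
  n <- length(q)
  flow_u <- sort(unique(q))
  # Weibull-type plotting position on the strict-exceedance count: the
  # fraction of the n+1 plotting intervals lying strictly above each flow
  n_above <- n - findInterval(flow_u, sort(q))
  exc_u <- 100 * n_above / (n + 1)
  if (length(flow_u) >= 4) {
    to_exc <- splinefun(flow_u, exc_u, method = "hyman")
    to_flow <- splinefun(exc_u, flow_u, method = "hyman")
  } else {
    to_exc <- approxfun(flow_u, exc_u, rule = 2)
    to_flow <- approxfun(exc_u, flow_u, rule = 2)
  }
  structure(list(support = flow_u, exceedance = exc_u,
                 to_exceedance = to_exc, to_flow = to_flow, n_days = n),
            class = "fdc")
}

#' @export
print.fdc <- function(x, ...) {
  cat("<flow duration curve> ", x$n_days, " days, flow range [",
      signif(min(x$support), 4), ", ", signif(max(x$support), 4),
      "] m^3/s\n", sep = "")
  invisible(x)
}

#' Percentage exceedance of an observed discharge
#'
#' Finds the Q-value (percentage exceedance) at which the flow duration
#' curve equals the observed discharge, by root-finding on the monotone
#' exceedance-to-flow interpolant. Exceedance is a size-independent measure
#' of discharge magnitude: scaling all flows of a river by a constant leaves
#' the exceedance of a correspondingly scaled observation unchanged.
#' Observations outside the observed flow range are clamped to it with a
#' warning rather than extrapolated.
#'
#' @param fdc A [build_fdc()] object.
#' @param q_obs Observed discharge(s), m^3 s^-1.
#' @return Percentage exceedance in \[0, 100\] for each observation.
#' @export
exceedance_for_discharge <- function(fdc, q_obs) {
  stopifnot(inherits(fdc, "fdc"))
  lo <- min(fdc$support); hi <- max(fdc$support)
  if (any(q_obs < lo | q_obs > hi, na.rm = TRUE)) {
    warning("observed discharge outside the flow-duration support; clamped")
    q_obs <- pmin(pmax(q_obs, lo), hi)
  }
  e_range <- range(fdc$exceedance)
  vapply(q_obs, function(q) {
    if (is.na(q)) return(NA_real_)
    if (q <= lo) return(max(fdc$exceedance))
    if (q >= hi) return(min(fdc$exceedance))
    f <- function(e) fdc$to_flow(e) - q
    if (f(e_range[1]) * f(e_range[2]) > 0)
      stop("root not bracketed on the flow duration curve", call. = FALSE)
    uniroot(f, interval = e_range, tol = 1e-8)$root
  }, numeric(1))
}

#' Mean discharge over the migration window
#'
#' Arithmetic mean of the daily mean discharges inside the closed window
#' from the day the first smolt was tagged to the day the last smolt was
#' detected at the most downstream receiver.
#'
#' @param discharge Data frame with `date` (Date) and `discharge_m3s` for
#'   one river-year.
#' @param window Length-2 Date (or coercible) vector `[start, end]`.
#' @return Mean discharge (m^3 s^-1).
#' @export
migration_window_mean_discharge <- function(discharge, window) {
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] <= window[2])
  inside <- discharge$date >= window[1] & discharge$date <= window[2]
  if (!any(inside)) {
    lbl <- if (all(c("river", "year") %in% names(discharge)))
      paste0(discharge$river[1], "-", discharge$year[1]) else "series"
    stop("migration window does not overlap the discharge series for ", lbl,
         call. = FALSE)
  }
  mean(discharge$discharge_m3s[inside])
}
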