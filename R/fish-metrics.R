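#' Body condition from the pooled length-mass regression
#'
#' Condition is the residual of an ordinary least-squares regression of
#' log(mass) on log(fork length), pooled across every fish in the table (all
#' rivers and years): a measure of mass independent of length. Natural
#' logarithms are used throughout; residuals are invariant to the unit of
#' length (a mm-to-cm change shifts the intercept only).
#'
#' @param fish Fish-record data frame with strictly positive `fork_length_mm`
#'   and `mass_g`; rows with a missing biometric are excluded from the fit
#'   and receive `NA` condition.
#' @return An object of class `condition_model`: `intercept`, `slope`,
#'   `residuals` (per-fish condition, aligned with `fish`, `NA` where a
#'   biometric is missing), and the underlying `lm` fit.
#' @examples
#' fish <- data.frame(fish_id = 1:4, fork_length_mm = c(130, 140, 150, 160),
#'                    mass_g = c(24, 30, 37, 45))
#' body_condition(fish)$slope
#' @export
body_condition <- function(fish) {
  stopifnot(all(c("fork_length_mm", "mass_g") %in% names(fish)))
  complete <- !is.na(fish$fork_length_mm) & !is.na(fish$mass_g)
  bad <- complete & (fish$fork_length_mm <= 0 | fish$mass_g <= 0)
  if (any(bad)) {
    id <- if ("fish_id" %in% names(fish)) fish$fish_id[bad] else which(bad)
    stop("non-positive length or mass for fish: ",
         paste(head(id, 5), collapse = ", "), call. = FALSE)
  }
  if (sum(complete) < 3)
    stop("need at least 3 fish with complete biometrics", call. = FALSE)
  dat <- data.frame(ll = log(fish$fork_length_mm[complete]),
                    lm = log(fish$mass_g[complete]))
  fit <- if (length(unique(dat$ll)) == 1) {
    # degenerate: all lengths identical; slope indeterminate, use mean-only fit
    lm(lm ~ 1, data = dat)
  } else {
    lm(lm ~ ll, data = dat)
  }
  res <- rep(NA_real_, nrow(fish))
  res[complete] <- resid(fit)
  cf <- coef(fit)
  structure(list(intercept = unname(cf[1]),
                 slope = if (length(cf) > 1) unname(cf[2]) else NA_real_,
                 residuals = res, fit = fit, n = sum(complete)),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat("<condition model> log(mass) = ", signif(x$intercept, 5), " + ",
      signif(x$slope, 5), " log(length), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tag burden
#'
#' Tag mass as a percentage of fish body mass in air:
#' `100 * tag_mass_g / mass_g`.
#'
#' @param fish Fish-record data frame with `tag_mass_g` and `mass_g`, or a
#'   numeric vector of tag masses (then `mass_g` must be supplied).
#' @param mass_g Fish masses, when `fish` is a numeric vector.
#' @return Numeric vector of burdens (percent); `NA` where mass is missing.
#' @examples
#' tag_burden(1.6, 32) # 5 percent
#' @export
tag_burden <- function(fish, mass_g = NULL) {
  if (is.data.frame(fish)) {
    tagm <- fish$tag_mass_g
    mass <- fish$mass_g
  } else {
    tagm <- fish
    mass <- mass_g
  }
  if (any(!is.na(mass) & mass <= 0))
    stop("fish mass must be strictly positive", call. = FALSE)
  100 * tagm / mass
}
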