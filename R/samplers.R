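#' Sampler specifications for the synthetic-data generator
#'
#' The simulator draws catchment covariates, river distances, migration speeds
#' and fish lengths from small declarative sampler specifications, so that a
#' study configuration is a plain, printable object and every distributional
#' assumption is visible in one place.
#'
#' Available samplers:
#' * `sampler_fixed(value)` — degenerate at `value`.
#' * `sampler_beta(shape1, shape2)` — Beta distribution on \[0, 1\], the
#'   natural choice for cover proportions.
#' * `sampler_lognormal(meanlog, sdlog)` — strictly positive, right-skewed;
#'   used for river distances, speeds and catchment areas.
#' * `sampler_normal(mean, sd, lower, upper)` — Gaussian, optionally
#'   truncated by rejection; used for fork lengths.
#'
#' @param value,shape1,shape2,meanlog,sdlog,mean,sd,lower,upper Numeric
#'   parameters of the respective distribution.
#' @return An object of class `smolt_sampler`.
#' @examples
#' s <- sampler_beta(2, 6)
#' sampler_mean(s)
#' sampler_draw(s, 5)
#' @name samplers
NULL

new_sampler <- function(dist, ...) {
  structure(list(dist = dist, ...), class = "smolt_sampler")
}

#' @rdname samplers
#' @export
sampler_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  new_sampler("fixed", value = value)
}

#' @rdname samplers
#' @export
sampler_beta <- function(shape1, shape2) {
  if (!is.numeric(shape1) || !is.numeric(shape2) || shape1 <= 0 || shape2 <= 0)
    stop("beta sampler requires strictly positive shape parameters", call. = FALSE)
  new_sampler("beta", shape1 = shape1, shape2 = shape2)
}

#' @rdname samplers
#' @export
sampler_lognormal <- function(meanlog, sdlog) {
  if (!is.numeric(meanlog) || !is.numeric(sdlog) || sdlog < 0)
    stop("lognormal sampler requires numeric meanlog and sdlog >= 0", call. = FALSE)
  new_sampler("lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname samplers
#' @export
sampler_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (!is.numeric(mean) || !is.numeric(sd) || sd < 0 || lower >= upper)
    stop("normal sampler requires sd >= 0 and lower < upper", call. = FALSE)
  new_sampler("normal", mean = mean, sd = sd, lower = lower, upper = upper)
}

is_sampler <- function(x) inherits(x, "smolt_sampler")

as_sampler <- function(x, what = "value") {
  if (is_sampler(x)) return(x)
  if (is.numeric(x) && length(x) == 1) return(sampler_fixed(x))
  stop("invalid sampler specification for ", what, call. = FALSE)
}

#' @rdname samplers
#' @param x A `smolt_sampler`.
#' @export
sampler_mean <- function(x) {
  stopifnot(is_sampler(x))
  switch(x$dist,
    fixed = x$value,
    beta = x$shape1 / (x$shape1 + x$shape2),
    lognormal = exp(x$meanlog + x$sdlog^2 / 2),
    normal = x$mean, # truncation ignored; bounds are guard rails, not shape
    stop("unknown sampler: ", x$dist)
  )
}

#' @rdname samplers
#' @param n Number of draws.
#' @export
sampler_draw <- function(x, n) {
  stopifnot(is_sampler(x), n >= 0)
  out <- switch(x$dist,
    fixed = rep(x$value, n),
    beta = rbeta(n, x$shape1, x$shape2),
    lognormal = rlnorm(n, x$meanlog, x$sdlog),
    normal = {
      y <- rnorm(n, x$mean, x$sd)
      bad <- which(y < x$lower | y > x$upper)
      while (length(bad)) {
        y[bad] <- rnorm(length(bad), x$mean, x$sd)
        bad <- bad[y[bad] < x$lower | y[bad] > x$upper]
      }
      y
    },
    stop("unknown sampler: ", x$dist)
  )
  out
}

#' @export
print.smolt_sampler <- function(x, ...) {
  pars <- x[setdiff(names(x), "dist")]
  pars <- pars[vapply(pars, is.finite, logical(1))]
  cat("<sampler ", x$dist, "(",
      paste(names(pars), unlist(pars), sep = "=", collapse = ", "),
      ")>\n", sep = "")
  invisible(x)
}
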