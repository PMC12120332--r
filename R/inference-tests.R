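#' Variance inflation factors
#'
#' For each covariate, the VIF is `1 / (1 - R2_j)` where `R2_j` is the
#' coefficient of determination from regressing that covariate on all the
#' others. A perfectly collinear covariate yields `Inf`.
#'
#' @param design Data frame or matrix of numeric covariates (>= 2 columns,
#'   none constant).
#' @return Named numeric vector of VIFs, each >= 1.
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(design) {
  X <- as.data.frame(design)
  if (ncol(X) < 2) stop("need at least 2 covariates", call. = FALSE)
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all covariates must be numeric", call. = FALSE)
  if (any(vapply(X, function(x) length(unique(x)) == 1, logical(1))))
    stop("constant covariate column", call. = FALSE)
  out <- vapply(seq_along(X), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[-j])
    # summary warns on the (expected) perfectly collinear case; R2 -> Inf VIF
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, names(X))
}

#' Likelihood ratio test between nested fits
#'
#' Computes `2 * (logLik(full) - logLik(nested))` against the chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference. Accepts any pair of fitted models with `logLik()` methods
#' (lm, glm, merMod, glmmTMB, or the package's `smolt_fit` wrappers) fitted
#' to the same data. Tiny negative statistics from optimizer noise are
#' clamped to zero; identical models give statistic 0 and p 1.
#'
#' @param nested The reduced model.
#' @param full The full model.
#' @return A list of class `lrt_result`: `statistic`, `df`, `p`.
#' @export
lrt <- function(nested, full) {
  m_n <- if (inherits(nested, "smolt_fit")) nested$model else nested
  m_f <- if (inherits(full, "smolt_fit")) full$model else full
  ll_n <- logLik(m_n); ll_f <- logLik(m_f)
  n_n <- tryCatch(stats::nobs(m_n), error = function(e) NA)
  n_f <- tryCatch(stats::nobs(m_f), error = function(e) NA)
  if (!is.na(n_n) && !is.na(n_f) && n_n != n_f)
    stop("models were fitted to different numbers of observations", call. = FALSE)
  df <- as.integer(attr(ll_f, "df") - attr(ll_n, "df"))
  if (df < 0)
    stop("'full' has fewer parameters than 'nested'; models are not nested as given",
         call. = FALSE)
  stat <- 2 * (as.numeric(ll_f) - as.numeric(ll_n))
  if (stat < -1e-6)
    warning("likelihood ratio statistic is negative (", signif(stat, 3),
            "); check that the models are nested and both converged")
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LRT: 2*dLL = ", signif(x$statistic, 5), ", df = ", x$df,
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Chi-squared test of temporal change in migration success
#'
#' For every river with more than one study year, later-year expected
#' success and failure counts are set by the river's first-year success
#' proportion; the statistic sums `(O - E)^2 / E` over the success and
#' failure cells of all later river-years, with degrees of freedom equal to
#' the number of later river-years.
#'
#' @param counts Data frame with `river`, `year`, `n_entered`,
#'   `n_succeeded`; rivers with a single year are dropped.
#' @return A list of class `temporal_chisq`: `statistic`, `df`, `p`, and the
#'   per-cell table `cells`.
#' @export
temporal_chisq <- function(counts) {
  stopifnot(all(c("river", "year", "n_entered", "n_succeeded") %in% names(counts)))
  if (any(counts$n_succeeded > counts$n_entered))
    stop("successes exceed entries", call. = FALSE)
  multi <- names(which(table(counts$river) >= 2))
  counts <- counts[counts$river %in% multi, ]
  if (nrow(counts) == 0) stop("no river has more than one year", call. = FALSE)
  cells <- list()
  for (r in unique(counts$river)) {
    sub <- counts[counts$river == r, ]
    sub <- sub[order(sub$year), ]
    p1 <- sub$n_succeeded[1] / sub$n_entered[1]
    if (p1 == 0 || p1 == 1)
      stop("river ", r, ": first-year success of ", p1,
           " gives an expected cell of zero; exclude this river", call. = FALSE)
    later <- sub[-1, , drop = FALSE]
    cells[[r]] <- data.frame(
      river = r, year = later$year,
      obs_succ = later$n_succeeded,
      obs_fail = later$n_entered - later$n_succeeded,
      exp_succ = p1 * later$n_entered,
      exp_fail = (1 - p1) * later$n_entered)
  }
  cells <- do.call(rbind, cells)
  stat <- sum((cells$obs_succ - cells$exp_succ)^2 / cells$exp_succ +
                (cells$obs_fail - cells$exp_fail)^2 / cells$exp_fail)
  df <- nrow(cells)
  structure(list(statistic = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE), cells = cells),
            class = "temporal_chisq")
}

#' @export
print.temporal_chisq <- function(x, ...) {
  cat("Temporal chi-squared: X2 = ", signif(x$statistic, 6), ", df = ", x$df,
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Largest complete submatrix (greedy)
#'
#' Iteratively drops the row or column with the highest proportion of
#' missing values until the matrix is complete. Used to restrict an
#' unbalanced river-by-year success matrix before computing concordance.
#'
#' @param mat Numeric matrix, possibly with `NA`s.
#' @return A complete submatrix (possibly with fewer rows/columns).
#' @export
complete_submatrix <- function(mat) {
  while (anyNA(mat) && nrow(mat) > 1 && ncol(mat) > 1) {
    rna <- rowMeans(is.na(mat)); cna <- colMeans(is.na(mat))
    if (max(rna) >= max(cna)) mat <- mat[-which.max(rna), , drop = FALSE]
    else mat <- mat[, -which.max(cna), drop = FALSE]
  }
  if (anyNA(mat)) stop("no complete submatrix found", call. = FALSE)
  mat
}

#' Kendall's coefficient of concordance
#'
#' Agreement of m judges (columns) ranking n objects (rows), with the
#' standard tie correction, and the chi-squared approximation
#' `X2 = m * (n - 1) * W` on `n - 1` degrees of freedom. For the temporal
#' concordance question, each river is a judge ranking the study years: a
#' large W means rivers agree on which years were good.
#'
#' @param mat Numeric matrix, objects in rows, judges in columns. Must be
#'   complete; use [complete_submatrix()] first if necessary.
#' @return A list of class `kendall_w`: `W`, `statistic`, `df`, `p`,
#'   `n_objects`, `n_judges`.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(1.1, 2.2, 3.3))
#' kendalls_w(m)$W # perfectly concordant: 1
#' @export
kendalls_w <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete; see complete_submatrix()",
                       call. = FALSE)
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2 || m < 2) stop("need at least 2 objects and 2 judges", call. = FALSE)
  ranks <- apply(mat, 2, rank)
  R <- rowSums(ranks)
  S <- sum((R - mean(R))^2)
  ties <- sum(apply(ranks, 2, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * ties
  W <- if (denom <= 0) NA_real_ else 12 * S / denom
  stat <- m * (n - 1) * W
  structure(list(W = W, statistic = stat, df = n - 1,
                 p = pchisq(stat, n - 1, lower.tail = FALSE),
                 n_objects = n, n_judges = m),
            class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat("Kendall's W = ", signif(x$W, 4), " (", x$n_judges, " judges, ",
      x$n_objects, " objects), X2 = ", signif(x$statistic, 5),
      ", df = ", x$df, ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Levene/Brown-Forsythe test of equal variances
#'
#' One-way ANOVA on absolute deviations from the group centre (the median by
#' default, the robust Brown-Forsythe form). Groups of size one contribute
#' zero deviation and no spread.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 groups).
#' @param center `"median"` (default) or `"mean"`.
#' @return A list of class `levene_test`: `statistic` (F), `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (all(table(groups) <= 1))
    stop("all groups have a single observation", call. = FALSE)
  cfun <- if (center == "median") median else mean
  ctr <- tapply(values, groups, cfun)
  z <- abs(values - ctr[groups])
  a <- anova(lm(z ~ groups))
  structure(list(statistic = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p = a$`Pr(>F)`[1]),
            class = "levene_test")
}

#' @export
print.levene_test <- function(x, ...) {
  cat("Levene (Brown-Forsythe): F(", x$df1, ", ", x$df2, ") = ",
      signif(x$statistic, 5), ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}
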