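fixed_coef_table <- function(model) {
  if (inherits(model, "merMod")) {
    s <- summary(model)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  } else if (inherits(model, "glmmTMB")) {
    s <- summary(model)$coefficients$cond
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    s <- summary(model)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

new_smolt_fit <- function(model, kind) {
  ll <- logLik(model)
  structure(list(model = model, kind = kind,
                 coefficients = fixed_coef_table(model),
                 logLik = as.numeric(ll), df = attr(ll, "df"),
                 n = stats::nobs(model)),
            class = "smolt_fit")
}

#' @export
print.smolt_fit <- function(x, ...) {
  cat("<smolt_fit: ", x$kind, "> n = ", x$n, ", logLik = ",
      signif(x$logLik, 6), "\n", sep = "")
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
logLik.smolt_fit <- function(object, ...) logLik(object$model)

#' Binomial mixed model for individual migration success
#'
#' Fits a logit-link binomial GLMM of individual success on body condition
#' and tag burden, with crossed random intercepts for river and year, then
#' (optionally) applies likelihood-ratio step-down selection of the two
#' fixed covariates.
#'
#' @param data Data frame with `succeeded` (logical/0-1), `condition`,
#'   `tag_burden`, `river`, `year`.
#' @param select Run step-down selection at level `alpha` (default TRUE).
#' @param alpha Selection level, default 0.05.
#' @return A list of class `individual_success_fit`: `full` (smolt_fit of
#'   the full model), `final`, `trace` (selection trace), `lrt` (per-term
#'   LRTs against the full model), `vif` of the covariates.
#' @export
fit_individual_success <- function(data, select = TRUE, alpha = 0.05) {
  need <- c("succeeded", "condition", "tag_burden", "river", "year")
  stopifnot(all(need %in% names(data)))
  data <- data[complete.cases(data[, need]), ]
  if (length(unique(data$river)) < 2 || length(unique(data$year)) < 2)
    stop("need at least 2 rivers and 2 years for the random effects",
         call. = FALSE)
  data$year <- factor(data$year)
  full <- lme4::glmer(succeeded ~ condition + tag_burden + (1 | river) + (1 | year),
                      data = data, family = binomial())
  conv <- full@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    grad <- sqrt(sum(full@optinfo$derivs$gradient^2))
    stop("GLMM optimizer failed to converge (gradient norm ",
         signif(grad, 3), ")", call. = FALSE)
  }
  drops <- lapply(c(condition = "condition", tag_burden = "tag_burden"),
                  function(tm) {
    red <- update(full, as.formula(paste(". ~ . -", tm)), data = data)
    lrt(red, full)
  })
  sel <- if (select)
    step_down(full, data = data, alpha = alpha)
  else list(final = full, trace = NULL)
  structure(list(full = new_smolt_fit(full, "individual success GLMM"),
                 final = new_smolt_fit(sel$final, "individual success GLMM (final)"),
                 trace = sel$trace, lrt = drops,
                 vif = vif(data[, c("condition", "tag_burden")])),
            class = "individual_success_fit")
}

#' @export
print.individual_success_fit <- function(x, ...) {
  print(x$final)
  cat("term LRTs against the full model:\n")
  for (nm in names(x$lrt))
    cat("  ", nm, ": 2*dLL = ", signif(x$lrt[[nm]]$statistic, 4),
        ", p = ", signif(x$lrt[[nm]]$p, 3), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio step-down selection
#'
#' Repeatedly drops the fixed-effect term whose removal has the largest
#' likelihood-ratio p-value above `alpha` (ties broken in favour of the term
#' with fewer parameters), refitting until every remaining term is
#' significant. Random effects and any term named in `keep` are never
#' dropped.
#'
#' @param model A fitted glm, glmer or glmmTMB model.
#' @param data The data the model was fitted to.
#' @param alpha Retention level, default 0.05.
#' @param keep Character vector of term labels never to drop.
#' @return A list: `final` (the selected model) and `trace` (data frame of
#'   round, term, statistic, df, p, removed).
#' @export
step_down <- function(model, data, alpha = 0.05, keep = character()) {
  trace <- list(); round <- 0L
  repeat {
    round <- round + 1L
    tl <- attr(terms(model), "term.labels")
    droppable <- setdiff(tl, keep)
    if (!length(droppable)) break
    tests <- lapply(droppable, function(tm) {
      red <- update(model, as.formula(paste(". ~ . -", tm)), data = data)
      list(term = tm, red = red, lrt = lrt(red, model))
    })
    ps <- vapply(tests, function(t) t$lrt$p, numeric(1))
    dfs <- vapply(tests, function(t) t$lrt$df, numeric(1))
    ord <- order(-ps, dfs)
    worst <- tests[[ord[1]]]
    removed <- worst$lrt$p > alpha
    trace[[round]] <- data.frame(round = round, term = worst$term,
                                 statistic = worst$lrt$statistic,
                                 df = worst$lrt$df, p = worst$lrt$p,
                                 removed = removed, stringsAsFactors = FALSE)
    if (!removed) break
    model <- worst$red
  }
  list(final = model,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Gamma models for migration speed
#'
#' Log-link gamma GLMs of per-fish migration speed, testing river and year
#' terms each against the intercept-only model by likelihood ratio.
#'
#' @param outcomes Outcome table with positive `speed_km_per_day`, `river`,
#'   `year`; rows without a speed are dropped.
#' @return A list of class `speed_fit`: `null`, `river`, `year` (smolt_fit
#'   objects) and `lrt_river`, `lrt_year`.
#' @export
fit_speed_glm <- function(outcomes) {
  dat <- outcomes[!is.na(outcomes$speed_km_per_day), ]
  if (any(dat$speed_km_per_day <= 0))
    stop("migration speeds must be strictly positive", call. = FALSE)
  dat$river <- factor(dat$river); dat$year <- factor(dat$year)
  m0 <- glm(speed_km_per_day ~ 1, data = dat, family = Gamma(link = "log"))
  one_level <- function(f) nlevels(droplevels(f)) < 2
  mr <- if (one_level(dat$river)) NULL else
    glm(speed_km_per_day ~ river, data = dat, family = Gamma(link = "log"))
  my <- if (one_level(dat$year)) NULL else
    glm(speed_km_per_day ~ year, data = dat, family = Gamma(link = "log"))
  structure(list(null = new_smolt_fit(m0, "speed gamma GLM (null)"),
                 river = if (!is.null(mr)) new_smolt_fit(mr, "speed gamma GLM (river)"),
                 year = if (!is.null(my)) new_smolt_fit(my, "speed gamma GLM (year)"),
                 lrt_river = if (!is.null(mr)) lrt(m0, mr),
                 lrt_year = if (!is.null(my)) lrt(m0, my)),
            class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat("Migration speed, gamma GLM (log link), n = ", x$null$n, "\n", sep = "")
  if (!is.null(x$lrt_river)) { cat("  river: "); print(x$lrt_river) }
  if (!is.null(x$lrt_year)) { cat("  year:  "); print(x$lrt_year) }
  invisible(x)
}

#' Squeeze proportions off the boundary
#'
#' Smithson-Verkuilen transformation `(y * (n - 1) + 0.5) / n`, mapping
#' exact 0s and 1s into (0, 1) so a beta likelihood is defined.
#'
#' @param y Proportions in \[0, 1\].
#' @param n Sample size used for the squeeze (default `length(y)`).
#' @return Squeezed proportions in (0, 1).
#' @export
squeeze_proportions <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

#' Beta regression of per-km migration success on landscape covariates
#'
#' Fits a logit-link beta regression (single scalar dispersion) of the rate
#' of migration success on catchment land cover, superficial peat, geology
#' and channel covariates, with likelihood-ratio step-down selection.
#'
#' @param data Data frame with `rate_per_km` in (0, 1) plus the covariates.
#' @param covariates Candidate covariate names; defaults to every candidate
#'   present in `data` among grassland, woodland, wetland, urban,
#'   agricultural, peat, area_km2, gradient, barriers, bedrock.
#' @param bedrock_as_intercept If TRUE the model is parameterized with one
#'   intercept per bedrock class (`~ 0 + bedrock + ...`), the form whose
#'   coefficients are directly the per-class logit intercepts; bedrock is
#'   then never dropped. If FALSE (default) a global intercept is used.
#' @param select Run step-down selection (default TRUE).
#' @param alpha Selection level.
#' @param squeeze If TRUE, apply [squeeze_proportions()] before fitting;
#'   required when any rate is exactly 0 or 1.
#' @return A list of class `landscape_fit`: `full`, `final` (smolt_fit),
#'   `trace`, and the model frame used.
#' @export
fit_rate_landscape <- function(data, covariates = NULL,
                               bedrock_as_intercept = FALSE,
                               select = TRUE, alpha = 0.05, squeeze = FALSE) {
  candidates <- c("grassland", "woodland", "wetland", "urban", "agricultural",
                  "peat", "area_km2", "gradient", "barriers", "bedrock")
  if (is.null(covariates)) covariates <- intersect(candidates, names(data))
  stopifnot("rate_per_km" %in% names(data), length(covariates) >= 1)
  y <- data$rate_per_km
  if (any(y <= 0 | y >= 1)) {
    if (!squeeze)
      stop("rate_per_km touches the boundary of (0, 1); refit with squeeze = TRUE",
           call. = FALSE)
    y <- squeeze_proportions(y)
  }
  dat <- data
  dat$rate_per_km <- y
  if ("bedrock" %in% covariates) dat$bedrock <- factor(dat$bedrock)
  rhs <- if (bedrock_as_intercept && "bedrock" %in% covariates)
    paste(c("0", "bedrock", setdiff(covariates, "bedrock")), collapse = " + ")
  else paste(covariates, collapse = " + ")
  full <- glmmTMB::glmmTMB(as.formula(paste("rate_per_km ~", rhs)),
                           data = dat, family = glmmTMB::beta_family())
  keep <- if (bedrock_as_intercept) "bedrock" else character()
  sel <- if (select) step_down(full, data = dat, alpha = alpha, keep = keep)
  else list(final = full, trace = NULL)
  structure(list(full = new_smolt_fit(full, "landscape beta GLM"),
                 final = new_smolt_fit(sel$final, "landscape beta GLM (final)"),
                 trace = sel$trace, data = dat),
            class = "landscape_fit")
}

#' @export
print.landscape_fit <- function(x, ...) {
  print(x$final)
  if (!is.null(x$trace)) {
    cat("step-down trace:\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' Marginal effect of one covariate on standardized migration success
#'
#' Predicts the per-km rate across a grid of one covariate with every other
#' covariate held at its observed mean (the modal class for bedrock), then
#' standardizes the prediction to a common river distance. The uncertainty
#' ribbon is the prediction transformed at plus/minus 2 SD of the linear
#' predictor.
#'
#' @param fit A `landscape_fit`.
#' @param covariate Covariate name present in the final model.
#' @param grid Numeric grid of covariate values; defaults to 50 points over
#'   the observed range. Values outside the observed range trigger a
#'   warning (extrapolation), not an error.
#' @param standard_km Standardization distance, default 31.52 km.
#' @return Data frame: covariate value, `rate_per_km`, `std_success`,
#'   `lower`, `upper` (standardized scale).
#' @export
marginal_effects <- function(fit, covariate, grid = NULL, standard_km = 31.52) {
  stopifnot(inherits(fit, "landscape_fit"))
  model <- fit$final$model
  tl <- attr(terms(model), "term.labels")
  if (!covariate %in% tl)
    stop("covariate '", covariate, "' is not in the final model", call. = FALSE)
  dat <- fit$data
  obs <- dat[[covariate]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 50)
  if (any(grid < min(obs) | grid > max(obs)))
    warning("grid extends beyond the observed range of ", covariate)
  nd <- dat[rep(1L, length(grid)), , drop = FALSE]
  for (v in setdiff(names(dat), c(covariate, "rate_per_km"))) {
    nd[[v]] <- if (is.numeric(dat[[v]])) mean(dat[[v]], na.rm = TRUE)
    else names(which.max(table(dat[[v]])))
  }
  if (is.factor(dat$bedrock)) nd$bedrock <- factor(nd$bedrock, levels = levels(dat$bedrock))
  nd[[covariate]] <- grid
  pr <- predict(model, newdata = nd, type = "link", se.fit = TRUE)
  rate <- plogis(pr$fit)
  data.frame(covariate = grid,
             rate_per_km = rate,
             std_success = standardize_rate(rate, standard_km),
             lower = standardize_rate(plogis(pr$fit - 2 * pr$se.fit), standard_km),
             upper = standardize_rate(plogis(pr$fit + 2 * pr$se.fit), standard_km))
}

#' Tukey-adjusted pairwise bedrock contrasts
#'
#' Estimated marginal means of the bedrock classes from the final landscape
#' model, with Tukey-adjusted pairwise comparisons.
#'
#' @param fit A `landscape_fit` whose final model retains `bedrock`.
#' @return A list: `emmeans` (marginal means on the link scale) and
#'   `contrasts` (pairwise, Tukey-adjusted), both as data frames.
#' @export
bedrock_pairwise <- function(fit) {
  stopifnot(inherits(fit, "landscape_fit"))
  model <- fit$final$model
  if (!"bedrock" %in% attr(terms(model), "term.labels"))
    stop("bedrock is not in the final model", call. = FALSE)
  em <- emmeans::emmeans(model, ~bedrock)
  list(emmeans = as.data.frame(em),
       contrasts = as.data.frame(emmeans::contrast(em, method = "pairwise",
                                                   adjust = "tukey")))
}

#' Beta mixed model of per-km success on discharge exceedance
#'
#' Fits a logit-link beta GLMM of the rate of migration success on the
#' percentage exceedance of migration-window discharge, with a random river
#' intercept, restricted to rivers observed in more than one year; the
#' exceedance effect is tested by likelihood ratio against the nested null.
#' With a single river the random effect is degenerate and a fixed-intercept
#' beta GLM is used instead, with a warning.
#'
#' @param data Data frame with `rate_per_km`, `exceedance`, `river`.
#' @param squeeze Apply [squeeze_proportions()] when rates touch 0/1.
#' @return A list of class `exceedance_fit`: `fit`, `null` (smolt_fit) and
#'   `lrt`.
#' @export
fit_rate_exceedance <- function(data, squeeze = FALSE) {
  stopifnot(all(c("rate_per_km", "exceedance", "river") %in% names(data)))
  multi <- names(which(table(data$river) >= 2))
  dat <- data[data$river %in% multi, ]
  if (nrow(dat) < 3) stop("too few multi-year river-years", call. = FALSE)
  y <- dat$rate_per_km
  if (any(y <= 0 | y >= 1)) {
    if (!squeeze)
      stop("rate_per_km touches the boundary of (0, 1); refit with squeeze = TRUE",
           call. = FALSE)
    dat$rate_per_km <- squeeze_proportions(y)
  }
  single_river <- length(unique(dat$river)) < 2
  if (single_river) {
    warning("single river: random intercept is degenerate, fitting fixed-intercept beta GLM")
    m1 <- glmmTMB::glmmTMB(rate_per_km ~ exceedance, data = dat,
                           family = glmmTMB::beta_family())
    m0 <- glmmTMB::glmmTMB(rate_per_km ~ 1, data = dat,
                           family = glmmTMB::beta_family())
  } else {
    m1 <- glmmTMB::glmmTMB(rate_per_km ~ exceedance + (1 | river), data = dat,
                           family = glmmTMB::beta_family())
    m0 <- glmmTMB::glmmTMB(rate_per_km ~ 1 + (1 | river), data = dat,
                           family = glmmTMB::beta_family())
  }
  structure(list(fit = new_smolt_fit(m1, "exceedance beta GLMM"),
                 null = new_smolt_fit(m0, "exceedance beta GLMM (null)"),
                 lrt = lrt(m0, m1)),
            class = "exceedance_fit")
}

#' @export
print.exceedance_fit <- function(x, ...) {
  print(x$fit)
  cat("exceedance effect: "); print(x$lrt)
  invisible(x)
}
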