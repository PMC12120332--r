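# -- variance inflation ------------------------------------------------------

test_that("VIF is exact on orthogonal, correlated and collinear designs", {
  x <- c(1, -1, 1, -1, 1, -1, 1, -1)
  z <- c(1, 1, -1, -1, 1, 1, -1, -1)
  expect_equal(unname(vif(data.frame(x, z))), c(1, 1))
  expect_true(is.infinite(vif(data.frame(a = x, b = 2 * x))[["b"]]))
  # pairwise correlation exactly 0.25 -> VIF 1/(1 - 0.0625) ~ 1.07
  y <- 0.25 * x + sqrt(1 - 0.25^2) * z
  v <- vif(data.frame(x, y))
  expect_equal(unname(v), rep(1 / (1 - 0.0625), 2), tolerance = 1e-10)
  expect_equal(round(unname(v[1]), 2), 1.07)
  expect_error(vif(data.frame(x)), "at least 2")
  expect_error(vif(data.frame(x, k = rep(1, 8))), "constant")
})

test_that("VIF agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(61)
  X <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  X$b <- X$b + 0.5 * X$a
  y <- rnorm(60)
  ours <- vif(X)
  theirs <- car::vif(lm(y ~ a + b + c, data = X))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})

# -- likelihood ratio test ---------------------------------------------------

test_that("the LRT matches a hand-computed binomial likelihood", {
  d <- data.frame(y = c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0),
                  x = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  m0 <- glm(y ~ 1, family = binomial(), data = d)
  m1 <- glm(y ~ x, family = binomial(), data = d)
  # saturated-by-group likelihoods, written out from Bernoulli mass functions
  ll0 <- sum(log(c(rep(0.5, 10)))) # phat = 5/10
  p1 <- 4 / 5; p2 <- 1 / 5
  ll1 <- 4 * log(p1) + 1 * log(1 - p1) + 1 * log(p2) + 4 * log(1 - p2)
  res <- lrt(m0, m1)
  expect_equal(res$statistic, 2 * (ll1 - ll0), tolerance = 1e-8)
  expect_identical(res$df, 1L)
  expect_equal(res$p, pchisq(2 * (ll1 - ll0), 1, lower.tail = FALSE))
})

test_that("identical models give statistic 0, p 1; inverted nesting errors", {
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  m <- lm(y ~ x, data = d)
  res <- lrt(m, m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  m0 <- lm(y ~ 1, data = d)
  expect_error(lrt(m, m0), "not nested")
  expect_error(lrt(lm(y ~ x, data = d[1:10, ]), m), "different numbers")
})

# -- temporal chi-squared ----------------------------------------------------

test_that("temporal chi-squared matches hand arithmetic and edge cases", {
  # later year identical to first-year proportion -> statistic 0
  same <- data.frame(river = "A", year = c(2019, 2020),
                     n_entered = c(100, 100), n_succeeded = c(40, 40))
  expect_equal(temporal_chisq(same)$statistic, 0)

  # O = (30, 70) against E from p1 = 0.5 of n = 100:
  # (30-50)^2/50 + (70-50)^2/50 = 16
  toy <- data.frame(river = "A", year = c(2019, 2020),
                    n_entered = c(100, 100), n_succeeded = c(50, 30))
  res <- temporal_chisq(toy)
  expect_equal(res$statistic, 16)
  expect_identical(res$df, 1L)

  # df equals the number of later-year river-years (13 rivers, 20 later years)
  set.seed(62)
  years_per <- c(4, 3, 3, 3, 2, 2, 2, 2, 2, 2, 2, 3, 3) # 33 rows, 20 later
  counts <- do.call(rbind, lapply(seq_along(years_per), function(i) {
    data.frame(river = paste0("R", i), year = 2018 + seq_len(years_per[i]),
               n_entered = 100,
               n_succeeded = sample(20:80, years_per[i]))
  }))
  expect_identical(temporal_chisq(counts)$df, 20L)

  # a degenerate first year has no valid expectation
  bad <- data.frame(river = "A", year = c(2019, 2020),
                    n_entered = c(50, 50), n_succeeded = c(0, 10))
  expect_error(temporal_chisq(bad), "zero")
})

# -- Kendall's W -------------------------------------------------------------

test_that("Kendall's W hits its concordance extremes", {
  perf <- cbind(a = c(10, 20, 30, 40), b = c(1, 2, 3, 4), c = c(5, 6, 7, 8))
  expect_equal(kendalls_w(perf)$W, 1)
  anti <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  expect_equal(kendalls_w(anti)$W, 0)
  expect_error(kendalls_w(cbind(a = 1:3)), "at least 2")
})

test_that("Kendall's W has null mean 1/m over random rankings", {
  set.seed(63)
  m <- 13; n <- 5
  Ws <- replicate(500, kendalls_w(matrix(rnorm(n * m), n, m))$W)
  expect_lt(abs(mean(Ws) - 1 / m), 3 * sd(Ws) / sqrt(500))
})

test_that("the greedy restriction returns a complete submatrix", {
  mat <- matrix(rnorm(20), 4, 5)
  mat[1, 2] <- NA; mat[3, 2] <- NA; mat[4, 5] <- NA
  sub <- complete_submatrix(mat)
  expect_false(anyNA(sub))
  expect_gte(nrow(sub), 3)
})

# -- Levene / Brown-Forsythe -------------------------------------------------

test_that("Levene's test matches manual ANOVA arithmetic", {
  g <- rep(c("a", "b"), each = 4)
  v <- c(0, 2, 4, 6, 10, 11, 12, 13) # |dev from median|: 3,1,1,3 / 1.5,0.5,0.5,1.5
  res <- levene_test(v, g)
  z <- c(3, 1, 1, 3, 1.5, 0.5, 0.5, 1.5)
  zb <- tapply(z, g, mean)
  ssb <- 4 * sum((zb - mean(z))^2)
  ssw <- sum((z - zb[g])^2)
  f_manual <- (ssb / 1) / (ssw / 6)
  expect_equal(res$statistic, f_manual, tolerance = 1e-10)
  expect_identical(c(res$df1, res$df2), c(1L, 6L))

  # equal spread pattern in every group -> F exactly 0
  eq <- levene_test(c(0, 1, 3, 10, 11, 13), rep(c("a", "b"), each = 3))
  expect_equal(eq$statistic, 0)
})

test_that("Levene's test detects a 10x spread group and matches car", {
  set.seed(64)
  v <- c(rnorm(14, sd = 10), rnorm(13, sd = 1), rnorm(13, sd = 1))
  g <- rep(c("wide", "a", "b"), times = c(14, 13, 13))
  res <- levene_test(v, g)
  expect_lt(res$p, 0.01)
  skip_if_not_installed("car")
  theirs <- car::leveneTest(v ~ factor(g))
  expect_equal(res$statistic, theirs$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, theirs$`Pr(>F)`[1], tolerance = 1e-10)
})

# -- gamma speed models ------------------------------------------------------

test_that("speed models: null identity, homogeneous and separated groups", {
  base <- c(2, 4, 6, 8)
  dat <- data.frame(speed_km_per_day = rep(base, times = 6),
                    river = rep(c("A", "B", "C"), each = 8),
                    year = rep(c(2019, 2020), times = 12))
  fits <- fit_speed_glm(dat)
  expect_gt(fits$lrt_river$p, 0.95) # identical distributions per river
  expect_equal(unname(exp(coef(fits$null$model)[1])), mean(base),
               tolerance = 1e-8)

  set.seed(65)
  sep <- data.frame(speed_km_per_day = c(rlnorm(100, log(2), 0.3),
                                         rlnorm(100, log(10), 0.3)),
                    river = rep(c("slow", "fast"), each = 100),
                    year = 2021)
  expect_lt(fit_speed_glm(sep)$lrt_river$p, 1e-6)
  sep$speed_km_per_day[1] <- -1
  expect_error(fit_speed_glm(sep), "positive")
})

# -- step-down selection -----------------------------------------------------

test_that("step-down removes a null covariate at close to the nominal rate", {
  set.seed(66)
  removed <- replicate(50, {
    n <- 300
    x <- rnorm(n); noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 + x))
    d <- data.frame(y, x, noise)
    full <- glm(y ~ x + noise, family = binomial(), data = d)
    sel <- step_down(full, data = d, alpha = 0.05)
    !"noise" %in% attr(terms(sel$final), "term.labels")
  })
  rate <- mean(removed)
  expect_gt(rate, 0.95 - 3 * sqrt(0.95 * 0.05 / 50))
  # and the signal covariate survives selection every time here
  expect_lt(abs(rate - 0.95), 0.15)
})

test_that("step-down never drops a significant term and records its trace", {
  set.seed(67)
  n <- 500
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(1.5 * d$x))
  full <- glm(y ~ x + z, family = binomial(), data = d)
  sel <- step_down(full, data = d)
  expect_true("x" %in% attr(terms(sel$final), "term.labels"))
  expect_false("z" %in% attr(terms(sel$final), "term.labels"))
  expect_true(all(sel$trace$p[sel$trace$removed] > 0.05))
})

# -- individual success GLMM -------------------------------------------------

test_that("the individual-success GLMM recovers injected condition and burden effects", {
  cfg <- sim_config(n_rivers = 4, n_years = 2, n_fish_per_river = 250,
                    individual_effects = c(condition = 2, tag_burden = -0.3),
                    detection_prob_first = 1, detection_prob_last = 1,
                    year_effect_sd = 0.3, seed = 71L)
  sim <- simulate_study(cfg)
  dat <- individual_success_data(sim)
  fit <- fit_individual_success(dat, select = FALSE)
  co <- fit$full$coefficients
  est <- setNames(co$estimate, co$term)
  se <- setNames(co$se, co$term)
  expect_gt(est[["condition"]], 0)
  expect_lt(est[["tag_burden"]], 0)
  expect_lt(abs(est[["condition"]] - 2), 1.96 * se[["condition"]] + 0.5)
  expect_lt(abs(est[["tag_burden"]] + 0.3), 1.96 * se[["tag_burden"]] + 0.1)
  expect_equal(unname(fit$vif), rep(1, 2), tolerance = 0.25)
})

test_that("the GLMM requires replication in both random effects", {
  d <- data.frame(succeeded = rbinom(50, 1, 0.5), condition = rnorm(50),
                  tag_burden = runif(50, 2, 8), river = "one", year = 2021)
  expect_error(fit_individual_success(d), "2 rivers")
})

# -- landscape beta regression -----------------------------------------------

test_that("a logit-linear beta mean with tiny dispersion is recovered to 2 decimals", {
  set.seed(72)
  n <- 300
  x <- runif(n, 0, 1)
  mu <- plogis(1 + 2 * x)
  phi <- 20000
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  fit <- fit_rate_landscape(data.frame(rate_per_km = y, grassland = x),
                            covariates = "grassland", select = FALSE)
  est <- setNames(fit$full$coefficients$estimate, fit$full$coefficients$term)
  expect_equal(unname(est[["grassland"]]), 2, tolerance = 0.01)
  expect_equal(unname(est[["(Intercept)"]]), 1, tolerance = 0.01)
})

test_that("step-down eliminates a pure-noise covariate from the landscape model", {
  set.seed(73)
  n <- 120
  grass <- rbeta(n, 1.5, 8); noise <- rnorm(n)
  mu <- plogis(3 - 4 * grass)
  phi <- 300
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  fit <- fit_rate_landscape(
    data.frame(rate_per_km = y, grassland = grass, gradient = noise),
    covariates = c("grassland", "gradient"))
  tl <- attr(terms(fit$final$model), "term.labels")
  expect_true("grassland" %in% tl)
  expect_false("gradient" %in% tl)
  expect_true(any(fit$trace$removed))
})

test_that("boundary rates demand the squeeze and the squeeze fixes them", {
  d <- data.frame(rate_per_km = c(0, 0.5, 0.9, 1), grassland = c(1, 2, 3, 4))
  expect_error(fit_rate_landscape(d, covariates = "grassland"), "squeeze")
  y2 <- squeeze_proportions(d$rate_per_km)
  expect_true(all(y2 > 0 & y2 < 1))
})

# -- bedrock contrasts -------------------------------------------------------

test_that("bedrock contrasts separate a dominant class and respect adjustment", {
  set.seed(74)
  n_per <- 40
  bed <- rep(c("igneous", "metamorphic", "sedimentary"), each = n_per)
  eta <- c(igneous = 2, metamorphic = 2.1, sedimentary = 4.5)[bed]
  phi <- 200
  mu <- plogis(eta)
  y <- rbeta(3 * n_per, mu * phi, (1 - mu) * phi)
  fit <- fit_rate_landscape(data.frame(rate_per_km = y, bedrock = bed),
                            covariates = "bedrock", select = FALSE)
  pw <- bedrock_pairwise(fit)
  p <- setNames(pw$contrasts$p.value, pw$contrasts$contrast)
  expect_lt(p[["igneous - sedimentary"]], 0.001)
  expect_lt(p[["metamorphic - sedimentary"]], 0.001)
  expect_gt(p[["igneous - metamorphic"]], 0.05)
})

# -- exceedance GLMM ---------------------------------------------------------

test_that("the exceedance model detects a strong injected discharge effect", {
  set.seed(75)
  rivers <- paste0("R", 1:13)
  d <- do.call(rbind, lapply(rivers, function(r) {
    exc <- runif(3, 10, 90)
    data.frame(river = r, exceedance = exc)
  }))
  riv_eff <- rnorm(13, 0, 0.3)
  mu <- plogis(3 + riv_eff[match(d$river, rivers)] - 0.03 * d$exceedance)
  phi <- 400
  d$rate_per_km <- rbeta(nrow(d), mu * phi, (1 - mu) * phi)
  res <- fit_rate_exceedance(d)
  expect_lt(res$lrt$p, 0.01)
  est <- setNames(res$fit$coefficients$estimate, res$fit$coefficients$term)
  expect_lt(est[["exceedance"]], 0)
})

test_that("a single river falls back to a fixed intercept with a warning", {
  set.seed(76)
  d <- data.frame(river = "only", exceedance = runif(8, 10, 90))
  d$rate_per_km <- rbeta(8, 40, 2)
  expect_warning(res <- fit_rate_exceedance(d), "single river")
  expect_s3_class(res$lrt, "lrt_result")
})
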