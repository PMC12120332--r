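#' Generate synthetic catchment profiles
#'
#' Draws one landscape/geology covariate profile per river: proportions of
#' grassland, woodland, wetland, urban and agricultural land cover (jointly
#' capped at 1 by rescaling on the rare draws whose sum exceeds 1), the
#' proportion of peat in the superficial geology, the dominant bedrock class,
#' catchment area, river gradient and in-channel barrier count.
#'
#' @param cfg A [sim_config()].
#' @return A data frame with one row per river (class `catchment_profiles`).
#' @examples
#' generate_catchments(sim_config(n_rivers = 3, seed = 1))
#' @export
generate_catchments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_rivers
  cover <- vapply(cfg$cover_samplers, sampler_draw, numeric(n), n = n)
  cover <- matrix(cover, nrow = n,
                  dimnames = list(NULL, names(cfg$cover_samplers)))
  tot <- rowSums(cover)
  over <- tot > 1
  if (any(over)) cover[over, ] <- cover[over, ] / tot[over]
  bed <- sample(names(cfg$bedrock_probs), n, replace = TRUE,
                prob = cfg$bedrock_probs)
  out <- data.frame(
    river = sprintf("R%02d", seq_len(n)),
    grassland = cover[, "grassland"],
    woodland = cover[, "woodland"],
    wetland = cover[, "wetland"],
    urban = cover[, "urban"],
    agricultural = cover[, "agricultural"],
    peat = sampler_draw(cfg$peat_sampler, n),
    bedrock = bed,
    area_km2 = sampler_draw(cfg$area_km2, n),
    gradient = sampler_draw(cfg$gradient, n),
    barriers = rpois(n, cfg$barrier_rate),
    stringsAsFactors = FALSE
  )
  class(out) <- c("catchment_profiles", "data.frame")
  out
}

#' True per-kilometre survival of a catchment
#'
#' Inverse-logit of the landscape linear predictor: the bedrock intercept of
#' the catchment's dominant geology plus the cover-proportion slopes for
#' grassland, woodland, wetland and superficial peat. This is the simulator's
#' ground-truth per-km survival, and the quantity the landscape beta
#' regression estimates from realized migration summaries.
#'
#' @param profile One row of [generate_catchments()] output (or a data frame;
#'   all rows are used).
#' @param cfg A [sim_config()] carrying the coefficients.
#' @return Numeric vector of per-km survival probabilities, strictly in (0, 1).
#' @examples
#' cfg <- sim_config(n_rivers = 2, seed = 1)
#' true_rate_per_km(generate_catchments(cfg), cfg)
#' @export
true_rate_per_km <- function(profile, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("grassland", "woodland", "wetland", "peat", "bedrock")
  if (!all(need %in% names(profile)))
    stop("profile must contain ", paste(need, collapse = ", "), call. = FALSE)
  b <- cfg$landscape_effects
  eta <- b[["grassland"]] * profile$grassland +
    b[["woodland"]] * profile$woodland +
    b[["wetland"]] * profile$wetland +
    b[["peat"]] * profile$peat +
    unname(cfg$bedrock_effects[profile$bedrock])
  plogis(eta)
}

#' Simulate tagged cohorts, detections and discharge for a set of catchments
#'
#' For each river and year: draws a river distance and places two audit
#' receivers (one 0.5 km below the release site, one at the river mouth);
#' tags a cohort with lengths, masses (log-mass linear in log-length plus
#' Gaussian noise), tag masses and staggered release dates; realizes each
#' fish's fate as a per-km Bernoulli survival chain at the catchment's true
#' per-km rate, with whole-river success additionally modulated on the logit
#' scale by cohort-centred body condition and tag burden and a random year
#' effect; and emits receiver detections with the configured detection
#' probabilities, plus exact-duplicate, out-of-window and unknown-tag
#' contaminant records for filter testing. A daily mean discharge series is
#' simulated per river-year (lognormal AR(1) with a declining spring trend,
#' scaled by catchment area).
#'
#' @param profiles Output of [generate_catchments()].
#' @param cfg The same [sim_config()].
#' @return A list of class `smolt_sim` with elements `fish`, `detections`,
#'   `receivers`, `marine_detections` (empty unless a marine audit array is
#'   configured), `discharge`, `catchments`, and `truth` (ground truth:
#'   per-river true rates and distances, per-fish fates, death kilometres,
#'   true passage times and condition draws, plus contaminant bookkeeping).
#' @examples
#' cfg <- sim_config(n_rivers = 2, n_fish_per_river = 10, seed = 42)
#' sim <- simulate_cohort(generate_catchments(cfg), cfg)
#' head(sim$fish)
#' @export
simulate_cohort <- function(profiles, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nrow(profiles) >= 1)
  if (cfg$detection_prob_first == 0 && cfg$detection_prob_last == 0)
    warning("both detection probabilities are zero; all detection tables will be empty")
  set.seed((cfg$seed + 1000003L) %% .Machine$integer.max)
  rate <- true_rate_per_km(profiles, cfg)
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  n_riv <- nrow(profiles)
  dist_km <- sampler_draw(cfg$river_distance_km, n_riv)

  receivers <- do.call(rbind, lapply(seq_len(n_riv), function(i) {
    do.call(rbind, lapply(years, function(yr) data.frame(
      river = profiles$river[i], year = yr,
      role = c("first", "last"),
      receiver_id = sprintf("%s-%d-%s", profiles$river[i], yr, c("F", "L")),
      river_km = c(0.5, 0.5 + dist_km[i]),
      elevation_m = c(40 + 1000 * profiles$gradient[i] * dist_km[i], 40),
      stringsAsFactors = FALSE)))
  }))

  fish_l <- list(); det_l <- list(); truth_l <- list(); disch_l <- list()
  mar_l <- list()
  fid <- 0L
  lm_par <- cfg$length_mass
  for (i in seq_len(n_riv)) {
    for (yr in years) {
      n <- cfg$n_fish_per_river
      fid_range <- fid + seq_len(n); fid <- fid + n
      len <- sampler_draw(cfg$fork_length_mm, n)
      eps <- rnorm(n, 0, lm_par[["sigma"]])
      mass <- exp(lm_par[["a"]] + lm_par[["b"]] * log(len) + eps)
      tagm <- sampler_draw(cfg$tag_mass_g, n)
      burden <- 100 * tagm / mass
      rel0 <- as.POSIXct(sprintf("%d-04-10 12:00:00", yr), tz = "UTC")
      release <- rel0 + runif(n, 0, 25) * 86400
      speed <- sampler_draw(cfg$speed_km_per_day, n)

      # whole-river survival, individual modulation centred within cohort
      d <- dist_km[i]
      yr_eff <- if (cfg$year_effect_sd > 0) rnorm(1, 0, cfg$year_effect_sd) else 0
      eta <- qlogis(pmin(pmax(rate[i]^d, 1e-12), 1 - 1e-12)) + yr_eff +
        cfg$individual_effects[["condition"]] * (eps - mean(eps)) +
        cfg$individual_effects[["tag_burden"]] * (burden - mean(burden))
      p_surv <- plogis(eta)
      survived <- runif(n) < p_surv

      # death km (conditional truncated geometric at per-km rate), NA if survived
      death_km <- rep(NA_real_, n)
      ndead <- sum(!survived)
      if (ndead > 0) {
        r <- pmin(pmax(rate[i], 1e-12), 1 - 1e-12)
        u <- runif(ndead)
        k <- ceiling(log(1 - u * (1 - r^d)) / log(r)) # in 1..ceiling(d)
        death_km <- replace(death_km, !survived, pmin(k, d))
      }

      t_first <- release + (0.5 / speed) * 86400
      t_last <- release + ((0.5 + d) / speed) * 86400
      det_first <- runif(n) < cfg$detection_prob_first
      det_last <- survived & (runif(n) < cfg$detection_prob_last)
      det_marine <- survived & (runif(n) < cfg$marine_detection_prob)

      tag_code <- sprintf("A69-1602-%05d", fid_range)
      fish_l[[length(fish_l) + 1L]] <- data.frame(
        fish_id = sprintf("F%05d", fid_range), tag_code = tag_code,
        river = profiles$river[i], year = yr,
        release_datetime = release,
        fork_length_mm = len, mass_g = mass, tag_mass_g = tagm,
        release_site_km = 0, stringsAsFactors = FALSE)

      mk_det <- function(idx, rec_role, times) {
        if (!length(idx)) return(NULL)
        rid <- receivers$receiver_id[receivers$river == profiles$river[i] &
                                       receivers$year == yr &
                                       receivers$role == rec_role]
        # two pings a nominal delay apart at each passage
        data.frame(
          tag_code = rep(tag_code[idx], each = 2L),
          receiver_id = rid,
          timestamp = rep(times[idx], each = 2L) + c(0, 90),
          stringsAsFactors = FALSE)
      }
      det_l[[length(det_l) + 1L]] <- mk_det(which(det_first), "first", t_first)
      det_l[[length(det_l) + 1L]] <- mk_det(which(det_last), "last", t_last)
      if (any(det_marine)) {
        idx <- which(det_marine)
        mar_l[[length(mar_l) + 1L]] <- data.frame(
          tag_code = tag_code[idx],
          receiver_id = sprintf("MAR-%s-%d", profiles$river[i], yr),
          timestamp = t_last[idx] + (2 / speed[idx]) * 86400,
          stringsAsFactors = FALSE)
      }

      truth_l[[length(truth_l) + 1L]] <- data.frame(
        fish_id = sprintf("F%05d", fid_range), river = profiles$river[i],
        year = yr, survived = survived, death_km = death_km,
        condition_true = eps, tag_burden = burden,
        t_pass_first = t_first,
        t_pass_last = as.POSIXct(ifelse(survived, t_last, NA),
                                 tz = "UTC", origin = "1970-01-01"),
        detected_first = det_first, detected_last = det_last,
        stringsAsFactors = FALSE)

      # daily mean discharge, 1 Mar - 31 Jul
      dates <- seq(as.Date(sprintf("%d-03-01", yr)),
                   as.Date(sprintf("%d-07-31", yr)), by = "day")
      nd <- length(dates)
      ar <- numeric(nd); ar[1] <- rnorm(1, 0, 0.3)
      innov <- rnorm(nd, 0, 0.3)
      for (t in 2:nd) ar[t] <- 0.9 * ar[t - 1] + innov[t]
      trend <- seq(0.4, -0.4, length.out = nd)
      base <- 0.05 * profiles$area_km2[i]
      disch_l[[length(disch_l) + 1L]] <- data.frame(
        river = profiles$river[i], year = yr, date = dates,
        discharge_m3s = base * exp(trend + ar), stringsAsFactors = FALSE)
    }
  }

  fish <- do.call(rbind, fish_l)
  detections <- do.call(rbind, det_l[!vapply(det_l, is.null, logical(1))])
  if (is.null(detections))
    detections <- data.frame(tag_code = character(), receiver_id = character(),
                             timestamp = as.POSIXct(character(), tz = "UTC"))
  truth_fish <- do.call(rbind, truth_l)
  n_clean <- nrow(detections)

  # contaminants: exact duplicates, pre-study records, unknown tag codes
  n_dup <- as.integer(cfg$dup_rate * n_clean)
  n_oow <- as.integer(cfg$out_of_window_rate * n_clean)
  n_unk <- as.integer(cfg$unknown_tag_rate * n_clean)
  contam <- list()
  if (n_dup > 0 && n_clean > 0)
    contam$dup <- detections[sample.int(n_clean, n_dup, replace = FALSE), ]
  if (n_oow > 0 && n_clean > 0) {
    idx <- sample.int(n_clean, n_oow, replace = TRUE)
    oow <- detections[idx, ]
    oow$timestamp <- min(fish$release_datetime) - runif(n_oow, 10, 100) * 86400
    contam$oow <- oow
  }
  if (n_unk > 0 && n_clean > 0) {
    idx <- sample.int(n_clean, n_unk, replace = TRUE)
    unk <- detections[idx, ]
    unk$tag_code <- sprintf("A69-9999-%05d", seq_len(n_unk))
    contam$unk <- unk
  }
  raw <- rbind(detections, do.call(rbind, unname(contam)))
  raw <- raw[order(raw$receiver_id, raw$timestamp), ]
  rownames(raw) <- NULL

  truth <- list(
    rivers = data.frame(river = profiles$river, rate_per_km = rate,
                        distance_km = dist_km, stringsAsFactors = FALSE),
    fish = truth_fish,
    clean_detection_count = n_clean,
    contaminants = c(duplicates = n_dup, out_of_window = n_oow,
                     unknown_tag = n_unk)
  )
  marine <- if (length(mar_l)) do.call(rbind, mar_l) else
    data.frame(tag_code = character(), receiver_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"))
  structure(list(fish = fish, detections = raw, receivers = receivers,
                 marine_detections = marine,
                 discharge = do.call(rbind, disch_l), catchments = profiles,
                 truth = truth),
            class = "smolt_sim")
}

#' One-call synthetic study
#'
#' Convenience wrapper: [generate_catchments()] then [simulate_cohort()].
#'
#' @inheritParams generate_catchments
#' @return A `smolt_sim` list; see [simulate_cohort()].
#' @export
simulate_study <- function(cfg) {
  simulate_cohort(generate_catchments(cfg), cfg)
}

#' @export
print.smolt_sim <- function(x, ...) {
  cat("<smolt_sim> ", length(unique(x$fish$river)), " rivers, ",
      nrow(x$fish), " fish, ", nrow(x$detections), " raw detections (",
      x$truth$clean_detection_count, " clean)\n", sep = "")
  invisible(x)
}
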