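test_that("outcome classification covers the four detection patterns", {
  fish <- toy_fish(c("T1", "T2", "T3", "T4"))
  rec <- toy_receivers(d = 10)
  d <- rbind(
    toy_det("T1", "REC-F", "2021-04-16 00:00:00"), # both receivers
    toy_det("T1", "REC-L", "2021-04-18 00:00:00"),
    toy_det("T2", "REC-F", "2021-04-16 06:00:00"), # first only
    toy_det("T3", "REC-L", "2021-04-19 00:00:00")  # last only: passed first undetected
  )                                                # T4: never detected
  out <- classify_outcomes(d, fish, rec)
  out <- out[order(out$fish_id), ]
  expect_identical(out$entered, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(out$succeeded, c(TRUE, FALSE, TRUE, FALSE))
  # duration: last detection at first receiver -> first detection at last
  expect_equal(out$duration_days[1], 2)
  expect_equal(out$speed_km_per_day[1], 10 / 2)
  expect_true(is.na(out$duration_days[3]))
})

test_that("a last-before-first fish stays successful but contributes no speed", {
  fish <- toy_fish("T1")
  d <- rbind(toy_det("T1", "REC-L", "2021-04-16 00:00:00"),
             toy_det("T1", "REC-F", "2021-04-18 00:00:00"))
  out <- classify_outcomes(d, fish, toy_receivers())
  expect_true(out$succeeded)
  expect_true(out$inconsistent)
  expect_true(is.na(out$speed_km_per_day))
})

test_that("speed equals reach distance over duration whenever both are defined", {
  sim <- simulate_study(flat_cfg(rate = 0.98, distance_km = 12, n_fish = 100,
                                 seed = 12L))
  out <- classify_outcomes(filter_detections(sim$detections, sim$fish)$detections,
                           sim$fish, sim$receivers)
  ok <- !is.na(out$speed_km_per_day)
  expect_true(any(ok))
  expect_equal(out$speed_km_per_day[ok], 12 / out$duration_days[ok])
})

test_that("release fallback switches the denominator to fish released", {
  fish <- toy_fish(paste0("T", 1:10))
  d <- toy_det("T1", "REC-L", "2021-04-19 00:00:00")
  out <- classify_outcomes(d, fish, toy_receivers())
  expect_identical(sum(out$entered), 1L)
  # Gryffe-2022 analogue: first receiver dead
  fb <- release_fallback(out, de_first = 0)
  expect_identical(sum(fb$entered), 10L)
  # Deveron-2021 analogue: 2.7% efficiency also triggers it
  fb2 <- release_fallback(out, de_first = 0.027)
  expect_identical(sum(fb2$entered), 10L)
  # healthy receiver: unchanged
  expect_identical(release_fallback(out, de_first = 0.95), out)
})

test_that("first-receiver detection efficiency is the known-passage ratio", {
  out <- data.frame(fish_id = seq_len(120),
                    detected_first = rep(c(TRUE, FALSE, FALSE),
                                         times = c(94, 6, 20)),
                    detected_last = rep(c(TRUE, TRUE, FALSE),
                                        times = c(94, 6, 20)))
  expect_equal(detection_efficiency_first(out), 0.94)
  out2 <- transform(out, detected_first = detected_first | detected_last)
  expect_equal(detection_efficiency_first(out2), 1.0)
  none <- data.frame(detected_first = FALSE, detected_last = FALSE)
  expect_warning(de <- detection_efficiency_first(none), "no fish")
  expect_true(is.na(de))
})

test_that("detection efficiency estimates are unbiased on simulated cohorts", {
  cfg <- flat_cfg(rate = plogis(40), distance_km = 5, n_fish = 5000,
                  p_first = 0.9, p_last = 1, seed = 13L)
  sim <- simulate_study(cfg)
  out <- classify_outcomes(filter_detections(sim$detections, sim$fish)$detections,
                           sim$fish, sim$receivers)
  de <- detection_efficiency_first(out)
  se <- sqrt(0.9 * 0.1 / 5000)
  expect_lt(abs(de - 0.9), 3 * se)
})

test_that("last-receiver efficiency uses the marine audit and degrades to NA", {
  fish <- toy_fish(paste0("T", 1:100))
  out <- data.frame(fish_id = fish$fish_id,
                    detected_first = TRUE,
                    detected_last = rep(c(TRUE, FALSE), times = c(91, 9)))
  marine <- toy_det(fish$tag_code, "MARINE-1", "2021-05-01 00:00:00")
  expect_equal(detection_efficiency_last(out, marine, fish), 0.91)
  expect_true(is.na(detection_efficiency_last(out, NULL, fish)))
})

test_that("rate of migration success inverts the geometric survival chain", {
  expect_equal(rate_of_migration_success(1, 50), 1)
  expect_equal(rate_of_migration_success(0.25, 2), 0.5)
  expect_equal(rate_of_migration_success(0.9^3, 3), 0.9)
  expect_equal(rate_of_migration_success(0, 10), 0)
  expect_error(rate_of_migration_success(0.5, 0), "distance")
})

test_that("standardization round-trips and is monotone", {
  expect_equal(standardize_rate(1, 31.52), 1)
  expect_equal(standardize_rate(0.5, 2), 0.25)
  for (S in c(0.034, 0.3, 0.75, 0.968)) {
    for (d in c(2.3, 10, 31.52, 119)) {
      expect_equal(standardize_rate(rate_of_migration_success(S, d), d), S,
                   tolerance = 1e-12)
    }
  }
  # at fixed success, longer rivers imply higher per-km rates
  rates <- rate_of_migration_success(0.5, c(5, 10, 20, 40))
  expect_true(all(diff(rates) > 0))
  # at fixed rate, longer standard distances imply lower standardized success
  std <- standardize_rate(0.97, c(10, 20, 40))
  expect_true(all(diff(std) < 0))
})

test_that("river-year summaries satisfy the rate-success identity", {
  sim <- simulate_study(sim_config(n_rivers = 4, n_fish_per_river = 60,
                                   seed = 14L))
  flt <- filter_detections(sim$detections, sim$fish)
  summ <- summarize_migration(flt$detections, sim$fish, sim$receivers)
  expect_identical(nrow(summ), 4L)
  ok <- !is.na(summ$success)
  expect_true(all(abs(summ$rate_per_km[ok]^summ$distance_km[ok] -
                        summ$success[ok]) < 1e-9))
  expect_true(all(summ$success[ok] == summ$n_succeeded[ok] / summ$n_entered[ok]))
})

test_that("summaries match ground truth exactly under perfect detection", {
  sim <- simulate_study(flat_cfg(rate = 0.96, distance_km = 15, n_fish = 150,
                                 n_rivers = 3, seed = 15L))
  flt <- filter_detections(sim$detections, sim$fish)
  summ <- summarize_migration(flt$detections, sim$fish, sim$receivers)
  tru <- tapply(sim$truth$fish$survived, sim$truth$fish$river, mean)
  expect_equal(summ$success, as.vector(tru[summ$river]))
})

test_that("an all-failure cohort gives success 0 and rate 0", {
  fish <- toy_fish(paste0("T", 1:5))
  d <- toy_det(paste0("T", 1:5), "REC-F", "2021-04-16 00:00:00")
  out <- classify_outcomes(d, fish, toy_receivers())
  s <- summarize_river_year(out, toy_receivers())
  expect_equal(s$success, 0)
  expect_equal(s$rate_per_km, 0)
})

test_that("the packaged study table reproduces the published extremes", {
  t2 <- migration_success_table()
  expect_identical(t2$river[which.max(t2$migration_success)], "Bush")
  expect_identical(t2$year[which.max(t2$migration_success)], 2022L)
  expect_equal(max(t2$migration_success), 0.968)
  expect_equal(min(t2$migration_success), 0.034)
})
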