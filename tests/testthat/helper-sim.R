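# Shared builders for small deterministic study fixtures.

tiny_cfg <- function(...) {
  sim_config(n_rivers = 2, n_fish_per_river = 20, seed = 101L, ...)
}

# A configuration with a single known per-km survival everywhere:
# landscape slopes zeroed, all bedrock intercepts at qlogis(rate), fixed
# distance, no individual or year effects.
flat_cfg <- function(rate, distance_km, n_fish, n_rivers = 1,
                     p_first = 1, p_last = 1, seed = 1L, ...) {
  sim_config(
    n_rivers = n_rivers, n_fish_per_river = n_fish,
    river_distance_km = sampler_fixed(distance_km),
    landscape_effects = c(grassland = 0, woodland = 0, wetland = 0, peat = 0),
    bedrock_effects = c(igneous = qlogis(rate), metamorphic = qlogis(rate),
                        sedimentary = qlogis(rate)),
    individual_effects = c(condition = 0, tag_burden = 0),
    detection_prob_first = p_first, detection_prob_last = p_last,
    year_effect_sd = 0, seed = seed, ...
  )
}

# Hand-built two-receiver deployment for one river-year.
toy_receivers <- function(river = "Test", year = 2021, d = 10) {
  data.frame(river = river, year = year, role = c("first", "last"),
             receiver_id = c("REC-F", "REC-L"), river_km = c(0.5, 0.5 + d),
             elevation_m = c(50, 5), stringsAsFactors = FALSE)
}

toy_fish <- function(tags, river = "Test", year = 2021) {
  data.frame(fish_id = paste0("F", seq_along(tags)), tag_code = tags,
             river = river, year = year,
             release_datetime = as.POSIXct("2021-04-15 12:00:00", tz = "UTC"),
             fork_length_mm = 140, mass_g = 27, tag_mass_g = 1.6,
             release_site_km = 0, stringsAsFactors = FALSE)
}

toy_det <- function(tag, receiver, when) {
  data.frame(tag_code = tag, receiver_id = receiver,
             timestamp = as.POSIXct(when, tz = "UTC"),
             stringsAsFactors = FALSE)
}
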