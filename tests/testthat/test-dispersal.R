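site_at <- function(lon, lat, acr = "AAA") {
  tibble::tibble(acronym = acr, lon = lon, lat = lat)
}

test_that("the spawning gate follows the temperature threshold", {
  cfg <- dispersal_config(years = 2005L)
  # 15 degC all year: every day Apr 1 - Jul 31 spawns
  f_cold <- per_day_temp_field(rep(15, 365))
  days <- spawning_days(f_cold, site_at(19.5, 40.5), 2005, cfg)
  expect_length(days, 122)
  # 20 degC all year: gate always closed
  f_warm <- per_day_temp_field(rep(20, 365))
  expect_length(spawning_days(f_warm, site_at(19.5, 40.5), 2005, cfg), 0)
  # sinusoid crossing 18 degC between May 31 and Jun 1 (doy 152)
  doy <- 1:365
  temps <- 18 + 5 * sin(2 * pi * (doy - 151.5) / 365)
  f_mix <- per_day_temp_field(temps)
  days <- spawning_days(f_mix, site_at(19.5, 40.5), 2005, cfg)
  expect_equal(days, seq(as.Date("2005-04-01"), as.Date("2005-05-31"),
                         by = "day"))
  expect_length(days, 61)
  # site outside domain errors
  expect_error(spawning_days(f_mix, site_at(30, 40.5), 2005, cfg),
               "outside")
})

test_that("release draws honour counts, kernel and PLD truncation", {
  f <- uniform_field(temp = 15, lon = c(19, 20), lat = c(40, 41))
  cfg <- dispersal_config(particles_per_day = 1000L, seed = 1)
  set.seed(42)
  st <- draw_release_states(f, site_at(19.5, 40.5), "2004-04-01", cfg)
  expect_equal(nrow(st), 1000)
  expect_true(all(st$weight == 1))
  expect_true(all(st$depth >= 0.5 & st$depth <= 10))
  expect_true(all(st$pld >= 1 & st$pld <= 60))
  # kernel sd ~ 1 km in metres
  dx <- (st$lon - 19.5) * 111320 * cos(40.5 * pi / 180)
  expect_equal(sd(dx), 1000, tolerance = 0.15)
  # PLD sample mean near 30 over many draws
  cfg2 <- dispersal_config(particles_per_day = 100000L)
  set.seed(7)
  st2 <- draw_release_states(f, site_at(19.5, 40.5), "2004-04-01", cfg2)
  expect_equal(mean(st2$pld), 30, tolerance = 0.05 / 30)
  # degenerate kernel: all particles exactly at the site
  cfg0 <- dispersal_config(release_sigma_km = 0)
  set.seed(1)
  st0 <- draw_release_states(f, site_at(19.5, 40.5), "2004-04-01", cfg0)
  expect_true(all(st0$lon == 19.5 & st0$lat == 40.5))
})

test_that("RK4 reproduces uniform-drift displacement", {
  f <- uniform_field(u = 0.1, v = 0, lon = c(0, 1), lat = c(0, 1))
  dt <- 6 / 60 / 24
  lon <- 0.2; lat <- 0.5
  for (i in 1:240) { # one day of 6-minute steps
    s <- seascaper:::.rk4_positions(f, lon, lat, 1, (i - 1) * dt, dt)
    lon <- s$lon; lat <- s$lat
  }
  km <- (lon - 0.2) * 111320 * cos(lat * pi / 180) / 1000
  expect_equal(km, 8.640, tolerance = 1e-6 / 8.64)
  expect_equal(lat, 0.5)
  # zero field: no motion (through the exported single-particle API)
  f0 <- uniform_field(u = 0, v = 0)
  st <- tibble::tibble(lon = 0.3, lat = 0.3, depth = 1, pld = 1,
                       weight = 1, origin = "AAA",
                       birth_date = as.Date("2004-01-01"),
                       status = "in_transit")
  s <- rk4_step(f0, st, 0.5, dt)
  expect_equal(c(s$lon, s$lat), c(0.3, 0.3))
  expect_equal(s$status, "in_transit")
})

test_that("RK4 global error on the rotation oracle scales as dt^4", {
  omega <- 4 * pi
  f <- solid_body_field(omega, center = c(0, 0), radius_km = 20, n_days = 2)
  r0 <- 0.08
  period <- 2 * pi / omega
  errs <- vapply(c(24, 12, 6, 3), function(dtm) {
    dt <- dtm / 60 / 24
    lon <- r0; lat <- 0
    for (i in seq_len(round(period / dt))) {
      s <- seascaper:::.rk4_positions(f, lon, lat, 1, 0.2 + (i - 1) * dt, dt)
      lon <- s$lon; lat <- s$lat
    }
    sqrt((lon - r0)^2 + lat^2)
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(c(24, 12, 6, 3))))[2]
  expect_equal(unname(slope), 4, tolerance = 0.3 / 4)
})

test_that("survival weight decays exponentially with time above threshold", {
  site <- site_at(19.5, 40.5)
  f_warm <- uniform_field(u = 0, v = 0, temp = 20, lon = c(19, 20),
                          lat = c(40, 41), n_days = 5)
  cfg <- dispersal_config(dt_minutes = 6, release_sigma_km = 0)
  st <- tibble::tibble(lon = 19.5, lat = 40.5, depth = 5, pld = 1,
                       weight = 1, origin = "AAA",
                       birth_date = as.Date("2004-01-01"),
                       status = "in_transit")
  fin <- advect_particle(f_warm, st, cfg)
  expect_equal(fin$weight, exp(-3), tolerance = 1e-9)
  expect_equal(fin$hot_days, 1, tolerance = 1e-9)
  # half a day above threshold
  st$pld <- 0.5
  fin <- advect_particle(f_warm, st, cfg)
  expect_equal(fin$weight, exp(-1.5), tolerance = 1e-9)
  # cold water: no decay
  f_cold <- uniform_field(u = 0, v = 0, temp = 15, lon = c(19, 20),
                          lat = c(40, 41), n_days = 5)
  st$pld <- 1
  fin <- advect_particle(f_cold, st, cfg)
  expect_equal(fin$weight, 1)
  # weight always equals exp(-mu * hot_days)
  doy_temp <- rep(c(15, 20), length.out = 10)
  f_alt <- per_day_temp_field(doy_temp, lon = c(19, 20), lat = c(40, 41),
                              origin = "2004-01-01")
  st$pld <- 8
  fin <- advect_particle(f_alt, st, cfg)
  expect_equal(fin$weight, exp(-3 * fin$hot_days), tolerance = 1e-9)
  expect_true(fin$weight >= 0 && fin$weight <= 1)
})

test_that("arrival classification applies the 5-km buffer and tie rules", {
  sites <- tibble::tibble(acronym = c("BBB", "AAA"),
                          lon = c(19.5, 19.0), lat = c(40.5, 40.5))
  cfg <- dispersal_config()
  # at a site's coordinates
  expect_equal(classify_arrival(19.5, 40.5, sites, cfg), "BBB")
  # just beyond 5 km from everything
  d_deg <- 5.2 * 1000 / (111320 * cos(40.5 * pi / 180))
  expect_true(is.na(classify_arrival(19.5 + d_deg, 40.5, sites, cfg)))
  # exact tie (co-located sites within radius): alphabetical winner
  mid <- tibble::tibble(acronym = c("ZZZ", "AAA"),
                        lon = c(19.46, 19.46), lat = c(40.5, 40.5))
  expect_equal(classify_arrival(19.47, 40.5, mid, cfg), "AAA")
})

test_that("a closed still-water system retains everything it releases", {
  f <- uniform_field(u = 0, v = 0, temp = 15, lon = c(19, 20),
                     lat = c(40, 41), n_days = 40,
                     origin = "2004-03-25")
  site <- site_at(19.5, 40.5)
  cfg <- dispersal_config(particles_per_day = 10L, years = 2004L,
                          spawn_start = "04-01", spawn_end = "04-05",
                          dt_minutes = 60, pld_mean = 8, pld_sd = 1,
                          pld_range = c(1, 16), seed = 3)
  flux <- run_simulation(f, site, cfg)
  eff <- effectiveness(flux, "actual")
  expect_equal(unname(eff["AAA", "AAA"]), 1)
  # mass bound: arrivals never exceed releases
  rel <- sum(flux$releases$released_actual)
  expect_lte(sum(flux$records$weight), rel + 1e-9)
  # determinism under the config seed
  flux2 <- run_simulation(f, site, cfg)
  expect_identical(tidy(flux), tidy(flux2))
  # empty site list errors
  expect_error(run_simulation(f, site[0, ], cfg), "empty")
})

test_that("raising the mortality threshold never decreases connectivity", {
  g <- grid_spec(19, 20, 40, 41, d_lon = 1 / 45, d_lat = 1 / 45,
                 depth_levels = c(0, 10), time_origin = "2004-03-20",
                 n_days = 60)
  f <- make_synthetic_field(g, gyre_strength = 0.2,
                            mean_temp_winter = 17.5, mean_temp_summer = 24,
                            temp_peak_day = 170, seed = 2)
  sites <- tibble::tibble(acronym = c("AAA", "BBB"),
                          lon = c(19.45, 19.55), lat = c(40.45, 40.55))
  base <- dispersal_config(particles_per_day = 10L, years = 2004L,
                           spawn_start = "04-01", spawn_end = "04-06",
                           spawn_temp_max = 1e9, # keep releases identical
                           dt_minutes = 60, pld_mean = 6, pld_sd = 1,
                           pld_range = c(1, 12), seed = 5)
  no_kill <- base; no_kill$mortality_temp <- 1e9
  e1 <- effectiveness(run_simulation(f, sites, base), "actual")
  e2 <- effectiveness(run_simulation(f, sites, no_kill), "actual")
  expect_true(all(e2 - e1 >= -1e-12))
})
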