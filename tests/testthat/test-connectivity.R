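# build a flux table by hand from per-year arrival weights
hand_flux <- function(weights_by_year, released = 1000,
                      origin = "AAA", dest = "AAA",
                      sites = c("AAA", "BBB")) {
  years <- seq_along(weights_by_year) + 2003
  recs <- tibble::tibble(year = years, month = 4L, origin = origin,
                         destination = dest,
                         weight = weights_by_year)
  recs <- recs[recs$weight > 0, ]
  rels <- tidyr::expand_grid(year = years, month = 4L, origin = sites)
  rels$released_actual <- released
  rels$released_potential <- released
  flux_table(recs, rels, site_order = sites)
}

test_that("effectiveness is the mean of annual arrival ratios", {
  fx <- hand_flux(c(10, 20), released = 1000)
  eff <- effectiveness(fx, "actual")
  expect_equal(unname(eff["AAA", "AAA"]), mean(c(10, 20) / 1000))
  expect_equal(unname(eff["AAA", "BBB"]), 0)
  # actual-normalised effectiveness >= potential-normalised entrywise
  fx2 <- hand_flux(c(10, 20), released = 1000)
  fx2$releases$released_actual <- 500
  ea <- effectiveness(fx2, "actual")
  ep <- effectiveness(fx2, "potential")
  expect_true(all(ea - ep >= -1e-12))
})

test_that("zero-release origin-years are excluded with a warning", {
  fx <- hand_flux(c(10, 20))
  fx$releases$released_actual[fx$releases$year == 2004 &
                                fx$releases$origin == "AAA"] <- 0
  expect_warning(eff <- effectiveness(fx, "actual"), "zero release")
  expect_equal(unname(eff["AAA", "AAA"]), 20 / 1000)
})

test_that("persistence reproduces the hand-computed stabilization coefficients", {
  # positive in exactly 1 of 10 years: 1/sqrt(10)
  fx <- hand_flux(c(7, rep(0, 9)))
  per <- persistence(fx)
  expect_equal(unname(per["AAA", "AAA"]), 1 / sqrt(10), tolerance = 1e-12)
  # (5, 15): mean 10, sd sqrt(50)
  fx2 <- hand_flux(c(5, 15))
  expect_equal(unname(persistence(fx2)["AAA", "AAA"]), 10 / sqrt(50))
  # constant flux: +Inf sentinel; all-zero pair: NA
  fx3 <- hand_flux(c(10, 10, 10))
  per3 <- persistence(fx3)
  expect_true(is.infinite(per3["AAA", "AAA"]))
  expect_true(is.na(per3["BBB", "AAA"]))
  # single year: error
  expect_error(persistence(hand_flux(5)), "2 simulated years")
  # scale invariance
  fx4 <- hand_flux(c(3, 8, 0, 2))
  fx5 <- hand_flux(10 * c(3, 8, 0, 2))
  expect_equal(persistence(fx4)["AAA", "AAA"], persistence(fx5)["AAA", "AAA"])
})

test_that("persistence estimates 1/CV of the generating distribution", {
  set.seed(99)
  n <- 1000
  w <- rgamma(n, shape = 4, rate = 2) # CV = 1/2
  fx <- hand_flux(w)
  expect_equal(unname(persistence(fx)["AAA", "AAA"]), 2, tolerance = 0.05)
})

test_that("rate decomposition recovers constructed rates", {
  # gate closed half the window, no mortality, none arrive
  rels <- tibble::tibble(year = 2004L, month = 4L, origin = "AAA",
                         released_actual = 500,
                         released_potential = 1000,
                         sum_survival = 500, n_arrived = 0L)
  recs <- tibble::tibble(year = integer(), month = integer(),
                         origin = character(), destination = character(),
                         weight = numeric())
  fx <- flux_table(recs, rels, site_order = "AAA")
  rd <- rate_decomposition(fx)
  expect_equal(rd$release_rate, 0.5)
  expect_equal(rd$survival_rate, 1)
  expect_equal(rd$success_rate, 0)
  # full success: all four rates 1
  rels2 <- rels
  rels2$released_actual <- 1000; rels2$sum_survival <- 1000
  rels2$n_arrived <- 1000L
  recs2 <- tibble::tibble(year = 2004L, month = 4L, origin = "AAA",
                          destination = "AAA", weight = 1000)
  rd2 <- rate_decomposition(flux_table(recs2, rels2, site_order = "AAA"))
  expect_equal(unlist(rd2[, -1]), c(release_rate = 1, survival_rate = 1,
                                    arrival_rate = 1, success_rate = 1))
})

test_that("monthly matrices partition the annual arrival weights", {
  recs <- tibble::tibble(year = 2004L, month = c(4L, 5L), origin = "AAA",
                         destination = "AAA", weight = c(6, 9))
  rels <- tidyr::expand_grid(year = 2004L, month = 4:7, origin = "AAA")
  rels$released_actual <- c(300, 310, 0, 0)
  rels$released_potential <- c(300, 310, 300, 310)
  fx <- flux_table(recs, rels, site_order = "AAA")
  mm <- monthly_matrices(fx)
  expect_named(mm, c("4", "5", "6", "7"))
  expect_equal(unname(mm[["4"]]["AAA", "AAA"]), 6 / 300)
  expect_equal(unname(mm[["5"]]["AAA", "AAA"]), 9 / 310)
  expect_true(attr(mm[["6"]], "empty"))
  # partition identity on weights
  monthly_sum <- sum(vapply(c("4", "5"), function(m)
    mm[[m]]["AAA", "AAA"] * rels$released_actual[rels$month == as.integer(m)],
    numeric(1)))
  expect_equal(monthly_sum, sum(recs$weight))
})

test_that("connectivity matrices tidy and plot", {
  fx <- hand_flux(c(10, 20))
  eff <- effectiveness(fx)
  td <- tidy(eff)
  expect_equal(nrow(td), 4)
  p <- autoplot(eff)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_csv(eff, path)
  got <- read.csv(path, check.names = FALSE)
  expect_equal(got[1, "AAA"], 1.5) # percent, 3 decimals
})
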