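test_that("drift generations have binomial variance and absorb at 0", {
  m <- forward_model(n_demes = 2, N = 50,
                     init_freq = rep(0.3, 1), sample_sizes = 10)
  set.seed(61)
  p1 <- replicate(10000, drift_generation(matrix(0.3, 2, 1), m)[1, 1])
  expect_equal(var(p1), 0.3 * 0.7 / 100, tolerance = 0.05)
  # absorption with no mutation
  p0 <- drift_generation(matrix(0, 2, 1), m)
  expect_true(all(p0 == 0))
  # huge N: frequencies barely move
  mN <- forward_model(n_demes = 2, N = 1e6, init_freq = 0.3,
                      sample_sizes = 10)
  set.seed(62)
  expect_lt(max(abs(drift_generation(matrix(0.3, 2, 1), mN) - 0.3)), 0.002)
})

test_that("expected drift F_ST follows the closed form", {
  expect_equal(expected_drift_fst(100, 0), 0)
  expect_equal(expected_drift_fst(100, 2), 0.009975, tolerance = 1e-6)
  expect_equal(expected_drift_fst(400, 2), 1 - (1 - 1 / 800)^2)
})

test_that("sampled drift F_ST is consistent with the expectation", {
  p0 <- sample_allele_frequencies(300, seed = 63)
  for (cell in list(c(100, 2), c(1000, 20))) {
    m <- forward_model(n_demes = 4, N = cell[1], init_freq = p0,
                       sample_sizes = 30)
    r <- simulate_drift_fst(m, cell[2], replicates = 40, seed = 64)
    expect_lt(abs(r$mean_theta - r$expected), 3 * r$mc_se + 5e-4)
  }
  # t = 0: theta within noise of zero
  m0 <- forward_model(n_demes = 4, N = 100, init_freq = p0,
                      sample_sizes = 30)
  r0 <- simulate_drift_fst(m0, 0, replicates = 40, seed = 65)
  expect_lt(abs(r0$mean_theta), 3 * r0$mc_se + 1e-4)
})

test_that("heterozygosity decays as (1 - 1/(2N))^t", {
  N <- 50; t <- 20
  # run 500 demes as independent replicates of one locus
  m <- forward_model(n_demes = 500, N = N, init_freq = 0.5,
                     sample_sizes = 10)
  set.seed(66)
  p <- matrix(0.5, 500, 1)
  for (g in seq_len(t)) p <- drift_generation(p, m)
  h_ratio <- mean(2 * p * (1 - p)) / 0.5
  se <- sd(2 * p * (1 - p)) / 0.5 / sqrt(500)
  expect_lt(abs(h_ratio - (1 - 1 / (2 * N))^t), 3 * se)
})

test_that("generations-to-target inverts the drift accumulation", {
  m <- forward_model(n_demes = 8, N = 10000,
                     init_freq = sample_allele_frequencies(200, seed = 67),
                     sample_sizes = 30)
  expect_equal(generations_to_fst(m, 0.00217, mode = "expected"), 44L)
  m100 <- forward_model(n_demes = 8, N = 100, init_freq = 0.3,
                        sample_sizes = 30)
  expect_equal(generations_to_fst(m100, 0.00217, mode = "expected"), 1L)
  expect_equal(generations_to_fst(m100, 0), 0L)
})

test_that("full mixing drives the equilibrium theta to zero", {
  m <- forward_model(n_demes = 4, N = 100,
                     init_freq = sample_allele_frequencies(100, seed = 68),
                     migrants_per_generation = 100, sample_sizes = 50)
  r <- equilibrium_migration_fst(m, window = 30, max_generations = 400,
                                 seed = 69)
  expect_lt(abs(r$equilibrium_theta), 0.01)
})

test_that("equilibrium theta decreases with the migrant count", {
  eq_at <- function(mig) {
    mean(vapply(1:3, function(i) {
      m <- forward_model(n_demes = 4, N = 200,
                         init_freq = sample_allele_frequencies(
                           150, seed = 70),
                         migrants_per_generation = mig, sample_sizes = 50)
      suppressWarnings(
        equilibrium_migration_fst(m, window = 40, max_generations = 300,
                                  seed = 70 + i)$equilibrium_theta)
    }, numeric(1)))
  }
  eqs <- vapply(c(1, 5, 15, 50), eq_at, numeric(1))
  expect_true(all(diff(eqs) < 0))
})

test_that("power is calibrated at t = 0 and increases with divergence", {
  p0 <- sample_allele_frequencies(150, seed = 71)
  m <- forward_model(n_demes = 4, N = 400, init_freq = p0,
                     sample_sizes = 25)
  null <- powsim_power(m, 0, replicates = 100, seed = 72)
  bound <- 1.96 * sqrt(0.05 * 0.95 / 100)
  expect_lt(abs(null$power - 0.05), bound + 0.02)
  ladder <- vapply(c(1, 4, 16), function(t)
    powsim_power(m, t, replicates = 60, seed = 73)$power, numeric(1))
  expect_true(all(diff(ladder) >= 0))
})

test_that("haplotypic drift uses the 2N convention by default", {
  h <- sample_haplotype_frequencies(10, concentration = 2, seed = 74)
  m <- forward_model(n_demes = 7, N = 500, marker_type = "haplotypic",
                     init_freq = h, sample_sizes = 50)
  r <- simulate_drift_fst(m, 20, replicates = 40, seed = 75)
  # 2N convention: expectation 1 - (1 - 1/1000)^20 = 0.0198
  expect_lt(abs(r$mean_theta - expected_drift_fst(500, 20)),
            3 * r$mc_se + 2e-3)
  # strict haploid mode drifts twice as fast
  ms <- forward_model(n_demes = 7, N = 500, marker_type = "haplotypic",
                      init_freq = h, sample_sizes = 50,
                      strict_haploid = TRUE)
  rs <- simulate_drift_fst(ms, 20, replicates = 40, seed = 75)
  expect_gt(rs$mean_theta, 1.5 * r$mean_theta)
})
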