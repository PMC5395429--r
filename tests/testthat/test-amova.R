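test_that("AMOVA F_ST agrees with theta on two-population data", {
  set.seed(51)
  geno <- matrix(rbinom(30 * 8, 2, runif(8, 0.1, 0.5)), 30, 8, byrow = TRUE)
  ds <- toy_dataset(geno, rep(c("A", "B"), each = 15))
  am <- amova(ds, n_perm = 0)
  th <- wc_theta(ds, n_perm = 0, n_boot = 0)
  expect_equal(am$fstats[["f_st"]], th$theta, tolerance = 1e-9)
})

test_that("percent variation sums to 100 on arbitrary inputs", {
  set.seed(52)
  for (i in 1:5) {
    ds <- simulate_genotype_dataset(
      n_loci = 30, n_pops = 4, sample_sizes = rep(10, 4),
      target_fst = runif(1, 0, 0.2), seed = 52 + i)
    part <- setNames(c(1, 1, 2, 2), sort(unique(ds$ind$pop)))
    am <- amova(ds, part, n_perm = 0)
    expect_equal(sum(am$percent, na.rm = TRUE), 100, tolerance = 1e-9)
  }
})

test_that("identical populations give F_CT near zero, variation within", {
  set.seed(53)
  block <- matrix(rbinom(12 * 25, 2, 0.35), 12, 25)
  geno <- rbind(block, block, block, block) # four copies of one sample
  ds <- toy_dataset(geno, rep(c("A", "B", "C", "D"), each = 12))
  am <- amova(ds, setNames(c(1, 1, 2, 2), c("A", "B", "C", "D")),
              n_perm = 0)
  expect_lt(abs(am$fstats[["f_ct"]]), 0.02)
  expect_gt(am$percent[["within_pops"]], 95)
})

test_that("planted three-group structure is recovered by F_CT and the scan", {
  make_planted <- function(seed) {
    set.seed(seed)
    p_anc <- runif(200, 0.1, 0.5)
    fst_b <- 0.02
    shape <- (1 - fst_b) / fst_b
    # three group-level frequency vectors; pops copy their group exactly
    grp_freq <- lapply(1:3, function(g)
      rbeta(200, p_anc * shape, (1 - p_anc) * shape))
    pops <- sprintf("P%d", 1:6)
    grp_of <- rep(1:3, each = 2)
    geno <- do.call(rbind, lapply(1:6, function(k)
      matrix(rbinom(20 * 200, 2, rep(grp_freq[[grp_of[k]]], each = 20)),
             20, 200)))
    list(ds = toy_dataset(geno, rep(pops, each = 20)),
         partition = setNames(grp_of, pops))
  }
  fcts <- vapply(1:10, function(i) {
    pl <- make_planted(530 + i)
    amova(pl$ds, pl$partition, n_perm = 0)$fstats[["f_ct"]]
  }, numeric(1))
  expect_lt(abs(mean(fcts) - 0.02), 3 * sd(fcts) / sqrt(10))
  # scan ranks the true grouping first
  pl <- make_planted(999)
  sc <- scan_partitions(pl$ds, k_values = 3)
  best <- attr(sc, "best_partition")
  expect_equal(as.integer(factor(best[names(pl$partition)])),
               as.integer(factor(pl$partition)))
})

test_that("the partition scan enumerates Stirling numbers of partitions", {
  expect_length(seascaper:::.partitions_k(3, 2), 3)
  expect_length(seascaper:::.partitions_k(10, 2), 511)
  expect_length(seascaper:::.partitions_k(10, 3), 9330)
  ds <- simulate_genotype_dataset(n_loci = 10, n_pops = 3,
                                  sample_sizes = rep(8, 3), seed = 3)
  sc <- scan_partitions(ds, k_values = 2)
  expect_equal(nrow(sc), 3)
  # combinatorial guard
  big <- simulate_genotype_dataset(n_loci = 2, n_pops = 13,
                                   sample_sizes = rep(4, 13), seed = 4)
  expect_error(scan_partitions(big), "12 populations")
})

test_that("permutation p-values flag planted group structure", {
  set.seed(55)
  pl_freq <- list(runif(60, 0.2, 0.4), runif(60, 0.4, 0.6))
  geno <- do.call(rbind, lapply(c(1, 1, 2, 2), function(g)
    matrix(rbinom(15 * 60, 2, rep(pl_freq[[g]], each = 15)), 15, 60)))
  ds <- toy_dataset(geno, rep(c("A", "B", "C", "D"), each = 15))
  am <- amova(ds, setNames(c(1, 1, 2, 2), c("A", "B", "C", "D")),
              n_perm = 99, seed = 9)
  expect_lt(am$p[["f_st"]], 0.05)
  # F_CT permutes only 4 populations across 2 groups: 3 distinct
  # arrangements, so its permutation p is coarse but defined
  expect_true(am$p[["f_ct"]] > 0 && am$p[["f_ct"]] <= 1)
})

test_that("BH adjustment matches the hand-stepped example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
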