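# Shared fixtures: tiny analytic fields, toy genotype tables, and the
# independent Weir & Cockerham (1984) oracle used to cross-check the
# nested-ANOVA implementation.

# uniform-velocity, uniform-temperature field on a small grid
uniform_field <- function(u = 0, v = 0, temp = 15,
                          lon = c(0, 1), lat = c(0, 1),
                          d = 0.05, depths = c(0, 10), n_days = 3,
                          origin = "2004-01-01", wet = NULL) {
  g <- grid_spec(lon[1], lon[2], lat[1], lat[2], d_lon = d, d_lat = d,
                 depth_levels = depths, time_origin = origin,
                 n_days = n_days)
  dims <- c(length(g$lon), length(g$lat), length(depths), n_days)
  if (is.null(wet)) wet <- matrix(TRUE, dims[1], dims[2])
  ocean_field(g, array(u, dims), array(v, dims), array(temp, dims), wet)
}

# field with an arbitrary per-day temperature series (uniform in space)
per_day_temp_field <- function(temps, lon = c(19, 20), lat = c(40, 41),
                               d = 0.1, origin = "2005-01-01") {
  g <- grid_spec(lon[1], lon[2], lat[1], lat[2], d_lon = d, d_lat = d,
                 depth_levels = c(0, 10), time_origin = origin,
                 n_days = length(temps))
  dims <- c(length(g$lon), length(g$lat), 2L, length(temps))
  temp <- array(rep(temps, each = prod(dims[1:3])), dims)
  ocean_field(g, array(0, dims), array(0, dims), temp,
              matrix(TRUE, dims[1], dims[2]))
}

# small genotype dataset from an explicit matrix
toy_dataset <- function(geno, pops) {
  ids <- sprintf("%s_%03d", pops, stats::ave(seq_along(pops), pops,
                                             FUN = seq_along))
  genotype_dataset(geno, tibble::tibble(id = ids, pop = pops))
}

# Literal transcription of the Weir & Cockerham (1984) single-locus
# formulas (n-bar, n_c, p-bar, s^2, h-bar) - the independent oracle.
wc84_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# multilocus WC84 theta on a genotype matrix, via the oracle formulas
wc84_theta <- function(geno, pop) {
  num <- den <- 0
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    ok <- !is.na(g)
    pops <- unique(pop[ok])
    if (length(pops) < 2) next
    n <- sapply(pops, function(pp) sum(ok & pop == pp))
    p <- sapply(pops, function(pp) sum(g[ok & pop == pp]) / (2 * sum(ok & pop == pp)))
    h <- sapply(pops, function(pp) mean(g[ok & pop == pp] == 1))
    k <- wc84_components(n, p, h)
    num <- num + k[["a"]]
    den <- den + sum(k)
  }
  num / den
}
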