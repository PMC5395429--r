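#' Forward-time multi-deme Wright-Fisher model configuration
#'
#' Demes of constant size `N` diverge from a common ancestral allele (or
#' haplotype) pool by binomial/multinomial drift, optionally exchanging
#' `m` migrants per generation (island model) and mutating symmetrically.
#'
#' The drift increment per generation is `1/(2N)` for the entered `N`
#' regardless of marker type: published mtDNA power tables are reproduced
#' only when the "haploid" female effective size drives diploid-style
#' drift, so the 2N-copies convention is the default for both marker
#' types. A `strict_haploid = TRUE` flag switches to an increment of
#' `1/N` for haplotypic markers.
#'
#' @param n_demes Number of demes.
#' @param N Effective deme size (individuals, as entered).
#' @param marker_type `"biallelic_diploid"` or `"haplotypic"`.
#' @param init_freq Initial frequencies shared by all demes: a numeric
#'   vector of per-locus minor-allele frequencies (biallelic), or a single
#'   haplotype-frequency vector summing to 1 (haplotypic).
#' @param mutation_rate Per-generation symmetric mutation rate (default 0;
#'   drift/migration scenarios also use 2.5e-8 and 1e-6).
#' @param migrants_per_generation Island-model migrant count `m` (default
#'   0 = pure drift).
#' @param sample_sizes Per-deme sample sizes (individuals) drawn when
#'   estimating F(ST) or power.
#' @param strict_haploid Use `1/N` drift for haplotypic markers.
#' @return A `forward_model`.
#' @export
forward_model <- function(n_demes, N,
                          marker_type = c("biallelic_diploid", "haplotypic"),
                          init_freq,
                          mutation_rate = 0,
                          migrants_per_generation = 0,
                          sample_sizes = NULL,
                          strict_haploid = FALSE) {
  marker_type <- match.arg(marker_type)
  stopifnot(n_demes >= 2, N >= 1, mutation_rate >= 0,
            migrants_per_generation >= 0)
  if (migrants_per_generation > N) abort("m cannot exceed N")
  if (marker_type == "haplotypic") {
    if (abs(sum(init_freq) - 1) > 1e-8)
      abort("haplotype frequencies must sum to 1")
  } else {
    if (any(init_freq < 0 | init_freq > 1))
      abort("allele frequencies must be in [0, 1]")
  }
  if (!is.null(sample_sizes) && length(sample_sizes) == 1)
    sample_sizes <- rep(sample_sizes, n_demes)
  if (!is.null(sample_sizes) && length(sample_sizes) != n_demes)
    abort("sample_sizes must have one entry per deme")
  structure(list(n_demes = as.integer(n_demes), N = N,
                 marker_type = marker_type, init_freq = init_freq,
                 mutation_rate = mutation_rate,
                 m = migrants_per_generation,
                 sample_sizes = sample_sizes,
                 strict_haploid = strict_haploid),
            class = "forward_model")
}

# number of resampled gene copies per generation
.n_copies <- function(model) {
  if (model$marker_type == "haplotypic" && model$strict_haploid)
    ceiling(model$N) else 2 * model$N
}

#' One generation of drift, migration and mutation
#'
#' Binomial (biallelic) or multinomial (haplotypic) resampling of the
#' deme's gene copies, followed by deterministic island-model migration
#' `p' = (1 - m/N) p + (m/N) mean(p)` and symmetric mutation.
#'
#' @param freq Frequencies: demes x loci matrix (biallelic) or demes x
#'   haplotypes matrix (haplotypic).
#' @param model A [forward_model()].
#' @return Updated frequency matrix.
#' @export
drift_generation <- function(freq, model) {
  copies <- .n_copies(model)
  if (model$marker_type == "biallelic_diploid") {
    p <- matrix(rbinom(length(freq), copies, freq) / copies,
                nrow(freq), ncol(freq))
  } else {
    p <- t(apply(freq, 1, function(f)
      as.numeric(rmultinom(1, copies, f)) / copies))
  }
  if (model$m > 0) {
    mig <- model$m / model$N
    pbar <- matrix(colMeans(p), nrow(p), ncol(p), byrow = TRUE)
    p <- (1 - mig) * p + mig * pbar
  }
  mu <- model$mutation_rate
  if (mu > 0) {
    if (model$marker_type == "biallelic_diploid")
      p <- p * (1 - mu) + (1 - p) * mu
    else
      p <- p * (1 - mu) + mu / ncol(p)
  }
  p
}

#' Expected drift F(ST)
#'
#' Inbreeding accumulation under pure drift from a common ancestor:
#' `1 - (1 - 1/(2N))^t`.
#'
#' @param N Effective deme size.
#' @param t Generations of drift.
#' @return Expected F(ST), dimensionless.
#' @export
expected_drift_fst <- function(N, t) {
  stopifnot(N >= 1, all(t >= 0))
  1 - (1 - 1 / (2 * N))^t
}

# initial frequency matrix (demes share the ancestral pool)
.init_freq_matrix <- function(model) {
  if (model$marker_type == "biallelic_diploid")
    matrix(model$init_freq, model$n_demes, length(model$init_freq),
           byrow = TRUE)
  else
    matrix(model$init_freq, model$n_demes, length(model$init_freq),
           byrow = TRUE)
}

# sample genotype counts per deme under HW and return WC theta.
# biallelic: draws (n0, n1, n2) per deme x locus; haplotypic: multinomial
# haplotype counts treated as haploid samples (theta = a/(a+b) analogue
# via grouped gene copies with no within-individual level).
.sample_theta <- function(freq, model) {
  ns <- model$sample_sizes
  if (is.null(ns)) abort("model needs sample_sizes for estimation")
  r <- model$n_demes
  if (model$marker_type == "biallelic_diploid") {
    L <- ncol(freq)
    nmat <- matrix(rep(ns, L), r, L)
    # genotype counts under HW: hom-minor then het among the rest
    p2 <- freq^2; p1 <- 2 * freq * (1 - freq)
    n2 <- matrix(rbinom(r * L, nmat, p2), r, L)
    cond <- ifelse(1 - p2 > 0, p1 / (1 - p2), 0)
    n1 <- matrix(rbinom(r * L, nmat - n2, pmin(cond, 1)), r, L)
    comp <- vapply(seq_len(L), function(j)
      .locus_components(nmat[, j], 2 * n2[, j] + n1[, j], n1[, j],
                        rep(1L, r))[2:4], numeric(3))
    b <- sum(comp[1, ], na.rm = TRUE)
    tot <- sum(comp, na.rm = TRUE)
    b / tot
  } else {
    counts <- t(vapply(seq_len(r), function(i)
      as.numeric(rmultinom(1, ns[i], freq[i, ])), numeric(ncol(freq))))
    .haploid_theta(counts)
  }
}

# Weir-Cockerham-style theta for haploid counts (demes x haplotypes):
# two-level ANOVA of haplotype indicators, copies within demes,
# ratio-of-sums over haplotypes.
.haploid_theta <- function(counts) {
  n <- rowSums(counts)
  keep <- n > 0
  counts <- counts[keep, , drop = FALSE]
  n <- n[keep]
  r <- nrow(counts)
  if (r < 2) return(NA_real_)
  N <- sum(n)
  a_sum <- 0; tot_sum <- 0
  for (h in seq_len(ncol(counts))) {
    Tt <- sum(counts[, h])
    if (Tt == 0 || Tt == N) next
    U_tot <- Tt^2 / N
    U_pop <- sum(counts[, h]^2 / n)
    U_copy <- Tt
    # E[U_pop - U_tot] = sig_b (N - sum n^2/N) + sig_w (r - 1)
    # E[U_copy - U_pop] = sig_w (N - r)
    sig_w <- (U_copy - U_pop) / (N - r)
    sig_b <- (U_pop - U_tot - sig_w * (r - 1)) / (N - sum(n^2) / N)
    a_sum <- a_sum + sig_b
    tot_sum <- tot_sum + sig_b + sig_w
  }
  if (tot_sum == 0) return(NA_real_)
  a_sum / tot_sum
}

#' Mean sampled F(ST) after t generations of drift
#'
#' Each replicate drifts the model `t` generations from the shared initial
#' frequencies, draws per-deme samples, and estimates multilocus
#' Weir-Cockerham theta; the replicate mean and its Monte Carlo standard
#' error are returned.
#'
#' @param model A [forward_model()] with `sample_sizes` set.
#' @param t Generations of drift.
#' @param replicates Number of replicates (default 200).
#' @param seed Integer seed.
#' @return A tibble with `mean_theta`, `mc_se`, `replicates`, `expected`.
#' @export
simulate_drift_fst <- function(model, t, replicates = 200, seed = 1L) {
  .with_seed(seed, {
    thetas <- vapply(seq_len(replicates), function(i) {
      p <- .init_freq_matrix(model)
      for (g in seq_len(t)) p <- drift_generation(p, model)
      .sample_theta(p, model)
    }, numeric(1))
    tibble(mean_theta = mean(thetas, na.rm = TRUE),
           mc_se = sd(thetas, na.rm = TRUE) / sqrt(sum(!is.na(thetas))),
           replicates = replicates,
           expected = expected_drift_fst(model$N, t))
  })
}

#' Generations of pure drift needed to reach a target F(ST)
#'
#' Expected mode inverts the closed form `1 - (1 - 1/(2N))^t >= target`;
#' sampled mode records, per replicate, the first generation at which the
#' sampled multilocus theta meets the target, and returns the median.
#'
#' @param model A [forward_model()].
#' @param target_fst Target differentiation in (0, 1) (0 returns 0).
#' @param mode `"expected"` or `"sampled"`.
#' @param replicates Replicates for sampled mode.
#' @param max_generations Guard for sampled mode.
#' @param seed Integer seed.
#' @return Number of generations (median over replicates in sampled mode);
#'   `NA` with a warning if the target is unreachable.
#' @export
generations_to_fst <- function(model, target_fst,
                               mode = c("expected", "sampled"),
                               replicates = 20, max_generations = 1000,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (target_fst < 0 || target_fst >= 1)
    abort("target_fst must be in [0, 1)")
  if (target_fst == 0) return(0L)
  if (mode == "expected") {
    t <- ceiling(log1p(-target_fst) / log1p(-1 / (2 * model$N)))
    return(as.integer(t))
  }
  .with_seed(seed, {
    firsts <- vapply(seq_len(replicates), function(i) {
      p <- .init_freq_matrix(model)
      for (g in seq_len(max_generations)) {
        p <- drift_generation(p, model)
        th <- .sample_theta(p, model)
        if (!is.na(th) && th >= target_fst) return(g)
      }
      NA_real_
    }, numeric(1))
    if (anyNA(firsts))
      warn("target F_ST not reached in max_generations for some replicates")
    as.integer(median(firsts, na.rm = TRUE))
  })
}

#' Equilibrium F(ST) under drift-migration balance
#'
#' Runs the island model until a sliding-window Mann-Kendall slope test on
#' the sampled theta series declares stationarity (p > 0.5 on the last
#' `window` generations, twice in a row), then reports the window mean and
#' the first generation at which sampled theta reached that mean.
#'
#' @param model A [forward_model()] with `m >= 1` and `sample_sizes`.
#' @param window Window length in generations (default 50).
#' @param max_generations Non-convergence guard (default 2,000).
#' @param seed Integer seed.
#' @return A tibble with `equilibrium_theta`, `first_passage_generation`,
#'   `generations_run`, `converged`.
#' @export
equilibrium_migration_fst <- function(model, window = 50,
                                      max_generations = 2000, seed = 1L) {
  if (model$m < 1) abort("equilibrium analysis needs m >= 1")
  .with_seed(seed, {
    p <- .init_freq_matrix(model)
    thetas <- numeric(0)
    hits <- 0
    converged <- FALSE
    g <- 0
    while (g < max_generations) {
      g <- g + 1
      p <- drift_generation(p, model)
      thetas[g] <- .sample_theta(p, model)
      if (g >= window && g %% 10 == 0) {
        wi <- thetas[(g - window + 1):g]
        tr <- hamed_rao_trend(wi)
        hits <- if (tr$p > 0.5) hits + 1 else 0
        if (hits >= 2) { converged <- TRUE; break }
      }
    }
    eq <- mean(tail(thetas, window))
    first <- which(thetas >= eq)[1]
    if (!converged) warn("equilibrium not reached within max_generations")
    tibble(equilibrium_theta = eq,
           first_passage_generation = as.integer(first),
           generations_run = g, converged = converged)
  })
}

#' POWSIM-style power analysis
#'
#' Per replicate: drift `t` generations from the shared initial
#' frequencies, draw per-deme samples, build the per-locus contingency
#' table of allele (or haplotype) counts across demes, sum the chi-square
#' statistics and degrees of freedom over polymorphic loci, and test
#' against the summed chi-square tail. Power is the fraction of
#' replicates significant at `alpha`; the mean sampled theta is reported
#' alongside.
#'
#' @param model A [forward_model()] with `sample_sizes`.
#' @param t Generations of drift.
#' @param replicates Replicates (default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return A `power_result` tibble row: `power`, `mean_theta`, `mc_se`,
#'   `replicates`, `alpha`, `expected_fst`.
#' @export
powsim_power <- function(model, t, replicates = 200, alpha = 0.05,
                         seed = 1L) {
  ns <- model$sample_sizes
  if (is.null(ns)) abort("model needs sample_sizes")
  r <- model$n_demes
  .with_seed(seed, {
    res <- vapply(seq_len(replicates), function(i) {
      p <- .init_freq_matrix(model)
      for (g in seq_len(t)) p <- drift_generation(p, model)
      if (model$marker_type == "biallelic_diploid") {
        L <- ncol(p)
        nmat <- matrix(rep(ns, L), r, L)
        p2 <- p^2; p1 <- 2 * p * (1 - p)
        n2 <- matrix(rbinom(r * L, nmat, p2), r, L)
        cond <- ifelse(1 - p2 > 0, p1 / (1 - p2), 0)
        n1 <- matrix(rbinom(r * L, nmat - n2, pmin(cond, 1)), r, L)
        minor <- 2 * n2 + n1              # demes x loci allele counts
        major <- 2 * nmat - minor
        chi <- .chisq_sum_biallelic(minor, major)
        comp <- vapply(seq_len(L), function(j)
          .locus_components(nmat[, j], minor[, j], n1[, j],
                            rep(1L, r))[2:4], numeric(3))
        th <- sum(comp[1, ], na.rm = TRUE) / sum(comp, na.rm = TRUE)
      } else {
        counts <- t(vapply(seq_len(r), function(k)
          as.numeric(rmultinom(1, ns[k], p[k, ])), numeric(ncol(p))))
        chi <- .chisq_haplotypes(counts)
        th <- .haploid_theta(counts)
      }
      c(pval = chi, theta = th)
    }, numeric(2))
    pw <- mean(res["pval", ] < alpha)
    structure(tibble(power = pw,
                     mean_theta = mean(res["theta", ], na.rm = TRUE),
                     mc_se = sd(res["theta", ], na.rm = TRUE) /
                       sqrt(replicates),
                     replicates = replicates, alpha = alpha,
                     expected_fst = expected_drift_fst(model$N, t)),
              class = c("power_result", class(tibble())))
  })
}

# summed chi-square p-value over biallelic loci (2 x r allele-count tables)
.chisq_sum_biallelic <- function(minor, major) {
  tot_col <- minor + major             # 2n per deme (column sums per locus)
  Tminor <- colSums(minor); Ttot <- colSums(tot_col)
  keep <- Tminor > 0 & Tminor < Ttot   # polymorphic in the pooled sample
  if (!any(keep)) return(1)
  phat <- rep(Tminor[keep] / Ttot[keep], each = nrow(minor))
  exp_minor <- tot_col[, keep, drop = FALSE] * phat
  exp_major <- tot_col[, keep, drop = FALSE] * (1 - phat)
  X2 <- sum((minor[, keep, drop = FALSE] - exp_minor)^2 / exp_minor +
              (major[, keep, drop = FALSE] - exp_major)^2 / exp_major)
  df <- sum(keep) * (nrow(minor) - 1)
  pchisq(X2, df, lower.tail = FALSE)
}

# chi-square p for one haplotype-count table (demes x haplotypes)
.chisq_haplotypes <- function(counts) {
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 2) return(1)
  n <- rowSums(counts); Tt <- colSums(counts); N <- sum(n)
  expd <- outer(n, Tt) / N
  X2 <- sum((counts - expd)^2 / expd)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  pchisq(X2, df, lower.tail = FALSE)
}
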