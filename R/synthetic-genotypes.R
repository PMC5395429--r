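#' Sample ancestral minor-allele frequencies
#'
#' Per-locus ancestral (pooled) minor-allele frequencies for the synthetic
#' genotype generator. `maf_dist` is either a single fixed value in
#' (0, 0.5], or two Beta shape parameters for a Beta draw rescaled to
#' (0, 0.5]. Frequencies are bounded away from 0 so that the expected
#' minor-allele count in the full sample is at least one copy
#' (`p >= 1 / (2 * total_n)`).
#'
#' @param n_loci Number of loci.
#' @param maf_dist Length-1 fixed value or length-2 Beta shapes
#'   (default `c(1, 1)`: uniform on (0, 0.5]).
#' @param total_n Total individuals the bound is computed for.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_loci`.
#' @export
sample_allele_frequencies <- function(n_loci, maf_dist = c(1, 1),
                                      total_n = 240, seed = NULL) {
  lo <- 1 / (2 * total_n)
  .with_seed(seed, {
    p <- if (length(maf_dist) == 1) rep(maf_dist, n_loci)
    else 0.5 * rbeta(n_loci, maf_dist[1], maf_dist[2])
    pmin(pmax(p, lo), 0.5)
  })
}

#' Dirichlet haplotype frequencies
#'
#' Synthetic stand-in for an empirical mtDNA haplotype spectrum: a single
#' Dirichlet draw of `k` haplotype frequencies summing to one. Large
#' `concentration` approaches the uniform spectrum `1/k`.
#'
#' @param k Number of haplotypes (>= 2).
#' @param concentration Common Dirichlet concentration parameter.
#' @param seed Integer seed.
#' @return Numeric vector of length `k` summing to 1.
#' @export
sample_haplotype_frequencies <- function(k, concentration = 1, seed = NULL) {
  if (k < 2) abort("k must be >= 2")
  .with_seed(seed, {
    g <- rgamma(k, shape = concentration, rate = 1)
    g / sum(g)
  })
}

#' Simulate a structured RAD-SNP genotype dataset
#'
#' Generates the raw multi-SNP-per-locus dataset the filtering stage
#' expects. Population allele frequencies are drawn around ancestral ones
#' with the Balding-Nichols Beta model parameterised by `target_fst`
#' (`target_fst = 0` copies the ancestral frequencies exactly); genotypes
#' are sampled under Hardy-Weinberg within populations; loci carry 1-3
#' SNPs in the proportions of `multi_snp_mix`; missingness is applied per
#' individual, uniformly across SNPs, at rate `missing_rate_individual`
#' (plus an optional per-locus knob).
#'
#' Defaults emulate the study panel: 1,122 polymorphic loci split
#' 261/420/441 into 1-, 2- and 3-SNP loci (2,424 SNPs in exact-count
#' mode) across 8 samples.
#'
#' @param n_loci Number of RAD loci.
#' @param n_pops Number of populations.
#' @param sample_sizes Individuals per population (length `n_pops`).
#' @param target_fst Balding-Nichols differentiation parameter in [0, 1).
#' @param maf_dist See [sample_allele_frequencies()].
#' @param multi_snp_mix Proportions of loci carrying 1/2/3 SNPs.
#' @param exact_counts If `TRUE`, assign SNP-count classes deterministically
#'   in the given proportions; otherwise multinomially.
#' @param missing_rate_individual Per-individual missingness rate (< 0.25).
#' @param missing_rate_locus Optional additional per-locus missingness.
#' @param pop_names Optional population labels.
#' @param seed Integer seed.
#' @return A [genotype_dataset()].
#' @export
simulate_genotype_dataset <- function(n_loci = 1122L,
                                      n_pops = 8L,
                                      sample_sizes = c(31, 30, 25, 26,
                                                       28, 31, 30, 29),
                                      target_fst = 0,
                                      maf_dist = c(1, 1),
                                      multi_snp_mix = c(261, 420, 441) / 1122,
                                      exact_counts = TRUE,
                                      missing_rate_individual = 0.05,
                                      missing_rate_locus = 0,
                                      pop_names = NULL,
                                      seed = 1L) {
  if (length(sample_sizes) != n_pops)
    abort("sample_sizes length must equal n_pops")
  if (target_fst < 0 || target_fst >= 1)
    abort("target_fst must be in [0, 1)")
  if (missing_rate_individual < 0 || missing_rate_individual >= 0.25)
    abort("missing_rate_individual must be in [0, 0.25) (safety margin under the 30% filter)")
  mix <- multi_snp_mix / sum(multi_snp_mix)
  if (is.null(pop_names))
    pop_names <- sprintf("POP%02d", seq_len(n_pops))
  .with_seed(seed, {
    # 1-3 SNPs per locus
    if (exact_counts) {
      base <- floor(mix * n_loci)
      rem <- n_loci - sum(base)
      if (rem > 0)
        base[order(mix * n_loci - base, decreasing = TRUE)[seq_len(rem)]] <-
          base[order(mix * n_loci - base, decreasing = TRUE)[seq_len(rem)]] + 1
      k_snps <- rep(1:3, times = base)
    } else {
      k_snps <- sample(1:3, n_loci, replace = TRUE, prob = mix)
    }
    snps <- tibble(
      locus = rep(sprintf("L%04d", seq_len(n_loci)), times = k_snps),
      pos = unlist(lapply(k_snps, function(k) sort(sample.int(32, k)))))
    n_snp <- nrow(snps)
    total_n <- sum(sample_sizes)
    p_anc <- sample_allele_frequencies(n_snp, maf_dist, total_n)
    # Balding-Nichols population frequencies
    pfreq <- matrix(0, n_pops, n_snp)
    if (target_fst == 0) {
      pfreq[] <- rep(p_anc, each = n_pops)
    } else {
      shape <- (1 - target_fst) / target_fst
      pfreq[] <- rbeta(n_pops * n_snp,
                       rep(p_anc, each = n_pops) * shape,
                       rep(1 - p_anc, each = n_pops) * shape)
    }
    # Hardy-Weinberg genotypes
    geno <- matrix(NA_integer_, total_n, n_snp)
    ind_pop <- rep(pop_names, times = sample_sizes)
    for (k in seq_len(n_pops)) {
      rows <- which(ind_pop == pop_names[k])
      geno[rows, ] <- rbinom(length(rows) * n_snp, 2,
                             rep(pfreq[k, ], each = length(rows)))
    }
    # per-individual missingness applied at the locus level (a RAD tag
    # dropping out takes all its SNPs with it), uniform across loci
    locus_of_snp <- match(snps$locus, unique(snps$locus))
    if (missing_rate_individual > 0) {
      drop_loc <- matrix(runif(total_n * n_loci) < missing_rate_individual,
                         total_n, n_loci)
      geno[drop_loc[, locus_of_snp]] <- NA_integer_
    }
    if (missing_rate_locus > 0) {
      # per-locus knob for exercising the 80%-presence filter: afflicted
      # loci lose a random half of all individuals
      for (l in which(runif(n_loci) < missing_rate_locus))
        geno[sample.int(total_n, ceiling(total_n * 0.5)),
             locus_of_snp == l] <- NA_integer_
    }
    ind <- tibble(id = sprintf("%s_%03d", ind_pop,
                               unlist(lapply(sample_sizes, seq_len))),
                  pop = ind_pop)
    genotype_dataset(geno, ind, snps)
  })
}
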