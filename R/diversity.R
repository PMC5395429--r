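#' Observed heterozygosity
#'
#' Per-locus fraction of heterozygotes among typed individuals, per
#' population, with per-population means.
#'
#' @param dataset A [genotype_dataset()].
#' @param population Optional subset of population labels.
#' @return A tibble (`pop`, `snp`, `n`, `ho`); the per-population means are
#'   attached by [diversity_summary()].
#' @export
observed_heterozygosity <- function(dataset, population = NULL) {
  .per_pop_stat(dataset, population, function(n, p, h) h, "ho")
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample-corrected gene diversity per locus and population:
#' `2n/(2n-1) * (1 - p^2 - q^2)` over typed genotypes (needs n >= 2).
#'
#' @inheritParams observed_heterozygosity
#' @return A tibble (`pop`, `snp`, `n`, `he`).
#' @export
unbiased_expected_heterozygosity <- function(dataset, population = NULL) {
  .per_pop_stat(dataset, population, function(n, p, h) {
    he <- 2 * n / (2 * n - 1) * (1 - p^2 - (1 - p)^2)
    he[n < 2] <- NA_real_
    he
  }, "he")
}

.per_pop_stat <- function(dataset, population, f, name) {
  st <- .pop_stats(dataset$geno, dataset$ind$pop)
  pops <- if (is.null(population)) st$pops else intersect(st$pops, population)
  out <- lapply(pops, function(pp) {
    k <- match(pp, st$pops)
    tibble(pop = pp, snp = colnames(dataset$geno),
           n = as.integer(st$n[k, ]),
           value = unname(f(st$n[k, ], st$p[k, ], st$h[k, ])))
  })
  out <- dplyr::bind_rows(out)
  names(out)[names(out) == "value"] <- name
  out
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a random draw of `2 *
#' rarefaction_n` gene copies (the study standardises to its smallest
#' sample, N = 16): `sum_alleles [1 - choose(N_genes - N_allele, g) /
#' choose(N_genes, g)]`. Loci with fewer typed gene copies than `g` in a
#' population are skipped with a warning. A monomorphic locus has richness
#' 1; `g = N_genes` returns the observed allele count.
#'
#' @inheritParams observed_heterozygosity
#' @param rarefaction_n Standardised sample size in individuals.
#' @return A tibble (`pop`, `snp`, `n`, `ar`).
#' @export
allelic_richness <- function(dataset, population = NULL,
                             rarefaction_n = 16) {
  st <- .pop_stats(dataset$geno, dataset$ind$pop)
  smallest <- min(table(dataset$ind$pop))
  if (rarefaction_n > smallest)
    abort(sprintf(
      "rarefaction_n (%d) exceeds the smallest sample size (%d)",
      rarefaction_n, smallest))
  g2 <- 2 * rarefaction_n
  pops <- if (is.null(population)) st$pops else intersect(st$pops, population)
  out <- lapply(pops, function(pp) {
    k <- match(pp, st$pops)
    n <- st$n[k, ]; p <- st$p[k, ]
    ngenes <- 2 * n
    cnt_minor <- round(p * ngenes)
    cnt_major <- ngenes - cnt_minor
    ar <- rep(NA_real_, length(n))
    okk <- ngenes >= g2
    if (any(!okk))
      warn(sprintf("%s: %d locus/loci with < %d typed gene copies skipped",
                   pp, sum(!okk), g2))
    piece <- function(cnt, N) 1 - exp(lchoose(N - cnt, g2) - lchoose(N, g2))
    ar[okk] <- ifelse(cnt_minor[okk] > 0,
                      piece(cnt_minor[okk], ngenes[okk]), 0) +
      ifelse(cnt_major[okk] > 0, piece(cnt_major[okk], ngenes[okk]), 0)
    tibble(pop = pp, snp = colnames(dataset$geno),
           n = as.integer(n), ar = ar)
  })
  dplyr::bind_rows(out)
}

#' Per-population diversity summary
#'
#' Mean observed heterozygosity, unbiased expected heterozygosity and
#' rarefied allelic richness per population - the standard diversity table.
#'
#' @inheritParams allelic_richness
#' @return A tibble with one row per population (`pop`, `n_mean`, `ho`,
#'   `he`, `ar`).
#' @export
diversity_summary <- function(dataset, rarefaction_n = 16) {
  ho <- observed_heterozygosity(dataset)
  he <- unbiased_expected_heterozygosity(dataset)
  ar <- suppressWarnings(allelic_richness(dataset, rarefaction_n = rarefaction_n))
  j <- dplyr::left_join(ho, dplyr::select(he, "pop", "snp", "he"),
                        by = c("pop", "snp"))
  j <- dplyr::left_join(j, dplyr::select(ar, "pop", "snp", "ar"),
                        by = c("pop", "snp"))
  dplyr::summarise(dplyr::group_by(j, .data$pop),
                   n_mean = mean(.data$n),
                   ho = mean(.data$ho, na.rm = TRUE),
                   he = mean(.data$he, na.rm = TRUE),
                   ar = mean(.data$ar, na.rm = TRUE), .groups = "drop")
}

#' One-way ANOVA across samples on per-locus diversity values
#'
#' Utility mirroring the usual "no significant differences among samples"
#' check: per-locus values are treated as replicates within populations.
#'
#' @param diversity_long A tibble as from [observed_heterozygosity()] (or
#'   kin), with a `pop` column and one value column.
#' @param value Name of the value column.
#' @return Tidied one-way ANOVA table (one row for the `pop` term).
#' @export
diversity_anova <- function(diversity_long, value = "ho") {
  d <- diversity_long[!is.na(diversity_long[[value]]), ]
  fit <- aov(d[[value]] ~ factor(d$pop))
  s <- summary(fit)[[1]]
  tibble(term = "pop", df = s$Df[1], statistic = s$`F value`[1],
         p.value = s$`Pr(>F)`[1])
}
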