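#' Keep the most heterozygous SNP of each locus
#'
#' RAD loci carrying 2-3 SNPs are reduced to a single SNP: the one with the
#' highest whole-dataset expected heterozygosity (a proxy for polymorphic
#' content). Ties go to the lowest SNP position within the tag.
#'
#' @param dataset A [genotype_dataset()].
#' @return The dataset with exactly one SNP per locus.
#' @export
select_top_snp_per_locus <- function(dataset) {
  g <- dataset$geno
  n <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n, 1))
  he <- 2 * p * (1 - p) # whole-dataset expected heterozygosity
  he[n == 0] <- -Inf
  pick <- tibble(j = seq_len(ncol(g)), locus = dataset$snps$locus,
                 pos = dataset$snps$pos, he = he)
  keep <- dplyr::slice_min(dplyr::group_by(pick, .data$locus),
                           order_by = tibble(-he, pos),
                           n = 1, with_ties = FALSE)
  keep <- dplyr::arrange(dplyr::ungroup(keep), .data$j)
  genotype_dataset(g[, keep$j, drop = FALSE], dataset$ind,
                   dataset$snps[keep$j, ])
}

#' Filter loci by presence across individuals
#'
#' Retains polymorphic loci genotyped in at least `min_presence` (80% by
#' default, boundary inclusive) of the individuals; monomorphic loci are
#' dropped too.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_presence Minimum fraction of individuals typed.
#' @return The filtered dataset.
#' @export
filter_by_locus_presence <- function(dataset, min_presence = 0.8) {
  g <- dataset$geno
  n_ind <- nrow(g)
  typed <- colSums(!is.na(g))
  present <- typed / n_ind >= min_presence - 1e-12
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(typed, 1))
  poly <- typed > 0 & p > 0 & p < 1
  keep <- which(present & poly)
  genotype_dataset(g[, keep, drop = FALSE], dataset$ind,
                   dataset$snps[keep, ])
}

#' Filter individuals by missingness
#'
#' Drops individuals missing more than `max_missing` (30%) of the retained
#' loci; exactly 30% is kept ("more than 30%" excluded).
#'
#' @param dataset A [genotype_dataset()].
#' @param max_missing Maximum tolerated missing fraction per individual.
#' @return The filtered dataset.
#' @export
filter_by_individual_missingness <- function(dataset, max_missing = 0.3) {
  g <- dataset$geno
  miss <- rowMeans(is.na(g))
  keep <- which(miss <= max_missing + 1e-12)
  genotype_dataset(g[keep, , drop = FALSE], dataset$ind[keep, ],
                   dataset$snps)
}

#' Apply the full filtering sequence
#'
#' SNP-per-locus selection, then the 80% locus-presence filter, then the
#' 30% individual-missingness filter. The locus-presence filter is not
#' re-applied after individuals are dropped (individuals are excluded a
#' posteriori). Per-stage in/out counts are attached as attribute
#' `"filter_log"`.
#'
#' @param dataset A raw [genotype_dataset()].
#' @param min_presence,max_missing Filter thresholds.
#' @return The filtered dataset.
#' @export
apply_filters <- function(dataset, min_presence = 0.8, max_missing = 0.3) {
  log <- list()
  s1 <- select_top_snp_per_locus(dataset)
  log$snp_selection <- c(snps_in = ncol(dataset$geno), snps_out = ncol(s1$geno))
  s2 <- filter_by_locus_presence(s1, min_presence)
  log$locus_presence <- c(loci_in = ncol(s1$geno), loci_out = ncol(s2$geno))
  s3 <- filter_by_individual_missingness(s2, max_missing)
  log$individual_missingness <-
    c(ind_in = nrow(s2$geno), ind_out = nrow(s3$geno))
  attr(s3, "filter_log") <- log
  s3
}
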