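#' Genotype dataset
#'
#' Individuals x SNPs matrix of minor-allele copy counts (0/1/2, `NA` =
#' missing) with individual metadata (`id`, `pop`) and SNP metadata
#' (`locus`, `pos`): RAD loci are short tags that may carry 1-3 SNPs each.
#'
#' @param geno Integer matrix, individuals in rows, SNPs in columns.
#' @param ind Tibble with columns `id`, `pop` (one row per matrix row).
#' @param snps Tibble with columns `locus`, `pos` (one row per matrix
#'   column); defaults to one single-SNP locus per column.
#' @return A `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, ind, snps = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (any(geno < 0 | geno > 2, na.rm = TRUE))
    abort("genotypes must be coded 0/1/2 minor-allele copies or NA")
  ind <- as_tibble(ind)
  stopifnot(all(c("id", "pop") %in% names(ind)), nrow(ind) == nrow(geno))
  if (anyNA(ind$pop)) abort("every individual needs a population label")
  if (is.null(snps))
    snps <- tibble(locus = sprintf("L%04d", seq_len(ncol(geno))), pos = 1L)
  snps <- as_tibble(snps)
  stopifnot(all(c("locus", "pos") %in% names(snps)),
            nrow(snps) == ncol(geno))
  if (ncol(geno) > 0) colnames(geno) <- paste0(snps$locus, "_p", snps$pos)
  if (nrow(geno) > 0) rownames(geno) <- ind$id
  structure(list(geno = geno, ind = ind, snps = snps),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d individuals in %d population(s); %d SNP(s) on %d locus/loci; %.1f%% missing\n",
    nrow(x$geno), length(unique(x$ind$pop)), ncol(x$geno),
    length(unique(x$snps$locus)), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.genotype_dataset <- function(x, ...) {
  long <- as_tibble(as.data.frame(x$geno))
  long$id <- x$ind$id
  long$pop <- x$ind$pop
  tidyr::pivot_longer(long, cols = -c("id", "pop"),
                      names_to = "snp", values_to = "genotype")
}

#' @exportS3Method generics::glance
glance.genotype_dataset <- function(x, ...) {
  tibble(n_individuals = nrow(x$geno),
         n_populations = length(unique(x$ind$pop)),
         n_snps = ncol(x$geno),
         n_loci = length(unique(x$snps$locus)),
         missing_fraction = mean(is.na(x$geno)))
}

# per-population per-SNP sufficient statistics on typed genotypes:
# number typed (n), minor-allele frequency (p), heterozygote frequency (h)
.pop_stats <- function(geno, pop) {
  pops <- sort(unique(pop))
  typed <- !is.na(geno)
  n <- rowsum(typed + 0, pop)[pops, , drop = FALSE]
  g0 <- geno; g0[!typed] <- 0L
  cnt <- rowsum(g0, pop)[pops, , drop = FALSE]
  het <- rowsum((geno == 1L & typed) + 0, pop)[pops, , drop = FALSE]
  list(pops = pops, n = n, p = ifelse(n > 0, cnt / (2 * n), NA),
       h = ifelse(n > 0, het / n, NA))
}
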