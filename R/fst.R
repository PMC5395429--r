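# ---- nested analysis-of-variance machinery on allele indicators ----------
#
# Genetic variance components are estimated by a method-of-moments nested
# ANOVA on minor-allele indicators of gene copies, with nesting
# group / population / individual / gene copy. For the three-level case
# (no groups) this is algebraically the Weir & Cockerham (1984) theta
# estimator; the four-level case yields the hierarchical F-statistics
# F_CT, F_SC, F_ST. Missing genotypes are handled by locus-wise deletion,
# so all size coefficients are locus-specific.
#
# For one locus let T_x, n_x be the minor-allele total and gene-copy count
# of cell x at some level, and U_level = sum_x T_x^2 / n_x. For a strictly
# nested design E[U_k] is linear in the variance components with
# coefficients C(k, l) = sum_{f in k} (sum_{d in l, d within f} n_d^2)/n_f
# for l at or below k, and N above (those cancel in differences).
# Successive differences of the U's are the nested sums of squares; the
# triangular system is solved innermost-first.

# Per-locus variance components from per-population genotype counts.
# n: typed individuals per pop; cnt: minor-allele copies; het: number of
# heterozygotes; grp: group index per pop. Returns
# c(a = among groups [NA if single group], b = among pops within groups,
#   c = among individuals within pops, d = within individuals).
.locus_components <- function(n, cnt, het, grp) {
  keep <- n > 0
  n <- n[keep]; cnt <- cnt[keep]; het <- het[keep]; grp <- grp[keep]
  r <- length(n)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_))
  I <- sum(n); N <- 2 * I
  Ttot <- sum(cnt)
  hom_minor <- (cnt - het) / 2
  hierarchical <- length(unique(grp)) > 1

  U_tot <- Ttot^2 / N
  U_pop <- sum(cnt^2 / (2 * n))
  U_ind <- sum(2 * hom_minor + het / 2) # sum over inds of T_ind^2 / 2
  U_copy <- Ttot                        # indicators are 0/1

  n_grp <- as.numeric(tapply(2 * n, grp, sum)) # gene copies per group
  T_grp <- as.numeric(tapply(cnt, grp, sum))
  I_grp <- as.numeric(tapply(n, grp, sum))
  p2_grp <- as.numeric(tapply((2 * n)^2, grp, sum))
  G <- length(n_grp)
  U_grp <- sum(T_grp^2 / n_grp)

  # C(k, l): rows tot/grp/pop/ind/copy, cols a(grp)/b(pop)/c(ind)/d(copy)
  Cmat <- rbind(
    tot  = c(sum(n_grp^2) / N, sum((2 * n)^2) / N, 4 * I / N, 1),
    grp  = c(N, sum(p2_grp / n_grp), sum(4 * I_grp / n_grp), G),
    pop  = c(N, N, 2 * r, r),
    ind  = c(N, N, N, I),
    copy = c(N, N, N, N))
  U <- c(tot = U_tot, grp = U_grp, pop = U_pop, ind = U_ind, copy = U_copy)

  lv <- c("tot", "grp", "pop", "ind", "copy")
  SS <- U[lv[-1]] - U[lv[-5]]
  A <- Cmat[lv[-1], , drop = FALSE] - Cmat[lv[-5], , drop = FALSE]

  d <- SS[["copy"]] / A["copy", 4]
  cc <- (SS[["ind"]] - A["ind", 4] * d) / A["ind", 3]
  b <- (SS[["pop"]] - A["pop", 4] * d - A["pop", 3] * cc) / A["pop", 2]
  a <- if (hierarchical)
    (SS[["grp"]] - A["grp", 4] * d - A["grp", 3] * cc - A["grp", 2] * b) /
    A["grp", 1]
  else NA_real_
  c(a = a, b = b, c = cc, d = d)
}

# components for all loci given a genotype matrix and labels; returns a
# loci x 4 matrix of components (a, b, c, d)
.all_components <- function(geno, pop, grp_of_pop = NULL) {
  pops <- sort(unique(pop))
  grp <- if (is.null(grp_of_pop)) rep(1L, length(pops))
  else grp_of_pop[pops]
  typed <- !is.na(geno)
  n <- rowsum(typed + 0, pop)[pops, , drop = FALSE]
  g0 <- geno; g0[!typed] <- 0L
  cnt <- rowsum(g0, pop)[pops, , drop = FALSE]
  het <- rowsum((geno == 1L & typed) + 0, pop)[pops, , drop = FALSE]
  t(vapply(seq_len(ncol(geno)), function(j)
    .locus_components(n[, j], cnt[, j], het[, j], grp),
    c(a = 0, b = 0, c = 0, d = 0)))
}

.theta_from_components <- function(comp) {
  ok <- !is.na(comp[, "b"])
  b <- sum(comp[ok, "b"]); cc <- sum(comp[ok, "c"]); d <- sum(comp[ok, "d"])
  a <- if (all(is.na(comp[, "a"]))) 0 else sum(comp[ok, "a"], na.rm = TRUE)
  (a + b) / (a + b + cc + d)
}

#' Weir-Cockerham F(ST) (theta) with permutation and bootstrap inference
#'
#' Locus-by-locus variance components on typed genotypes (unequal,
#' locus-specific sample sizes), combined across loci as a ratio of summed
#' components: `theta = sum(a) / sum(a + b + c)`. The permutation p-value
#' shuffles individuals among populations; the bootstrap CI resamples loci
#' with replacement (percentile interval). Negative estimates are reported
#' as-is, not clamped to zero.
#'
#' @param dataset A [genotype_dataset()].
#' @param populations Optional subset of population labels (default: all).
#' @param n_perm Number of permutations (default 10,023; 0 skips the test).
#' @param n_boot Number of locus bootstrap resamples (default 1,000; 0
#'   skips the CI).
#' @param conf_level Bootstrap CI level.
#' @param seed Integer seed for permutation/bootstrap draws.
#' @return An `fst_result` with multilocus `theta`, `per_locus` tibble,
#'   permutation `p`, bootstrap `ci`, and bookkeeping fields.
#' @export
wc_theta <- function(dataset, populations = NULL, n_perm = 10023,
                     n_boot = 1000, conf_level = 0.95, seed = 1L) {
  geno <- dataset$geno
  pop <- dataset$ind$pop
  if (!is.null(populations)) {
    keep <- pop %in% populations
    geno <- geno[keep, , drop = FALSE]
    pop <- pop[keep]
  }
  if (length(unique(pop)) < 2) abort("need at least 2 populations")
  typed_per_pop <- rowsum((!is.na(geno)) + 0, pop)
  if (any(apply(typed_per_pop, 1, max) < 2))
    abort("every population needs >= 2 typed individuals at some locus")
  comp <- .all_components(geno, pop)
  theta_obs <- .theta_from_components(comp)
  per_locus <- tibble(
    snp = colnames(geno),
    a = comp[, "b"], bc = comp[, "c"] + comp[, "d"],
    theta = comp[, "b"] / (comp[, "b"] + comp[, "c"] + comp[, "d"]))

  p_perm <- NA_real_
  perm_thetas <- NULL
  ci <- c(NA_real_, NA_real_)
  .with_seed(seed, {
    if (n_perm > 0) {
      perm_thetas <- vapply(seq_len(n_perm), function(i) {
        .theta_from_components(.all_components(geno, sample(pop)))
      }, numeric(1))
      p_perm <- (sum(perm_thetas >= theta_obs - 1e-15) + 1) / (n_perm + 1)
    }
    if (n_boot > 0 && ncol(geno) > 1) {
      ok <- !is.na(comp[, "b"])
      a_l <- comp[ok, "b"]
      tot_l <- comp[ok, "b"] + comp[ok, "c"] + comp[ok, "d"]
      bt <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(a_l), replace = TRUE)
        sum(a_l[idx]) / sum(tot_l[idx])
      }, numeric(1))
      al <- (1 - conf_level) / 2
      ci <- unname(quantile(bt, c(al, 1 - al), na.rm = TRUE))
    }
  })
  structure(list(theta = theta_obs, per_locus = per_locus, p = p_perm,
                 ci = ci, conf_level = conf_level,
                 n_perm = n_perm, n_boot = n_boot,
                 populations = sort(unique(pop)),
                 n_loci = ncol(geno)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta over %d loci, %d populations\n",
              x$n_loci, length(x$populations)))
  cat(sprintf("  theta = %.5f", x$theta))
  if (!is.na(x$p)) cat(sprintf(", permutation p = %.4f (%d perms)",
                               x$p, x$n_perm))
  if (!anyNA(x$ci)) cat(sprintf(", %g%% CI [%.5f, %.5f]",
                                100 * x$conf_level, x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fst_result <- function(x, ...) x$per_locus

#' @exportS3Method generics::glance
glance.fst_result <- function(x, ...) {
  tibble(theta = x$theta, p.value = x$p,
         ci_low = x$ci[1], ci_high = x$ci[2],
         n_loci = x$n_loci, n_populations = length(x$populations),
         n_perm = x$n_perm, n_boot = x$n_boot)
}

#' Pairwise Weir-Cockerham theta between all populations
#'
#' @inheritParams wc_theta
#' @param adjust_p Apply Benjamini-Hochberg correction to the permutation
#'   p-values (default TRUE).
#' @return A tibble (`pop1`, `pop2`, `theta`, `p.value`, `p.adjusted`).
#' @export
pairwise_fst <- function(dataset, n_perm = 1023, adjust_p = TRUE, seed = 1L) {
  pops <- sort(unique(dataset$ind$pop))
  prs <- combn(pops, 2)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    f <- wc_theta(dataset, populations = prs[, k], n_perm = n_perm,
                  n_boot = 0, seed = seed + k)
    tibble(pop1 = prs[1, k], pop2 = prs[2, k],
           theta = f$theta, p.value = f$p)
  })
  out <- dplyr::bind_rows(res)
  if (adjust_p) out$p.adjusted <- bh_adjust(out$p.value)
  out
}
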