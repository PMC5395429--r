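#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Locus-by-locus AMOVA on genotype data: per-locus variance components
#' (among groups, among populations within groups, among individuals
#' within populations, within individuals) are summed across loci before
#' forming the F-statistics, with missing genotypes handled by locus-wise
#' deletion. Permutation schemes follow convention: individuals among
#' populations for F(ST); whole populations among groups for F(CT);
#' individuals among populations within groups for F(SC). With a single
#' group the analysis is non-hierarchical and F(CT)/F(SC) are `NA`.
#'
#' Percent-of-variation figures merge the two intra-population levels
#' (among and within individuals) into "within populations", and always
#' sum to 100.
#'
#' @param dataset A [genotype_dataset()].
#' @param partition Named list/vector assigning each population to a group
#'   (e.g. `c(A = 1, B = 1, C = 2)`), or `NULL` for the non-hierarchical
#'   analysis.
#' @param n_perm Permutations per F-statistic (default 1,023; 0 skips).
#' @param seed Integer seed.
#' @return An `amova_result` with `components` (summed variance
#'   components), `fstats` (`f_st`, `f_ct`, `f_sc` and permutation
#'   p-values), and `percent` (percent variation per level).
#' @export
amova <- function(dataset, partition = NULL, n_perm = 1023, seed = 1L) {
  geno <- dataset$geno
  pop <- dataset$ind$pop
  pops <- sort(unique(pop))
  if (is.null(partition)) partition <- setNames(rep(1L, length(pops)), pops)
  grp <- .check_partition(partition, pops)
  hierarchical <- length(unique(grp)) > 1
  if (hierarchical) {
    sizes <- table(grp)
    if (all(sizes == 1))
      warn("every group has a single population: F_SC is undefined")
  }
  comp <- .all_components(geno, pop, grp)
  sums <- .sum_components(comp)
  fst_obs <- .fstats_from_sums(sums)

  ps <- c(f_st = NA_real_, f_ct = NA_real_, f_sc = NA_real_)
  if (n_perm > 0) {
    .with_seed(seed, {
      # F_ST: individuals among populations (regrouping follows pops)
      perm <- vapply(seq_len(n_perm), function(i) {
        cmp <- .all_components(geno, sample(pop), grp)
        .fstats_from_sums(.sum_components(cmp))[["f_st"]]
      }, numeric(1))
      ps["f_st"] <- (sum(perm >= fst_obs[["f_st"]] - 1e-15) + 1) / (n_perm + 1)
      if (hierarchical) {
        # F_CT: whole populations among groups
        perm_ct <- vapply(seq_len(n_perm), function(i) {
          g2 <- setNames(sample(grp), names(grp))
          cmp <- .all_components(geno, pop, g2)
          .fstats_from_sums(.sum_components(cmp))[["f_ct"]]
        }, numeric(1))
        ps["f_ct"] <- (sum(perm_ct >= fst_obs[["f_ct"]] - 1e-15) + 1) /
          (n_perm + 1)
        # F_SC: individuals among populations within their group
        grp_of_ind <- grp[pop]
        perm_sc <- vapply(seq_len(n_perm), function(i) {
          pop2 <- pop
          for (g in unique(grp)) {
            sel <- grp_of_ind == g
            pop2[sel] <- sample(pop[sel])
          }
          cmp <- .all_components(geno, pop2, grp)
          .fstats_from_sums(.sum_components(cmp))[["f_sc"]]
        }, numeric(1))
        ps["f_sc"] <- (sum(perm_sc >= fst_obs[["f_sc"]] - 1e-15) + 1) /
          (n_perm + 1)
      }
    })
  }

  total <- sum(sums, na.rm = TRUE)
  pct <- c(
    among_groups = if (hierarchical) 100 * sums[["a"]] / total else NA,
    among_pops = 100 * sums[["b"]] / total,
    within_pops = 100 * (sums[["c"]] + sums[["d"]]) / total)
  structure(list(components = sums, fstats = fst_obs, p = ps,
                 percent = pct, partition = grp, n_perm = n_perm,
                 hierarchical = hierarchical),
            class = "amova_result")
}

.check_partition <- function(partition, pops) {
  grp <- unlist(partition)
  if (is.null(names(grp)) || !setequal(names(grp), pops))
    abort("partition must name every population exactly once")
  grp <- grp[pops]
  setNames(as.integer(factor(grp)), pops)
}

.sum_components <- function(comp) {
  ok <- !is.na(comp[, "b"])
  c(a = if (all(is.na(comp[, "a"]))) NA_real_
    else sum(comp[ok, "a"], na.rm = TRUE),
    b = sum(comp[ok, "b"]), c = sum(comp[ok, "c"]), d = sum(comp[ok, "d"]))
}

.fstats_from_sums <- function(s) {
  a <- if (is.na(s[["a"]])) 0 else s[["a"]]
  total <- a + s[["b"]] + s[["c"]] + s[["d"]]
  c(f_st = (a + s[["b"]]) / total,
    f_ct = if (is.na(s[["a"]])) NA_real_ else a / total,
    f_sc = if (is.na(s[["a"]])) NA_real_
    else s[["b"]] / (s[["b"]] + s[["c"]] + s[["d"]]))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Locus-by-locus AMOVA\n")
  lv <- c("among groups", "among populations within groups",
          "among individuals within populations", "within individuals")
  comp <- x$components
  for (i in seq_along(comp))
    if (!is.na(comp[i]))
      cat(sprintf("  %-38s %10.5f\n", lv[i], comp[i]))
  f <- x$fstats
  cat(sprintf("  F_ST = %.5f (p = %s)\n", f[["f_st"]], format(x$p[["f_st"]])))
  if (x$hierarchical) {
    cat(sprintf("  F_CT = %.5f (p = %s)\n", f[["f_ct"]],
                format(x$p[["f_ct"]])))
    cat(sprintf("  F_SC = %.5f (p = %s)\n", f[["f_sc"]],
                format(x$p[["f_sc"]])))
  }
  pct <- x$percent[!is.na(x$percent)]
  cat("  percent variation:",
      paste(sprintf("%s %.2f%%", names(pct), pct), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.amova_result <- function(x, ...) {
  tibble(level = c("among_groups", "among_pops_within_groups",
                   "among_individuals", "within_individuals"),
         variance = unname(x$components),
         percent = unname(c(x$percent[1], x$percent[2], NA, NA)))
}

#' @exportS3Method generics::glance
glance.amova_result <- function(x, ...) {
  tibble(f_st = x$fstats[["f_st"]], f_ct = x$fstats[["f_ct"]],
         f_sc = x$fstats[["f_sc"]],
         p_f_st = x$p[["f_st"]], p_f_ct = x$p[["f_ct"]],
         p_f_sc = x$p[["f_sc"]], n_perm = x$n_perm)
}

# ---- exhaustive partition search -----------------------------------------

# all set partitions of `items` into exactly k non-empty groups, as a list
# of integer group-assignment vectors (restricted growth strings)
.partitions_k <- function(n_items, k) {
  out <- list()
  assign <- integer(n_items)
  recurse <- function(i, used) {
    if (i > n_items) {
      if (used == k) out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    remaining <- n_items - i + 1
    for (g in seq_len(min(used + 1, k))) {
      if (used + remaining < k && g <= used) next # cannot reach k groups
      assign[i] <<- g
      recurse(i + 1, max(used, g))
    }
  }
  recurse(1L, 0L)
  out
}

#' Exhaustive partition scan maximising F(CT)
#'
#' Enumerates every partition of the populations into exactly `k` nonempty
#' groups (k = 2 and 3 by default; Stirling numbers of the second kind:
#' 511 bipartitions and 9,330 tripartitions for 10 populations) and ranks
#' them by the hierarchical F(CT). Group-level aggregation is recomputed
#' from per-population sufficient statistics, so the scan does not touch
#' the genotype matrix per candidate.
#'
#' @param dataset A [genotype_dataset()].
#' @param k_values Group counts to scan (subset of 2:3 typically).
#' @return A tibble (`k`, `partition` label, `f_ct`) sorted by decreasing
#'   `f_ct`, with the best partition's assignment in attribute
#'   `"best_partition"`.
#' @export
scan_partitions <- function(dataset, k_values = c(2, 3)) {
  pops <- sort(unique(dataset$ind$pop))
  P <- length(pops)
  if (P > 12) abort("refusing exhaustive scan for > 12 populations")
  geno <- dataset$geno
  pop <- dataset$ind$pop

  # per-pop per-locus sufficient statistics (computed once)
  typed <- !is.na(geno)
  n <- rowsum(typed + 0, pop)[pops, , drop = FALSE]
  g0 <- geno; g0[!typed] <- 0L
  cnt <- rowsum(g0, pop)[pops, , drop = FALSE]
  het <- rowsum((geno == 1L & typed) + 0, pop)[pops, , drop = FALSE]

  rows <- list()
  for (k in k_values) {
    parts <- .partitions_k(P, k)
    fcts <- vapply(parts, function(grp) {
      comp <- t(vapply(seq_len(ncol(geno)), function(j)
        .locus_components(n[, j], cnt[, j], het[, j], grp),
        c(a = 0, b = 0, c = 0, d = 0)))
      .fstats_from_sums(.sum_components(comp))[["f_ct"]]
    }, numeric(1))
    labels <- vapply(parts, function(grp)
      paste(vapply(seq_len(k), function(g)
        paste(pops[grp == g], collapse = "+"), character(1)),
        collapse = " | "), character(1))
    rows[[length(rows) + 1]] <- tibble(k = k, partition = labels,
                                       f_ct = fcts)
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$f_ct))
  best_k <- out$k[1]
  best_label <- out$partition[1]
  idx <- which(vapply(.partitions_k(P, best_k), function(grp)
    paste(vapply(seq_len(best_k), function(g)
      paste(pops[grp == g], collapse = "+"), character(1)),
      collapse = " | "), character(1)) == best_label)[1]
  attr(out, "best_partition") <-
    setNames(.partitions_k(P, best_k)[[idx]], pops)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (wraps
#' `p.adjust(method = "BH")`): monotone, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
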