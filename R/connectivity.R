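#' Connectivity effectiveness matrix
#'
#' Effectiveness from origin to destination is the mean over simulated
#' years of the annual ratio between the survival-weighted number of
#' successful larvae and the number released from the origin. The diagonal
#' is retention (self-connectivity). `normalization = "actual"` divides by
#' larvae actually released (spawning days only; the default, which matches
#' the retention values quoted with the success-rate decomposition);
#' `"potential"` divides by the full-season potential release.
#'
#' @param flux A [flux_table()].
#' @param normalization `"actual"` or `"potential"`.
#' @param months Optional subset of release months to include.
#' @return A `connectivity_matrix`: origin x destination matrix of
#'   fractions with attributes `normalization` and `n_years`.
#' @export
effectiveness <- function(flux, normalization = c("actual", "potential"),
                          months = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(flux, "flux_table"))
  rel_col <- paste0("released_", normalization)
  recs <- flux$records
  rels <- flux$releases
  if (!is.null(months)) {
    recs <- dplyr::filter(recs, .data$month %in% months)
    rels <- dplyr::filter(rels, .data$month %in% months)
  }
  ann_rel <- dplyr::summarise(dplyr::group_by(rels, .data$year, .data$origin),
                              released = sum(.data[[rel_col]]),
                              .groups = "drop")
  zero <- dplyr::filter(ann_rel, .data$released == 0)
  if (nrow(zero) > 0) {
    warn(sprintf("excluding %d origin-year(s) with zero release", nrow(zero)))
    ann_rel <- dplyr::filter(ann_rel, .data$released > 0)
  }
  ann_w <- dplyr::summarise(
    dplyr::group_by(recs, .data$year, .data$origin, .data$destination),
    weight = sum(.data$weight), .groups = "drop")
  sites <- flux$site_order
  mat <- matrix(0, length(sites), length(sites),
                dimnames = list(origin = sites, destination = sites))
  for (o in sites) {
    yrs <- dplyr::filter(ann_rel, .data$origin == o)
    if (nrow(yrs) == 0) { mat[o, ] <- NA_real_; next }
    for (d in sites) {
      w <- dplyr::left_join(
        yrs,
        dplyr::filter(ann_w, .data$origin == o, .data$destination == d),
        by = c("year", "origin"))
      ratio <- ifelse(is.na(w$weight), 0, w$weight) / w$released
      mat[o, d] <- mean(ratio)
    }
  }
  structure(mat, normalization = normalization,
            n_years = length(unique(ann_rel$year)),
            class = c("connectivity_matrix", "matrix"))
}

#' Connectivity persistence matrix (stabilization coefficient)
#'
#' Persistence of a connection is the reciprocal of the coefficient of
#' variation of its annual larval flux over the simulation period:
#' `mean(flux) / sd(flux)`, with the sample (n-1) standard deviation. A
#' pair whose flux is zero in every year is undefined (`NA`); a constant
#' nonzero flux has zero variance (`Inf`). A flux positive in exactly one
#' of ten years gives the characteristic minimum 1/sqrt(10) = 0.316.
#'
#' @param flux A [flux_table()].
#' @return A `connectivity_matrix` of stabilization coefficients.
#' @export
persistence <- function(flux) {
  stopifnot(inherits(flux, "flux_table"))
  years <- sort(unique(flux$releases$year))
  if (length(years) < 2)
    abort("persistence needs at least 2 simulated years (sd undefined)")
  ann_w <- dplyr::summarise(
    dplyr::group_by(flux$records, .data$year, .data$origin,
                    .data$destination),
    weight = sum(.data$weight), .groups = "drop")
  sites <- flux$site_order
  mat <- matrix(NA_real_, length(sites), length(sites),
                dimnames = list(origin = sites, destination = sites))
  for (o in sites) for (d in sites) {
    w <- dplyr::filter(ann_w, .data$origin == o, .data$destination == d)
    series <- rep(0, length(years))
    series[match(w$year, years)] <- w$weight
    if (all(series == 0)) next # undefined, stays NA
    s <- sd(series)
    mat[o, d] <- if (s == 0) Inf else mean(series) / s
  }
  structure(mat, normalization = "flux", n_years = length(years),
            class = c("connectivity_matrix", "matrix"))
}

#' Per-origin rate decomposition
#'
#' Splits each origin's dispersal outcome, averaged over years, into:
#' `release_rate` (actual / potential release - the fraction of the season
#' with spawning-permissive temperatures), `survival_rate` (mean survival
#' weight of released larvae), `arrival_rate` (weight-free fraction of
#' released larvae whose endpoint fell in any arrival buffer) and
#' `success_rate` (survival-weighted arrivals over the actual release).
#'
#' @param flux A [flux_table()] produced by [run_simulation()].
#' @return A tibble with one row per origin.
#' @export
rate_decomposition <- function(flux) {
  stopifnot(inherits(flux, "flux_table"))
  if (!all(c("sum_survival", "n_arrived") %in% names(flux$releases)))
    abort("flux table lacks survival/arrival accounting columns")
  ann <- dplyr::summarise(
    dplyr::group_by(flux$releases, .data$year, .data$origin),
    actual = sum(.data$released_actual),
    potential = sum(.data$released_potential),
    sum_survival = sum(.data$sum_survival),
    n_arrived = sum(.data$n_arrived), .groups = "drop")
  ann_w <- dplyr::summarise(
    dplyr::group_by(flux$records, .data$year, .data$origin),
    success_w = sum(.data$weight), .groups = "drop")
  ann <- dplyr::left_join(ann, ann_w, by = c("year", "origin"))
  ann$success_w[is.na(ann$success_w)] <- 0
  per_year <- dplyr::mutate(
    ann,
    release_rate = .data$actual / .data$potential,
    survival_rate = ifelse(.data$actual > 0,
                           .data$sum_survival / .data$actual, NA_real_),
    arrival_rate = ifelse(.data$actual > 0,
                          .data$n_arrived / .data$actual, NA_real_),
    success_rate = ifelse(.data$actual > 0,
                          .data$success_w / .data$actual, NA_real_))
  out <- dplyr::summarise(
    dplyr::group_by(per_year, .data$origin),
    release_rate = mean(.data$release_rate, na.rm = TRUE),
    survival_rate = mean(.data$survival_rate, na.rm = TRUE),
    arrival_rate = mean(.data$arrival_rate, na.rm = TRUE),
    success_rate = mean(.data$success_rate, na.rm = TRUE),
    .groups = "drop")
  out[match(flux$site_order, out$origin), , drop = FALSE]
}

#' Monthly effectiveness matrices
#'
#' One effectiveness matrix per release month (April-July by default),
#' averaged over years, tracing the seasonal reshaping of connectivity as
#' waters warm.
#'
#' @param flux A [flux_table()].
#' @param normalization As in [effectiveness()].
#' @return A named list of `connectivity_matrix` objects (names `"4"` ..
#'   `"7"`); months with no actual release yield a matrix of `NA` with
#'   attribute `empty = TRUE`.
#' @export
monthly_matrices <- function(flux, normalization = c("actual", "potential")) {
  normalization <- match.arg(normalization)
  months <- sort(unique(flux$releases$month))
  out <- lapply(months, function(mo) {
    rels <- dplyr::filter(flux$releases, .data$month == mo)
    if (sum(rels$released_actual) == 0 && normalization == "actual") {
      sites <- flux$site_order
      m <- matrix(NA_real_, length(sites), length(sites),
                  dimnames = list(origin = sites, destination = sites))
      return(structure(m, normalization = normalization, empty = TRUE,
                       class = c("connectivity_matrix", "matrix")))
    }
    suppressWarnings(effectiveness(flux, normalization, months = mo))
  })
  names(out) <- months
  out
}

#' @export
print.connectivity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<connectivity_matrix> normalization: %s\n",
              attr(x, "normalization")))
  m <- unclass(x)
  attr(m, "normalization") <- NULL; attr(m, "n_years") <- NULL
  attr(m, "empty") <- NULL
  print(round(100 * m, digits)) # percent, as conventionally reported
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.connectivity_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    origin = rep(rownames(m), times = ncol(m)),
    destination = rep(colnames(m), each = nrow(m)),
    value = as.vector(m))
}

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param percent Plot percentages (default) rather than fractions.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_matrix <- function(object, percent = TRUE, ...) {
  d <- tidy(object)
  if (percent) d$value <- 100 * d$value
  d$origin <- factor(d$origin, levels = rev(rownames(object)))
  d$destination <- factor(d$destination, levels = colnames(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$destination, .data$origin,
                                  fill = log10(.data$value + 1e-4))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$value) | .data$value == 0, "-",
                     sprintf("%.3f", .data$value))), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", guide = "none") +
    ggplot2::labs(x = "destination", y = "origin",
                  title = sprintf("Connectivity (%s normalization%s)",
                                  attr(object, "normalization"),
                                  if (percent) ", percent" else "")) +
    ggplot2::theme_minimal()
}

#' Write a connectivity matrix as CSV
#'
#' Values in percent with 3 decimals; undefined entries empty (mirroring
#' the dash convention of printed matrices).
#'
#' @param x A `connectivity_matrix`.
#' @param path Output CSV path.
#' @param percent Write percent (default) or fractions.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(x, path, percent = TRUE) {
  m <- unclass(x)
  if (percent) m <- 100 * m
  out <- format(round(m, 3), trim = TRUE)
  out[is.na(m)] <- ""
  out[is.infinite(m)] <- "Inf"
  df <- data.frame(origin = rownames(m), out, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
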