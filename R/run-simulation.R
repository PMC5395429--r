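# Vectorised advection of a batch of particles (possibly many birth days):
# a single global clock steps all in-transit, already-born particles
# together. Survival weight decays step-wise as exp(-mu * dt) whenever the
# sampled temperature at the particle's fixed depth exceeds the threshold;
# cumulative time above threshold is tracked in `hot_days`.
.advect_particles <- function(field, states, config) {
  n <- nrow(states)
  g <- field$grid
  dt0 <- config$dt_minutes / 60 / 24
  birth <- .date_to_time(field, states$birth_date)
  lon <- states$lon; lat <- states$lat; depth <- states$depth
  pld <- states$pld
  weight <- states$weight
  status <- states$status
  hot <- numeric(n)
  age <- numeric(n)
  mu <- config$mortality_rate
  bern <- identical(config$mortality_mode, "bernoulli")
  t_glob <- min(birth)
  while (any(status == "in_transit")) {
    ia <- which(status == "in_transit" & birth <= t_glob + 1e-9)
    if (length(ia)) {
      step_dt <- pmin(dt0, pld[ia] - age[ia])
      stp <- .rk4_positions(field, lon[ia], lat[ia], depth[ia],
                            birth[ia] + age[ia], step_dt)
      out <- stp$lon < g$lon_min | stp$lon > g$lon_max |
        stp$lat < g$lat_min | stp$lat > g$lat_max
      lost <- stp$lost | out
      beach <- !lost & !is_wet(field, stp$lon, stp$lat)
      move <- !lost & !beach
      lon[ia[move]] <- stp$lon[move]
      lat[ia[move]] <- stp$lat[move]
      status[ia[lost]] <- "lost_domain"
      age[ia] <- age[ia] + step_dt
      surv <- ia[!lost]
      if (length(surv)) {
        tv <- .sample_var(field, "temperature", lon[surv], lat[surv],
                          depth[surv], birth[surv] + age[surv],
                          dry_zero = FALSE)$value
        is_hot <- !is.na(tv) & tv > config$mortality_temp
        sdt <- step_dt[!lost]
        hot[surv] <- hot[surv] + ifelse(is_hot, sdt, 0)
        if (bern) {
          die <- surv[is_hot & runif(length(surv)) > exp(-mu * sdt)]
          weight[die] <- 0
          status[die] <- "dead"
        } else {
          weight[surv] <- weight[surv] * ifelse(is_hot, exp(-mu * sdt), 1)
        }
      }
      done <- ia[age[ia] >= pld[ia] - 1e-9 &
                   status[ia] == "in_transit"]
      status[done] <- "completed"
    }
    t_glob <- t_glob + dt0
  }
  states$lon <- lon; states$lat <- lat
  states$weight <- weight; states$status <- status
  states$hot_days <- hot
  states
}

# kept as the single-cohort entry point used by advect_particle()
.advect_cohort <- .advect_particles

#' Run the full dispersal simulation
#'
#' For every simulated year, site and spawning day: draws releases, advects
#' larvae at fixed depth with RK4 steps (6 minutes by default), applies
#' temperature-triggered mortality, and classifies arrivals into 5-km site
#' buffers. The result aggregates, per (year, release month, origin,
#' destination), the summed survival weight of successful larvae, together
#' with actual releases (spawning days only), potential releases (all
#' season days), arrival-independent survival weights and weight-free
#' arrival counts needed by the rate decomposition.
#'
#' @param field An [ocean_field()] spanning the simulated years.
#' @param sites Sites tibble (`acronym`, `lon`, `lat`).
#' @param config A [dispersal_config()]; `config$seed` makes the run
#'   deterministic.
#' @return A `flux_table` object.
#' @export
run_simulation <- function(field, sites, config = dispersal_config()) {
  if (nrow(sites) == 0) abort("empty site list")
  if (anyDuplicated(sites$acronym)) abort("site acronyms must be unique")
  records <- list()
  releases <- list()
  .with_seed(config$seed, {
    for (year in config$years) {
      season <- seq(as.Date(sprintf("%d-%s", year, config$spawn_start)),
                    as.Date(sprintf("%d-%s", year, config$spawn_end)),
                    by = "day")
      season_month <- as.integer(format(season, "%m"))
      cohorts <- list()
      spawn_count <- list() # per site: spawning days per month
      for (si in seq_len(nrow(sites))) {
        site <- sites[si, ]
        sdays <- spawning_days(field, site, year, config)
        spawn_count[[site$acronym]] <-
          table(factor(as.integer(format(sdays, "%m")),
                       levels = sort(unique(season_month))))
        for (day in as.list(sdays))
          cohorts[[length(cohorts) + 1]] <-
            draw_release_states(field, site, day, config)
      }
      if (length(cohorts)) {
        fin <- .advect_particles(field, dplyr::bind_rows(cohorts), config)
        fin$month <- as.integer(format(fin$birth_date, "%m"))
        comp <- fin$status == "completed"
        fin$destination <- NA_character_
        if (any(comp))
          fin$destination[comp] <-
            classify_arrival(fin$lon[comp], fin$lat[comp], sites, config)
        arr <- dplyr::filter(fin, !is.na(.data$destination))
        if (nrow(arr))
          records[[length(records) + 1]] <- dplyr::summarise(
            dplyr::group_by(arr, .data$month, .data$origin,
                            .data$destination),
            weight = sum(.data$weight), .groups = "drop") |>
            dplyr::mutate(year = year, .before = 1)
        acct <- dplyr::summarise(
          dplyr::group_by(fin, .data$month, .data$origin),
          sum_survival = sum(.data$weight),
          n_arrived = sum(!is.na(.data$destination)), .groups = "drop")
      } else {
        acct <- tibble(month = integer(), origin = character(),
                       sum_survival = numeric(), n_arrived = integer())
      }
      for (si in seq_len(nrow(sites))) {
        acr <- sites$acronym[si]
        sc <- spawn_count[[acr]]
        for (mo in sort(unique(season_month))) {
          a <- dplyr::filter(acct, .data$origin == acr, .data$month == mo)
          releases[[length(releases) + 1]] <- tibble(
            year = year, month = mo, origin = acr,
            released_actual = config$particles_per_day *
              as.integer(sc[as.character(mo)]),
            released_potential = config$particles_per_day *
              sum(season_month == mo),
            sum_survival = if (nrow(a)) a$sum_survival else 0,
            n_arrived = if (nrow(a)) a$n_arrived else 0L)
        }
      }
    }
  })
  flux_table(
    records = if (length(records)) dplyr::bind_rows(records) else
      tibble(year = integer(), month = integer(), origin = character(),
             destination = character(), weight = numeric()),
    releases = dplyr::bind_rows(releases),
    site_order = sites$acronym)
}

#' Construct a flux table
#'
#' The container tying the dispersal stage to the connectivity metrics:
#' per-(year, month, origin, destination) arrival weights plus per-(year,
#' month, origin) release accounting.
#'
#' @param records Tibble with `year`, `month`, `origin`, `destination`,
#'   `weight`.
#' @param releases Tibble with `year`, `month`, `origin`,
#'   `released_actual`, `released_potential`, and optionally
#'   `sum_survival`, `n_arrived`.
#' @param site_order Character vector fixing row/column order of
#'   connectivity matrices.
#' @return A `flux_table`.
#' @export
flux_table <- function(records, releases, site_order = NULL) {
  records <- as_tibble(records)
  releases <- as_tibble(releases)
  stopifnot(all(c("year", "month", "origin", "destination", "weight")
                %in% names(records)),
            all(c("year", "month", "origin", "released_actual",
                  "released_potential") %in% names(releases)))
  if (any(records$weight < 0)) abort("arrival weights must be >= 0")
  if (any(releases$released_actual > releases$released_potential))
    abort("released_actual cannot exceed released_potential")
  if (is.null(site_order))
    site_order <- sort(unique(c(records$origin, records$destination,
                                releases$origin)))
  structure(list(records = records, releases = releases,
                 site_order = site_order),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, ...) {
  yrs <- sort(unique(x$releases$year))
  cat(sprintf("<flux_table> %d site(s), year(s) %s; %d arrival record(s)\n",
              length(x$site_order),
              paste(range(yrs), collapse = "-"), nrow(x$records)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flux_table <- function(x, ...) {
  dplyr::left_join(
    x$records,
    dplyr::select(x$releases, "year", "month", "origin",
                  "released_actual", "released_potential"),
    by = c("year", "month", "origin"))
}
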