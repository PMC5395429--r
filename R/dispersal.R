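#' Release sites
#'
#' Reads a sites table (columns `acronym`, `lon`, `lat`). With no argument,
#' returns the packaged Adriatic-Ionian (plus Western Mediterranean)
#' sampling locations of the study design (OTH, KAP, BOK, KOR, TRE, TOG,
#' OTR, POC, FRN, TUN).
#'
#' @param path Optional CSV path; default uses the packaged table.
#' @param adriatic_ionian If `TRUE` (default) keep only the eight
#'   Adriatic-Ionian sites modelled by the dispersal simulator.
#' @return A tibble with columns `acronym`, `lon`, `lat`.
#' @export
release_sites <- function(path = NULL, adriatic_ionian = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "release_sites.csv",
                        package = "seascaper", mustWork = TRUE)
  sites <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("acronym", "lon", "lat") %in% names(sites)))
    abort("sites file needs columns acronym, lon, lat")
  if (anyDuplicated(sites$acronym)) abort("site acronyms must be unique")
  if (adriatic_ionian && "basin" %in% names(sites))
    sites <- dplyr::filter(sites, .data$basin == "adriatic_ionian")
  dplyr::select(sites, "acronym", "lon", "lat")
}

#' Dispersal simulation configuration
#'
#' Default values are the biophysical model's study conditions: 1,000
#' larvae per site per spawning day; daily spawning April-July gated by an
#' 18 degC ceiling; release depths uniform on 0.5-10 m around a 1-km
#' Gaussian kernel; pelagic larval duration (PLD) Gaussian 30 +/- 5 days
#' (truncated to 1-60); 6-minute RK4 time step; mortality 3/day above
#' 18 degC (5% daily survival); 5-km arrival buffers.
#'
#' @param particles_per_day Larvae released per site per spawning day.
#' @param spawn_start,spawn_end Month-day strings bounding the spawning
#'   season (`"04-01"`, `"07-31"`).
#' @param spawn_temp_max Spawning-gate temperature ceiling, degC.
#' @param release_depth_min,release_depth_max Release depth band, m.
#' @param release_sigma_km Gaussian release-kernel SD, km.
#' @param pld_mean,pld_sd PLD Gaussian parameters, days.
#' @param pld_range Truncation bounds on the PLD, days.
#' @param dt_minutes Integration step, minutes.
#' @param mortality_rate Instantaneous mortality above threshold, 1/day.
#' @param mortality_temp Mortality temperature threshold, degC.
#' @param arrival_radius_km Arrival buffer radius, km.
#' @param years Integer vector of simulated years.
#' @param mortality_mode `"weight"` (deterministic expected-survival decay,
#'   default) or `"bernoulli"` (random killing with the same expectation).
#' @param seed Integer seed for the whole simulation.
#' @return A `dispersal_config` list.
#' @export
dispersal_config <- function(particles_per_day = 1000L,
                             spawn_start = "04-01", spawn_end = "07-31",
                             spawn_temp_max = 18,
                             release_depth_min = 0.5, release_depth_max = 10,
                             release_sigma_km = 1,
                             pld_mean = 30, pld_sd = 5,
                             pld_range = c(1, 60),
                             dt_minutes = 6,
                             mortality_rate = 3, mortality_temp = 18,
                             arrival_radius_km = 5,
                             years = 2004:2013,
                             mortality_mode = c("weight", "bernoulli"),
                             seed = 1L) {
  stopifnot(particles_per_day >= 1, dt_minutes > 0, mortality_rate >= 0,
            arrival_radius_km > 0, pld_sd > 0,
            release_depth_max >= release_depth_min)
  if (pld_mean <= 3 * pld_sd)
    abort("pld_mean must exceed 3 * pld_sd (truncation guard)")
  structure(list(
    particles_per_day = as.integer(particles_per_day),
    spawn_start = spawn_start, spawn_end = spawn_end,
    spawn_temp_max = spawn_temp_max,
    release_depth_min = release_depth_min,
    release_depth_max = release_depth_max,
    release_sigma_km = release_sigma_km,
    pld_mean = pld_mean, pld_sd = pld_sd, pld_range = pld_range,
    dt_minutes = dt_minutes,
    mortality_rate = mortality_rate, mortality_temp = mortality_temp,
    arrival_radius_km = arrival_radius_km,
    years = as.integer(years),
    mortality_mode = match.arg(mortality_mode),
    seed = as.integer(seed)), class = "dispersal_config")
}

# continuous time (days since field time_origin) of midnight opening a date
.date_to_time <- function(field, date) {
  as.numeric(as.Date(date) - field$grid$time_origin)
}

#' Spawning calendar for a site and year
#'
#' All dates in the spawning season whose water temperature at the site does
#' not exceed the spawning gate (18 degC by default). The gate temperature
#' is read at the site's nearest wet cell, shallowest depth level, daily
#' mean (noon stamp).
#'
#' @param field An [ocean_field()].
#' @param site One-row tibble (or list) with `acronym`, `lon`, `lat`.
#' @param year Integer year.
#' @param config A [dispersal_config()].
#' @return A `Date` vector of spawning days.
#' @export
spawning_days <- function(field, site, year, config = dispersal_config()) {
  g <- field$grid
  if (site$lon < g$lon_min || site$lon > g$lon_max ||
      site$lat < g$lat_min || site$lat > g$lat_max)
    abort(sprintf("site %s is outside the field domain", site$acronym))
  near <- .nearest_wet(field, site$lon, site$lat)
  days <- seq(as.Date(sprintf("%d-%s", year, config$spawn_start)),
              as.Date(sprintf("%d-%s", year, config$spawn_end)), by = "day")
  tq <- .date_to_time(field, days) + 0.5 # daily mean at noon
  temps <- sample_temp(field, near$lon, near$lat,
                       depth = g$depth_levels[1], time = tq)
  days[!is.na(temps$temp) & temps$temp <= config$spawn_temp_max]
}

# nearest wet grid node to a point (within 5 km preferred; nearest otherwise)
.nearest_wet <- function(field, lon, lat) {
  g <- field$grid
  if (is_wet(field, lon, lat)) return(list(lon = lon, lat = lat))
  wet_idx <- which(field$wet_mask, arr.ind = TRUE)
  wlon <- g$lon[wet_idx[, 1]]; wlat <- g$lat[wet_idx[, 2]]
  mx <- .M_PER_DEG * cos(lat * pi / 180)
  d2 <- ((wlon - lon) * mx)^2 + ((wlat - lat) * .M_PER_DEG)^2
  k <- which.min(d2)
  list(lon = wlon[k], lat = wlat[k], dist_m = sqrt(d2[k]))
}

#' Draw initial particle states for one release day
#'
#' Exactly `particles_per_day` larvae: horizontal positions from an
#' isotropic Gaussian kernel (SD `release_sigma_km`) around the site,
#' resampled until wet (at most 100 tries, then placed at the site); depths
#' uniform on the release band; PLD Gaussian truncated to `pld_range`;
#' initial survival weight 1. Draws consume the session RNG stream (seeded
#' once by [run_simulation()]).
#'
#' @inheritParams spawning_days
#' @param date Release date (must be a spawning day).
#' @return A tibble of particle states (`lon`, `lat`, `depth`, `pld`,
#'   `weight`, `origin`, `birth_date`, `status`).
#' @export
draw_release_states <- function(field, site, date,
                                config = dispersal_config()) {
  n <- config$particles_per_day
  mx <- .M_PER_DEG * cos(site$lat * pi / 180)
  sig <- config$release_sigma_km * 1000
  lon <- rep(site$lon, n); lat <- rep(site$lat, n)
  pending <- rep(TRUE, n)
  tries <- 0
  while (any(pending) && tries < 100 && sig > 0) {
    k <- sum(pending)
    lon[pending] <- site$lon + rnorm(k, 0, sig) / mx
    lat[pending] <- site$lat + rnorm(k, 0, sig) / .M_PER_DEG
    pending[pending] <- !is_wet(field, lon[pending], lat[pending])
    tries <- tries + 1
  }
  # unplaceable particles fall back to the site itself
  lon[pending] <- site$lon; lat[pending] <- site$lat
  pld <- rnorm(n, config$pld_mean, config$pld_sd)
  bad <- pld < config$pld_range[1] | pld > config$pld_range[2]
  while (any(bad)) {
    pld[bad] <- rnorm(sum(bad), config$pld_mean, config$pld_sd)
    bad <- pld < config$pld_range[1] | pld > config$pld_range[2]
  }
  tibble(
    lon = lon, lat = lat,
    depth = runif(n, config$release_depth_min, config$release_depth_max),
    pld = pld, weight = 1,
    origin = site$acronym, birth_date = as.Date(date),
    status = "in_transit")
}

# One classical RK4 step for a set of particles; returns new positions and
# a lost flag for particles any of whose stages sampled out of domain.
# dt in days; time in days since field origin.
.rk4_positions <- function(field, lon, lat, depth, time, dt) {
  deriv <- function(lo, la, tm) {
    w <- .interp_weights(field, lo, la, depth, tm)
    u <- .apply_weights(field$u, w, dry_zero = TRUE)
    v <- .apply_weights(field$v, w, dry_zero = TRUE)
    lost <- !w$ok
    u[lost] <- 0; v[lost] <- 0
    mx <- .M_PER_DEG * cos(la * pi / 180)
    list(dlon = u * 86400 / mx, dlat = v * 86400 / .M_PER_DEG,
         lost = lost)
  }
  k1 <- deriv(lon, lat, time)
  k2 <- deriv(lon + 0.5 * dt * k1$dlon, lat + 0.5 * dt * k1$dlat, time + dt / 2)
  k3 <- deriv(lon + 0.5 * dt * k2$dlon, lat + 0.5 * dt * k2$dlat, time + dt / 2)
  k4 <- deriv(lon + dt * k3$dlon, lat + dt * k3$dlat, time + dt)
  list(
    lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
    lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat),
    lost = k1$lost | k2$lost | k3$lost | k4$lost)
}

#' Single RK4 step of a particle
#'
#' Classical four-stage Runge-Kutta update of horizontal position at the
#' particle's fixed depth. Degrees are converted to metres with the local
#' equirectangular approximation. A step any of whose stages samples
#' outside the domain flags the particle `lost_domain`; a step landing on a
#' dry cell is cancelled (the particle stalls at the coast).
#'
#' @param field An [ocean_field()].
#' @param state One-row particle tibble (as from [draw_release_states()]).
#' @param time Continuous time, days since the field origin.
#' @param dt Step, days.
#' @return The updated state row.
#' @export
rk4_step <- function(field, state, time, dt) {
  stp <- .rk4_positions(field, state$lon, state$lat, state$depth, time, dt)
  new_lon <- stp$lon; new_lat <- stp$lat
  lost <- stp$lost
  g <- field$grid
  out <- new_lon < g$lon_min | new_lon > g$lon_max |
    new_lat < g$lat_min | new_lat > g$lat_max
  lost <- lost | out
  beach <- !lost & !is_wet(field, new_lon, new_lat)
  state$status[lost] <- "lost_domain"
  keep <- beach | lost
  state$lon <- ifelse(keep, state$lon, new_lon)
  state$lat <- ifelse(keep, state$lat, new_lat)
  state
}

#' Advect one particle through its pelagic phase
#'
#' Repeats [rk4_step()] until the particle's PLD elapses (or the particle
#' leaves the domain). After each step the local temperature at the
#' particle's fixed depth is sampled; time spent above the mortality
#' threshold decays the survival weight as `exp(-mu * tau)` (mu = 3/day by
#' default, i.e. 5% daily survival).
#'
#' @inheritParams rk4_step
#' @param config A [dispersal_config()].
#' @return The final state row, with cumulative `weight` and an added
#'   `hot_days` column (total days spent above the threshold).
#' @export
advect_particle <- function(field, state, config = dispersal_config()) {
  out <- .advect_cohort(field, state, config)
  out
}

#' Classify a particle's arrival
#'
#' Returns the acronym of the nearest site whose great-circle distance from
#' the particle's final position is within the arrival radius (5 km), or
#' `NA` if none. Ties are broken by smallest distance, then alphabetically.
#'
#' @param lon,lat Final particle position(s), degrees (vectorised).
#' @param sites Sites tibble (`acronym`, `lon`, `lat`).
#' @param config A [dispersal_config()].
#' @return Character vector of destination acronyms (`NA` = no arrival).
#' @export
classify_arrival <- function(lon, lat, sites, config = dispersal_config()) {
  ord <- order(sites$acronym) # alphabetical tie-break built into which.min
  sites <- sites[ord, ]
  n <- length(lon)
  dmat <- sapply(seq_len(nrow(sites)), function(k)
    geosphere::distHaversine(cbind(lon, lat),
                             c(sites$lon[k], sites$lat[k])))
  dmat <- matrix(dmat, nrow = n)
  best <- max.col(-dmat, ties.method = "first")
  dist <- dmat[cbind(seq_len(n), best)]
  dest <- sites$acronym[best]
  dest[!is.finite(dist) | dist > config$arrival_radius_km * 1000] <- NA
  dest
}
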