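#' Synthetic ocean fields
#'
#' Generates divergence-free daily velocity fields (superposed Gaussian
#' gyres derived from a streamfunction, plus optional noise) with a
#' sinusoidal annual temperature cycle, emulating the structure of a coastal
#' reanalysis product: daily u/v/T on a regular grid with a seasonal
#' temperature signal crossing the 18 degC spawning threshold between spring
#' and summer.
#'
#' Velocities are obtained from a discrete streamfunction by central
#' differences, so the central-difference divergence of the unperturbed
#' field vanishes identically on interior nodes.
#'
#' @param domain A [grid_spec()].
#' @param gyre_strength Peak streamfunction-derived speed scale, m/s.
#' @param gyre_centers List of `c(lon, lat)` gyre centres (default: one gyre
#'   at the domain centre).
#' @param gyre_radius_km Gaussian e-folding radius of each gyre, km.
#' @param mean_temp_winter,mean_temp_summer Winter minimum / summer maximum
#'   of the annual temperature cycle, degC.
#' @param temp_peak_day Day of year of the temperature maximum.
#' @param noise_sd Standard deviation of white velocity noise, m/s.
#' @param wet_mask Optional logical matrix; default all wet.
#' @param seed Integer seed; the field is reproducible given the seed.
#' @return An [ocean_field()].
#' @export
make_synthetic_field <- function(domain,
                                 gyre_strength = 0.2,
                                 gyre_centers = NULL,
                                 gyre_radius_km = 40,
                                 mean_temp_winter = 13,
                                 mean_temp_summer = 26,
                                 temp_peak_day = 225,
                                 noise_sd = 0,
                                 wet_mask = NULL,
                                 seed = 1L) {
  g <- domain
  stopifnot(inherits(g, "grid_spec"))
  if (gyre_strength < 0) abort("gyre_strength must be >= 0")
  if (mean_temp_summer < mean_temp_winter)
    abort("mean_temp_summer must be >= mean_temp_winter")
  nx <- length(g$lon); ny <- length(g$lat)
  nz <- length(g$depth_levels); nt <- g$n_days
  if (nx < 2 || ny < 2) abort("domain must span at least 2 x 2 grid nodes")
  if (is.null(gyre_centers))
    gyre_centers <- list(c(mean(range(g$lon)), mean(range(g$lat))))
  lat0 <- mean(range(g$lat))
  mx <- .M_PER_DEG * cos(lat0 * pi / 180) # metres per degree lon
  my <- .M_PER_DEG
  L <- gyre_radius_km * 1000

  # streamfunction on the nodes (sum of Gaussian bumps)
  psi <- matrix(0, nx, ny)
  X <- outer(g$lon, rep(1, ny)) * mx
  Y <- outer(rep(1, nx), g$lat) * my
  for (ctr in gyre_centers) {
    x0 <- ctr[1] * mx; y0 <- ctr[2] * my
    r2 <- (X - x0)^2 + (Y - y0)^2
    # amplitude chosen so the peak azimuthal speed is ~gyre_strength
    amp <- gyre_strength * L * exp(0.5)
    psi <- psi + amp * exp(-r2 / (2 * L^2))
  }
  # u = -dpsi/dy, v = dpsi/dx by central differences (one-sided at edges)
  dpsi_dy <- matrix(0, nx, ny)
  dpsi_dy[, 2:(ny - 1)] <- (psi[, 3:ny] - psi[, 1:(ny - 2)]) / (2 * g$d_lat * my)
  dpsi_dy[, 1] <- (psi[, 2] - psi[, 1]) / (g$d_lat * my)
  dpsi_dy[, ny] <- (psi[, ny] - psi[, ny - 1]) / (g$d_lat * my)
  dpsi_dx <- matrix(0, nx, ny)
  dpsi_dx[2:(nx - 1), ] <- (psi[3:nx, ] - psi[1:(nx - 2), ]) / (2 * g$d_lon * mx)
  dpsi_dx[1, ] <- (psi[2, ] - psi[1, ]) / (g$d_lon * mx)
  dpsi_dx[nx, ] <- (psi[nx, ] - psi[nx - 1, ]) / (g$d_lon * mx)
  u2 <- -dpsi_dy
  v2 <- dpsi_dx

  dims <- c(nx, ny, nz, nt)
  u <- array(u2, dim = dims)
  v <- array(v2, dim = dims)

  # annual temperature cycle, identical at every wet node and depth
  t0 <- as.POSIXlt(g$time_origin)$yday + 1 # day-of-year of day 1
  doy <- (t0 + seq_len(nt) - 1 - 1) %% 365.25
  mid <- (mean_temp_winter + mean_temp_summer) / 2
  amp <- (mean_temp_summer - mean_temp_winter) / 2
  temp_day <- mid + amp * cos(2 * pi * (doy - temp_peak_day) / 365.25)
  temp <- array(rep(temp_day, each = nx * ny * nz), dim = dims)

  if (noise_sd > 0) {
    .with_seed(seed, {
      u <- u + array(rnorm(prod(dims), 0, noise_sd), dim = dims)
      v <- v + array(rnorm(prod(dims), 0, noise_sd), dim = dims)
    })
  }
  if (is.null(wet_mask)) wet_mask <- matrix(TRUE, nx, ny)
  ocean_field(g, u, v, temp, wet_mask)
}

#' Solid-body rotation field (analytic advection oracle)
#'
#' A velocity field of rigid rotation about `center`: every particle moves
#' on an exact circle in degree coordinates, traversed at angular rate
#' `omega`. The stored eastward velocity carries a `cos(lat)` factor that
#' cancels the equirectangular metric conversion in the particle stepper, so
#' the governing ODE in degree space is exactly linear and the analytic
#' trajectory is exact - the canonical convergence oracle for the RK4
#' integrator.
#'
#' @param omega Angular rate, radians per day (positive = anticlockwise).
#' @param center `c(lon, lat)` of the rotation centre, degrees.
#' @param radius_km Domain half-width around the centre, km.
#' @param d_deg Grid spacing, degrees (default 1/200 degree: fine enough
#'   that bilinear interpolation error is negligible next to RK4 truncation
#'   error).
#' @param n_days Stored time span, days.
#' @param temperature Uniform temperature, degC (default 15, below the
#'   mortality threshold).
#' @return An [ocean_field()].
#' @export
solid_body_field <- function(omega, center = c(0, 0), radius_km = 30,
                             d_deg = 1 / 200, n_days = 3L,
                             temperature = 15) {
  stopifnot(is.finite(omega))
  half_deg <- radius_km * 1000 / .M_PER_DEG * 1.6
  g <- grid_spec(center[1] - half_deg, center[1] + half_deg,
                 center[2] - half_deg, center[2] + half_deg,
                 d_lon = d_deg, d_lat = d_deg,
                 depth_levels = c(0, 20), n_days = n_days)
  nx <- length(g$lon); ny <- length(g$lat)
  # degree-space ODE: dlon/dt = -omega (lat - lat0), dlat/dt = omega (lon - lon0)
  # stepper converts u [m/s] -> dlon/dt = u * 86400 / (M cos lat), so store
  # u = -omega (lat - lat0) * M cos(lat) / 86400 and v without the cos factor.
  latm <- outer(rep(1, nx), g$lat)
  lonm <- outer(g$lon, rep(1, ny))
  u2 <- -omega * (latm - center[2]) * .M_PER_DEG * cos(latm * pi / 180) / 86400
  v2 <- omega * (lonm - center[1]) * .M_PER_DEG / 86400
  dims <- c(nx, ny, 2L, n_days)
  u <- array(u2, dim = dims)
  v <- array(v2, dim = dims)
  temp <- array(temperature, dim = dims)
  ocean_field(g, u, v, temp, matrix(TRUE, nx, ny))
}
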