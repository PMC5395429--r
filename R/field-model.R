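#' Grid specification for gridded ocean fields
#'
#' Describes the regular longitude/latitude grid, fixed depth levels (metres,
#' surface down) and daily time axis on which velocity and temperature fields
#' are stored. Daily means are stamped at 12:00, i.e. stored day `d`
#' (1-based) lives at continuous time `d - 0.5` days since `time_origin`.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds in degrees.
#' @param d_lon,d_lat Grid spacing in degrees (default 1/45 degree, about
#'   2.2 km, the resolution of the Adriatic reanalysis this emulates).
#' @param depth_levels Numeric vector of depth levels in metres, strictly
#'   increasing from the surface down.
#' @param time_origin Calendar date (`Date` or ISO string) of time zero.
#' @param n_days Number of stored daily fields.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max,
                      d_lon = 1 / 45, d_lat = 1 / 45,
                      depth_levels = c(0, 10),
                      time_origin = as.Date("2004-01-01"),
                      n_days = 1L) {
  stopifnot(d_lon > 0, d_lat > 0, lon_max > lon_min, lat_max > lat_min)
  depth_levels <- as.numeric(depth_levels)
  if (length(depth_levels) < 1 || is.unsorted(depth_levels, strictly = TRUE))
    abort("depth_levels must be strictly increasing (surface down)")
  if (n_days < 1) abort("n_days must be >= 1")
  lon <- seq(lon_min, lon_max, by = d_lon)
  lat <- seq(lat_min, lat_max, by = d_lat)
  structure(
    list(lon_min = lon_min, lon_max = max(lon), lat_min = lat_min,
         lat_max = max(lat), d_lon = d_lon, d_lat = d_lat,
         lon = lon, lat = lat,
         depth_levels = depth_levels,
         time_origin = as.Date(time_origin), n_days = as.integer(n_days)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d nodes, lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
    length(x$lon), length(x$lat), x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  cat(sprintf("  %d depth level(s) [%g, %g] m; %d day(s) from %s\n",
              length(x$depth_levels), min(x$depth_levels),
              max(x$depth_levels), x$n_days, format(x$time_origin)))
  invisible(x)
}

#' Gridded daily ocean field
#'
#' Bundles eastward/northward velocity (m/s) and temperature (degrees C) on a
#' regular (lon, lat, depth, time) grid with a land/sea mask. This is the
#' physical driver of the larval-dispersal simulator.
#'
#' @param grid A [grid_spec()].
#' @param u,v,temperature Numeric arrays of dimension
#'   `(n_lon, n_lat, n_depth, n_days)`.
#' @param wet_mask Logical matrix `(n_lon, n_lat)`; `TRUE` marks sea cells.
#' @return An `ocean_field` object.
#' @export
ocean_field <- function(grid, u, v, temperature, wet_mask) {
  stopifnot(inherits(grid, "grid_spec"))
  dims <- c(length(grid$lon), length(grid$lat),
            length(grid$depth_levels), grid$n_days)
  for (nm in c("u", "v", "temperature")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), as.integer(dims)))
      abort(sprintf("variable '%s' must be an array of dim (%s)",
                    nm, paste(dims, collapse = ", ")))
  }
  wet_mask <- as.matrix(wet_mask)
  storage.mode(wet_mask) <- "logical"
  if (!identical(dim(wet_mask), as.integer(dims[1:2])))
    abort("wet_mask dimensions do not match the grid")
  if (!any(wet_mask)) abort("wet_mask must contain at least one wet cell")
  wet4 <- array(wet_mask, dim = dims)
  for (nm in c("u", "v", "temperature")) {
    a <- get(nm)
    if (any(!is.finite(a[wet4])))
      abort(sprintf("variable '%s' is not finite on wet cells", nm))
  }
  # dry cells are normalised to 0 so that fields round-trip exactly
  u[!wet4] <- 0; v[!wet4] <- 0; temperature[!wet4] <- 0
  structure(list(grid = grid, u = u, v = v, temperature = temperature,
                 wet_mask = wet_mask),
            class = "ocean_field")
}

#' @export
print.ocean_field <- function(x, ...) {
  cat("<ocean_field>\n")
  print(x$grid)
  cat(sprintf("  wet fraction %.1f%%; u in [%.3g, %.3g] m/s; T in [%.1f, %.1f] C\n",
              100 * mean(x$wet_mask),
              min(x$u[is.finite(x$u)]), max(x$u[is.finite(x$u)]),
              min(x$temperature[is.finite(x$temperature)]),
              max(x$temperature[is.finite(x$temperature)])))
  invisible(x)
}

# Locate queries on the grid. Returns integer cell indices and fractional
# offsets; ok = FALSE for points outside the horizontal domain.
.locate <- function(grid, lon, lat) {
  fx <- (lon - grid$lon[1]) / grid$d_lon
  fy <- (lat - grid$lat[1]) / grid$d_lat
  nx <- length(grid$lon); ny <- length(grid$lat)
  ok <- is.finite(fx) & is.finite(fy) &
    fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  i <- pmin(pmax(floor(fx), 0), nx - 2) # left node of the bracketing cell
  j <- pmin(pmax(floor(fy), 0), ny - 2)
  tx <- fx - floor(pmin(pmax(fx, 0), nx - 2))
  ty <- fy - floor(pmin(pmax(fy, 0), ny - 2))
  if (nx == 1) { i <- rep(0L, length(fx)); tx <- rep(0, length(fx)) }
  if (ny == 1) { j <- rep(0L, length(fy)); ty <- rep(0, length(fy)) }
  list(i = as.integer(i) + 1L, j = as.integer(j) + 1L,
       tx = tx, ty = ty, ok = ok)
}

# Fractional index along depth and time axes (clamped to the stored range).
.axis_frac <- function(coords, x) {
  n <- length(coords)
  if (n == 1) return(list(k = rep(1L, length(x)), t = rep(0, length(x))))
  x <- pmin(pmax(x, coords[1]), coords[n])
  k <- findInterval(x, coords, all.inside = TRUE)
  list(k = k, t = (x - coords[k]) / (coords[k + 1] - coords[k]))
}

# Shared interpolation weights for a set of query points: horizontal
# corner indices/weights with wet-mask info, plus depth/time brackets.
.interp_weights <- function(field, lon, lat, depth, time) {
  g <- field$grid
  n <- length(lon)
  lat <- rep_len(lat, n); depth <- rep_len(depth, n)
  time <- rep_len(time, n)
  loc <- .locate(g, lon, lat)
  dz <- .axis_frac(g$depth_levels, depth)
  tstamp <- seq_len(g$n_days) - 0.5
  tt <- .axis_frac(tstamp, time)
  ok <- loc$ok & time >= 0 & time <= g$n_days
  idx <- which(ok)
  if (!length(idx))
    return(list(n = n, idx = idx, ok = ok))
  nx <- length(g$lon); ny <- length(g$lat)
  tx <- loc$tx[idx]; ty <- loc$ty[idx]
  ii <- loc$i[idx]; jj <- loc$j[idx]
  i1 <- pmin(ii + 1L, nx); j1 <- pmin(jj + 1L, ny)
  wm <- field$wet_mask
  m00 <- wm[(jj - 1L) * nx + ii]; m10 <- wm[(jj - 1L) * nx + i1]
  m01 <- wm[(j1 - 1L) * nx + ii]; m11 <- wm[(j1 - 1L) * nx + i1]
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  wetw <- w00 * m00 + w10 * m10 + w01 * m01 + w11 * m11
  list(n = n, idx = idx, ok = ok,
       ii = ii, jj = jj, i1 = i1, j1 = j1,
       w00 = w00, w10 = w10, w01 = w01, w11 = w11,
       m00 = m00, m10 = m10, m01 = m01, m11 = m11,
       wetw = wetw, all_dry = wetw <= 0,
       kk = dz$k[idx], tz = dz$t[idx], dd = tt$k[idx], td = tt$t[idx],
       nx = nx, ny = ny, nz = length(g$depth_levels), nt = g$n_days)
}

# Apply precomputed weights to one variable array. dry_zero = TRUE treats
# dry nodes as 0 (velocities); FALSE renormalises over wet nodes
# (temperature), returning NA where all four nodes are dry.
.apply_weights <- function(arr, w, dry_zero) {
  if (!length(w$idx)) return(rep(NA_real_, w$n))
  nx <- w$nx; nxy <- w$nx * w$ny; nxyz <- nxy * w$nz
  val <- numeric(length(w$idx))
  zlo <- 0:(if (w$nz > 1) 1 else 0)
  tlo <- 0:(if (w$nt > 1) 1 else 0)
  for (zo in zlo) for (to in tlo) {
    wz <- if (w$nz > 1) (if (zo == 0) 1 - w$tz else w$tz) else 1
    wt <- if (w$nt > 1) (if (to == 0) 1 - w$td else w$td) else 1
    k2 <- pmin(w$kk + zo, w$nz); d2 <- pmin(w$dd + to, w$nt)
    base <- (d2 - 1L) * nxyz + (k2 - 1L) * nxy
    a00 <- arr[base + (w$jj - 1L) * nx + w$ii] * w$m00
    a10 <- arr[base + (w$jj - 1L) * nx + w$i1] * w$m10
    a01 <- arr[base + (w$j1 - 1L) * nx + w$ii] * w$m01
    a11 <- arr[base + (w$j1 - 1L) * nx + w$i1] * w$m11
    plane <- w$w00 * a00 + w$w10 * a10 + w$w01 * a01 + w$w11 * a11
    if (!dry_zero) plane <- plane / ifelse(w$all_dry, 1, w$wetw)
    val <- val + wz * wt * plane
  }
  if (dry_zero) val[w$all_dry] <- 0 else val[w$all_dry] <- NA_real_
  out <- rep(NA_real_, w$n)
  out[w$idx] <- val
  out
}

# Space-time interpolation of one variable, vectorised over query points.
# For velocities dry nodes contribute 0 m/s (free slip at the coast);
# for temperature weights are renormalised over wet nodes.
.sample_var <- function(field, var, lon, lat, depth, time, dry_zero = TRUE) {
  n <- max(length(lon), length(lat), length(depth), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  depth <- rep_len(depth, n); time <- rep_len(time, n)
  w <- .interp_weights(field, lon, lat, depth, time)
  value <- .apply_weights(field[[var]], w, dry_zero)
  status <- rep("out_of_domain", n)
  status[w$idx] <- ifelse(w$all_dry, "dry", "ok")
  list(value = value, status = status)
}

#' Sample velocity from an ocean field
#'
#' Bilinear interpolation in lon/lat, linear in depth and time (daily means
#' stamped at 12:00). Velocity at dry neighbour nodes contributes 0 m/s
#' (free slip), preventing spurious onshore extrapolation. Queries outside
#' the horizontal domain or time span are flagged `out_of_domain`; queries
#' whose four surrounding nodes are all dry are flagged `dry`.
#'
#' @param field An [ocean_field()].
#' @param lon,lat Query coordinates, degrees (vectorised).
#' @param depth Query depth, metres (clamped to the stored level range).
#' @param time Continuous time in days since the grid's `time_origin`.
#' @return A tibble with columns `u`, `v` (m/s) and `status`
#'   (`"ok"`, `"dry"` or `"out_of_domain"`).
#' @export
sample_uv <- function(field, lon, lat, depth, time) {
  su <- .sample_var(field, "u", lon, lat, depth, time, dry_zero = TRUE)
  sv <- .sample_var(field, "v", lon, lat, depth, time, dry_zero = TRUE)
  tibble(u = su$value, v = sv$value, status = su$status)
}

#' Sample temperature from an ocean field
#'
#' Interpolation as in [sample_uv()], except that dry neighbour nodes are
#' excluded and weights renormalised over wet nodes (a 0 degC land value
#' would be physically meaningless).
#'
#' @inheritParams sample_uv
#' @return A tibble with columns `temp` (degrees C) and `status`.
#' @export
sample_temp <- function(field, lon, lat, depth, time) {
  st <- .sample_var(field, "temperature", lon, lat, depth, time,
                    dry_zero = FALSE)
  tibble(temp = st$value, status = st$status)
}

#' Is a position on a wet cell?
#'
#' `TRUE` iff the grid cell containing the point (nearest grid node) is sea.
#' Out-of-domain positions return `FALSE`.
#'
#' @inheritParams sample_uv
#' @return Logical vector.
#' @export
is_wet <- function(field, lon, lat) {
  g <- field$grid
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  i <- round((lon - g$lon[1]) / g$d_lon) + 1
  j <- round((lat - g$lat[1]) / g$d_lat) + 1
  ok <- is.finite(i) & is.finite(j) &
    i >= 1 & i <= length(g$lon) & j >= 1 & j <= length(g$lat)
  out <- rep(FALSE, n)
  out[ok] <- field$wet_mask[cbind(as.integer(i[ok]), as.integer(j[ok]))]
  out
}
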