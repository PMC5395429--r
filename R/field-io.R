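#' Write an ocean field to disk
#'
#' Fields are stored as a single self-describing JSON text container holding
#' the grid (dims time/depth/lat/lon, `time_origin` attribute) and the
#' flattened `u`, `v`, `temp` and `wet_mask` variables at full double
#' precision. Land cells are stored with the fill value `1e20`.
#'
#' @param field An [ocean_field()].
#' @param path Output file path (conventionally `.oceanfield.json`).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  g <- field$grid
  fill <- 1e20
  dry4 <- array(!field$wet_mask,
                dim = c(length(g$lon), length(g$lat),
                        length(g$depth_levels), g$n_days))
  num <- function(a) { a[dry4] <- fill; as.numeric(a) }
  obj <- list(
    format = "seascaper-oceanfield",
    version = 1L,
    grid = list(lon_min = g$lon_min, lon_max = g$lon_max,
                lat_min = g$lat_min, lat_max = g$lat_max,
                d_lon = g$d_lon, d_lat = g$d_lat,
                depth_levels = g$depth_levels,
                time_origin = format(g$time_origin),
                n_days = g$n_days),
    fill_value = fill,
    dims = c(length(g$lon), length(g$lat),
             length(g$depth_levels), g$n_days),
    u = num(field$u), v = num(field$v), temp = num(field$temperature),
    wet_mask = as.integer(field$wet_mask)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an ocean field from disk
#'
#' Reads a file written by [write_field()] and returns a validated
#' [ocean_field()]. Missing variables or inconsistent axes raise a format
#' error naming the offending variable.
#'
#' @param path File path.
#' @return An [ocean_field()].
#' @export
load_field <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such field file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "seascaper-oceanfield"))
    abort("not a seascaper ocean-field file (missing format marker)")
  for (nm in c("grid", "dims", "u", "v", "temp", "wet_mask"))
    if (is.null(obj[[nm]]))
      abort(sprintf("field file is missing variable '%s'", nm))
  gg <- obj$grid
  for (nm in c("lon_min", "lat_min", "d_lon", "d_lat", "depth_levels",
               "time_origin", "n_days"))
    if (is.null(gg[[nm]]))
      abort(sprintf("field file grid is missing '%s'", nm))
  grid <- grid_spec(gg$lon_min, gg$lon_max, gg$lat_min, gg$lat_max,
                    d_lon = gg$d_lon, d_lat = gg$d_lat,
                    depth_levels = gg$depth_levels,
                    time_origin = as.Date(gg$time_origin),
                    n_days = gg$n_days)
  dims <- as.integer(obj$dims)
  expect <- c(length(grid$lon), length(grid$lat),
              length(grid$depth_levels), grid$n_days)
  if (!identical(dims, as.integer(expect)))
    abort("field file axis mismatch: 'dims' do not match the grid")
  n <- prod(dims)
  fill <- obj$fill_value %||% 1e20
  get_arr <- function(nm) {
    x <- as.numeric(obj[[nm]])
    if (length(x) != n)
      abort(sprintf("variable '%s' has length %d, expected %d",
                    nm, length(x), n))
    x[x >= fill / 2] <- NA_real_
    array(x, dim = dims)
  }
  u <- get_arr("u"); v <- get_arr("v"); temp <- get_arr("temp")
  wet <- matrix(as.logical(obj$wet_mask), dims[1], dims[2])
  # land cells flagged via fill values must agree with the stored mask
  dry4 <- array(!wet, dim = dims)
  u[dry4] <- 0; v[dry4] <- 0; temp[dry4] <- 0
  ocean_field(grid, u, v, temp, wet)
}
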