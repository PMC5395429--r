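test_that("sampling a uniform field returns the constant anywhere", {
  f <- uniform_field(u = 0.1, v = 0, temp = 15)
  s <- sample_uv(f, c(0.13, 0.5, 0.99), c(0.21, 0.5, 0.01), 3, 1.2)
  expect_equal(s$u, rep(0.1, 3))
  expect_equal(s$v, rep(0, 3))
  expect_true(all(s$status == "ok"))
  expect_equal(sample_temp(f, 0.4, 0.6, 5, 0.7)$temp, 15)
})

test_that("interpolation is exact on grid nodes at stored days", {
  g <- grid_spec(0, 1, 0, 1, d_lon = 0.25, d_lat = 0.25,
                 depth_levels = c(0, 10), n_days = 3)
  dims <- c(5, 5, 2, 3)
  set.seed(11)
  u <- array(rnorm(prod(dims)), dims)
  f <- ocean_field(g, u, array(0, dims), array(15, dims),
                   matrix(TRUE, 5, 5))
  # node (3, 4), depth level 1, day 2 (time 1.5)
  s <- sample_uv(f, g$lon[3], g$lat[4], 0, 1.5)
  expect_equal(s$u, u[3, 4, 1, 2], tolerance = 1e-12)
})

test_that("time interpolation between daily means is linear", {
  g <- grid_spec(0, 1, 0, 1, d_lon = 0.5, d_lat = 0.5,
                 depth_levels = 0, n_days = 2)
  dims <- c(3, 3, 1, 2)
  u <- array(0, dims); u[, , , 2] <- 0.2
  f <- ocean_field(g, u, array(0, dims), array(c(16, 20)[slice.index(
    array(0, dims), 4)], dims), matrix(TRUE, 3, 3))
  expect_equal(sample_uv(f, 0.5, 0.5, 0, 1.0)$u, 0.1)
  expect_equal(sample_temp(f, 0.5, 0.5, 0, 1.0)$temp, 18)
})

test_that("interpolated values stay within the stored-value envelope", {
  g <- grid_spec(0, 1, 0, 1, d_lon = 0.2, d_lat = 0.2,
                 depth_levels = c(0, 5, 10), n_days = 4)
  dims <- c(6, 6, 3, 4)
  set.seed(21)
  u <- array(rnorm(prod(dims)), dims)
  f <- ocean_field(g, u, u, array(15, dims), matrix(TRUE, 6, 6))
  for (i in 1:50) {
    q <- sample_uv(f, runif(1, 0, 1), runif(1, 0, 1),
                   runif(1, 0, 10), runif(1, 0.5, 3.5))
    expect_gte(q$u, min(u))
    expect_lte(q$u, max(u))
  }
})

test_that("velocity sampling is continuous across cell boundaries", {
  g <- grid_spec(0, 1, 0, 1, d_lon = 0.2, d_lat = 0.2,
                 depth_levels = 0, n_days = 2)
  dims <- c(6, 6, 1, 2)
  set.seed(31)
  u <- array(rnorm(prod(dims)), dims)
  f <- ocean_field(g, u, u, array(15, dims), matrix(TRUE, 6, 6))
  eps <- 1e-9
  for (edge in c(0.2, 0.4, 0.6)) {
    lo <- sample_uv(f, edge - eps, 0.31, 0, 1)$u
    hi <- sample_uv(f, edge + eps, 0.31, 0, 1)$u
    expect_equal(lo, hi, tolerance = 1e-6)
  }
})

test_that("out-of-domain and dry queries are signalled", {
  wet <- matrix(TRUE, 21, 21); wet[1:6, 1:6] <- FALSE
  f <- uniform_field(u = 0.1, wet = wet)
  expect_equal(sample_uv(f, 2, 0.5, 0, 1)$status, "out_of_domain")
  expect_equal(sample_uv(f, 0.05, 0.05, 0, 1)$status, "dry")
  # velocity inside the dry block contributes zero
  expect_equal(sample_uv(f, 0.05, 0.05, 0, 1)$u, 0)
  expect_true(is.na(sample_temp(f, 0.05, 0.05, 0, 1)$temp))
  expect_false(is_wet(f, 0.05, 0.05))
  expect_true(is_wet(f, 0.9, 0.9))
  expect_false(is_wet(f, 1.5, 0.5)) # beyond lon_max
})

test_that("field files round-trip through disk", {
  path <- withr::local_tempfile(fileext = ".oceanfield.json")
  wet <- matrix(TRUE, 21, 21); wet[1, ] <- FALSE
  g <- grid_spec(10, 11, 40, 41, d_lon = 0.05, d_lat = 0.05,
                 depth_levels = c(0, 10), n_days = 2)
  dims <- c(21, 21, 2, 2)
  set.seed(5)
  f <- ocean_field(g, array(rnorm(prod(dims)), dims),
                   array(rnorm(prod(dims)), dims),
                   array(runif(prod(dims), 10, 25), dims), wet)
  write_field(f, path)
  f2 <- load_field(path)
  expect_equal(f2$grid$lon, f$grid$lon)
  expect_equal(f2$u, f$u, tolerance = 1e-12)
  expect_equal(f2$wet_mask, f$wet_mask)
  # sampled velocities agree at random points
  set.seed(6)
  lon <- runif(20, 10, 11); lat <- runif(20, 40, 41)
  expect_equal(sample_uv(f2, lon, lat, 5, 1)$u,
               sample_uv(f, lon, lat, 5, 1)$u, tolerance = 1e-6)
})

test_that("malformed field files raise named format errors", {
  path <- withr::local_tempfile(fileext = ".json")
  f <- uniform_field(u = 0.1)
  write_field(f, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$v <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_field(path), "'v'")
  obj$v <- obj$u[-1] # wrong length
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_field(path), "'v'")
})
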