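test_that("cell areas match the spherical closed form and conserve the sphere", {
  g <- geo_grid(2)
  a <- cell_areas(g)
  # 0-2N band cell, hand-evaluated closed form
  expect_equal(a$area[46, 1], band_area(0, 2, 2), tolerance = 1e-12)
  expect_equal(a$area[46, 1], 49447.2, tolerance = 1e-4)
  # conservation: sum = 4 pi R^2
  expect_lt(abs(sum(a$area) - 4 * pi * 6371^2) / (4 * pi * 6371^2), 1e-6)
  # equatorial symmetry: 40-42N vs 40-42S
  expect_equal(a$area[66, 10], a$area[25, 10], tolerance = 1e-12)
  # all positive, constant along longitude
  expect_true(all(a$area > 0))
  expect_equal(a$area[, 1], a$area[, 90])
  # conservation holds for other resolutions and radii too
  for (res in c(1, 5, 10)) {
    aa <- cell_areas(geo_grid(res), radius = 1)
    expect_lt(abs(sum(aa$area) - 4 * pi) / (4 * pi), 1e-6)
  }
})

test_that("grid construction validates its inputs", {
  expect_error(geo_grid(7), "divide")
  expect_error(geo_grid(-2), "positive")
  g <- geo_grid(2)
  expect_equal(g$nlat, 90L)
  expect_equal(g$nlon, 180L)
  expect_true(all(g$lat_centers > g$lat_edges[-length(g$lat_edges)]))
  expect_true(all(g$lat_centers < g$lat_edges[-1]))
  expect_error(cell_areas(g, radius = -1), "positive")
})

test_that("gridded_field enforces finiteness and sign constraints", {
  g <- geo_grid(10)
  expect_error(gridded_field(g, matrix(-1, g$nlat, g$nlon), "mg C m-2 day-1"),
               "non-negative")
  f <- gridded_field(g, matrix(-5, g$nlat, g$nlon), "degC")  # SST may be < 0
  expect_true(all(f$valid))
  v <- matrix(1, g$nlat, g$nlon); v[1, 1] <- NA
  f2 <- gridded_field(g, v, "h km-2 yr-1")
  expect_false(f2$valid[1, 1])
  expect_equal(sum(f2$valid), g$nlat * g$nlon - 1L)
})

test_that("regrid_mean takes area-weighted means and handles validity", {
  src <- geo_grid(1); tgt <- geo_grid(2)
  # constant field stays constant
  cf <- gridded_field(src, matrix(3.5, src$nlat, src$nlon), "mg C m-2 day-1")
  rg <- regrid_mean(cf, tgt)
  expect_true(all(abs(rg$values - 3.5) < 1e-12))
  # two equal-area valid cells (same 1-degree row), values 1 and 3 -> mean 2
  f <- sparse_field(src, cbind(c(91, 91), c(1, 2)), c(1, 3))
  rg <- regrid_mean(f, tgt)
  expect_equal(rg$values[46, 1], 2)
  expect_false(rg$valid[1, 1])  # no valid source cells -> invalid target
  # different latitudes: weights from the closed-form band areas
  f2 <- sparse_field(src, cbind(c(91, 92), c(1, 1)), c(0, 3))
  a1 <- band_area(0, 1, 1); a2 <- band_area(1, 2, 1)
  rg2 <- regrid_mean(f2, tgt)
  expect_equal(rg2$values[46, 1], (a1 * 0 + a2 * 3) / (a1 + a2), tolerance = 1e-12)
  # non-nesting grids rejected
  expect_error(regrid_mean(cf, geo_grid(1.5)), "nest")
})

test_that("regrid_mean conserves the area integral of fully valid fields", {
  src <- geo_grid(1); tgt <- geo_grid(5)
  set.seed(7)
  f <- gridded_field(src, matrix(rexp(src$nlat * src$nlon), src$nlat, src$nlon),
                     "mg C m-2 day-1")
  a_src <- cell_areas(src); a_tgt <- cell_areas(tgt)
  rg <- regrid_mean(f, tgt)
  before <- sum(f$values * a_src$area)
  after <- sum(rg$values * a_tgt$area)
  expect_lt(abs(before - after) / before, 1e-12)
})

test_that("log_z standardizes logged values with documented guards", {
  g <- geo_grid(10)
  # constant field -> zero-variance guard -> all zeros
  z <- log_z(gridded_field(g, matrix(4, g$nlat, g$nlon), "h km-2 yr-1"))
  expect_true(all(z$values[z$valid] == 0))
  # two-cell field {a, a e^2} -> z-scores -1, +1 (population SD)
  f <- sparse_field(g, cbind(c(5, 5), c(1, 2)), c(2, 2 * exp(2)), "h km-2 yr-1")
  z2 <- log_z(f)
  expect_equal(sort(z2$values[z2$valid]), c(-1, 1), tolerance = 1e-6)
  # zero cells stay finite via the epsilon guard
  f3 <- sparse_field(g, cbind(c(5, 5, 5), 1:3), c(0, 1, 5), "h km-2 yr-1")
  z3 <- log_z(f3)
  expect_true(all(is.finite(z3$values[z3$valid])))
  # mean 0, SD 1 whenever input has spread
  set.seed(1)
  f4 <- gridded_field(g, matrix(rexp(g$nlat * g$nlon), g$nlat, g$nlon),
                      "h km-2 yr-1")
  z4 <- log_z(f4)
  v <- z4$values[z4$valid]
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean(v^2)) - 1), 1e-9)
  # all-invalid field is an error
  empty <- gridded_field(g, matrix(NA_real_, g$nlat, g$nlon), "h km-2 yr-1",
                         matrix(FALSE, g$nlat, g$nlon))
  expect_error(log_z(empty), "valid")
})

test_that("global_integral converts mg C m-2 day-1 to Gt C yr-1", {
  g <- geo_grid(2); a <- cell_areas(g)
  f <- gridded_field(g, matrix(60, g$nlat, g$nlon), "mg C m-2 day-1")
  total_m2 <- sum(a$area) * 1e6
  expect_equal(global_integral(f, a), 60 * total_m2 * 365 / 1e18,
               tolerance = 1e-12)
  # zero field -> 0; linearity
  z <- gridded_field(g, matrix(0, g$nlat, g$nlon), "mg C m-2 day-1")
  expect_equal(global_integral(z, a), 0)
  f2 <- gridded_field(g, 2 * f$values, "mg C m-2 day-1")
  expect_equal(global_integral(f2, a), 2 * global_integral(f, a),
               tolerance = 1e-12)
  # splitting the domain into disjoint masks and summing is invariant
  m1 <- matrix(FALSE, g$nlat, g$nlon); m1[1:45, ] <- TRUE
  expect_equal(global_integral(f, a, m1) + global_integral(f, a, !m1),
               global_integral(f, a), tolerance = 1e-12)
  # unit mismatch is an error
  expect_error(global_integral(
    gridded_field(g, f$values, "h km-2 yr-1"), a), "units")
})

test_that("CSV grid dump round-trips values, grid and validity", {
  g <- geo_grid(10)
  set.seed(3)
  v <- matrix(rexp(g$nlat * g$nlon), g$nlat, g$nlon)
  v[sample(length(v), 20)] <- NA
  f <- gridded_field(g, v, "mg C m-2 day-1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  f2 <- read_field_csv(path, "mg C m-2 day-1")
  expect_equal(f2$grid$resolution, 10)
  expect_equal(f2$valid, f$valid)
  expect_equal(f2$values[f2$valid], f$values[f$valid], tolerance = 1e-9)
})
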