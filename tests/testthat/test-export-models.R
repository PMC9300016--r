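test_that("e-ratio registry matches hand-computed point values", {
  expect_equal(e_ratio("henson", sst = 0), 0.23, tolerance = 1e-12)
  expect_equal(e_ratio("henson", sst = 10), 0.23 * exp(-0.8), tolerance = 1e-12)
  expect_equal(e_ratio("henson", sst = 10), 0.1033, tolerance = 5e-4)
  expect_equal(e_ratio("laws", sst = 15, npp = 500),
               0.04756 * 0.565 * 500^0.307, tolerance = 1e-12)
  expect_equal(e_ratio("laws", sst = 15, npp = 500), 0.18108, tolerance = 1e-4)
  expect_equal(e_ratio("dunne", sst = 20, npp = 100, zeu = 100), 0.217,
               tolerance = 1e-12)
  expect_equal(e_ratio("dunne", sst = 40, npp = 100, zeu = 100), 0.04)
})

test_that("e-ratios stay in [0, 1] with documented clips over a sweep", {
  sst <- seq(-2, 60, by = 0.5)
  npp <- c(0.01, 1, 50, 500, 5000)
  grid <- expand.grid(sst = sst, npp = npp)
  for (alg in c("henson", "laws")) {
    r <- e_ratio(alg, sst = grid$sst, npp = grid$npp)
    expect_true(all(r >= 0 & r <= 1), info = alg)
  }
  r <- e_ratio("dunne", sst = grid$sst, npp = grid$npp, zeu = 80)
  expect_true(all(r >= 0.04 & r <= 0.72))
  # LAWS negative polynomial at extreme SST clips to 0
  expect_equal(e_ratio("laws", sst = 60, npp = 500), 0)
  # HENSON strictly decreasing in SST
  h <- e_ratio("henson", sst = sst)
  expect_true(all(diff(h) < 0))
  # DUNNE non-increasing in SST, non-decreasing in NPP/Zeu
  d1 <- e_ratio("dunne", sst = sst, npp = 300, zeu = 80)
  expect_true(all(diff(d1) <= 0))
  d2 <- e_ratio("dunne", sst = 12, npp = exp(seq(0, 9, 0.25)), zeu = 80)
  expect_true(all(diff(d2) >= 0))
  # DUNNE at NPP = 0 takes the lower clip
  expect_equal(e_ratio("dunne", sst = 12, npp = 0, zeu = 80), 0.04)
})

test_that("missing drivers and unknown algorithms are named errors", {
  expect_error(e_ratio("dunne", sst = 10, npp = 100), "zeu")
  expect_error(e_ratio("henson"), "sst")
  expect_error(e_ratio("nosuch", sst = 1), "unknown export algorithm")
  g <- geo_grid(10)
  inp <- export_inputs(
    sst = gridded_field(g, matrix(10, g$nlat, g$nlon), "degC"),
    npp = gridded_field(g, matrix(300, g$nlat, g$nlon), "mg C m-2 day-1"))
  expect_error(export_member(inp, "dunne"), "zeu")
  expect_error(export_member(inp, "model"), "model_export")
})

test_that("custom algorithms can be registered and used", {
  register_export_algorithm("flat10", function(sst, npp, zeu) rep(0.1, length(npp)),
                            needs = "npp")
  expect_equal(e_ratio("flat10", npp = c(1, 2)), c(0.1, 0.1))
  g <- geo_grid(10)
  inp <- export_inputs(
    sst = gridded_field(g, matrix(10, g$nlat, g$nlon), "degC"),
    npp = gridded_field(g, matrix(200, g$nlat, g$nlon), "mg C m-2 day-1"))
  m <- export_member(inp, "flat10")
  expect_true(all(abs(m$values - 20) < 1e-12))
})

test_that("ensemble mean is the valid-member cell-wise mean", {
  g <- geo_grid(10)
  mk <- function(v, valid = NULL) {
    vals <- matrix(v, g$nlat, g$nlon)
    gridded_field(g, vals, "mg C m-2 day-1", valid)
  }
  c0 <- 5
  ens <- ensemble_mean(list(a = mk(2 * c0), b = mk(0), c = mk(c0), d = mk(c0)))
  expect_true(all(abs(ens$mean_export$values - c0) < 1e-12))
  # identical members -> mean identical
  ens2 <- ensemble_mean(list(a = mk(3), b = mk(3)))
  expect_equal(ens2$mean_export$values, matrix(3, g$nlat, g$nlon))
  # one member invalid at a cell -> mean of the rest there
  valid <- matrix(TRUE, g$nlat, g$nlon); valid[1, 1] <- FALSE
  v <- matrix(9, g$nlat, g$nlon); v[1, 1] <- NA
  ens3 <- ensemble_mean(list(a = gridded_field(g, v, "mg C m-2 day-1", valid),
                             b = mk(3), c = mk(6)))
  expect_equal(ens3$mean_export$values[1, 1], 4.5)  # mean of 3, 6
  expect_equal(ens3$mean_export$values[2, 2], 6)    # mean of 9, 3, 6
  expect_equal(ens3$n_members[1, 1], 2L)
  # mean lies between member min and max everywhere
  set.seed(2)
  ms <- lapply(1:4, function(i) mk(matrix(rexp(g$nlat * g$nlon), g$nlat)))
  e4 <- ensemble_mean(ms)
  lo <- Reduce(pmin, lapply(ms, `[[`, "values"))
  hi <- Reduce(pmax, lapply(ms, `[[`, "values"))
  expect_true(all(e4$mean_export$values >= lo - 1e-12 &
                    e4$mean_export$values <= hi + 1e-12))
  # mismatched grids rejected
  other <- geo_grid(5)
  expect_error(ensemble_mean(list(mk(1),
    gridded_field(other, matrix(1, other$nlat, other$nlon), "mg C m-2 day-1"))),
    "mismatched")
})

test_that("global_range brackets the per-member totals", {
  g <- geo_grid(10); a <- cell_areas(g)
  mk <- function(v) gridded_field(g, matrix(v, g$nlat, g$nlon), "mg C m-2 day-1")
  ens <- ensemble_mean(list(mk(30), mk(60), mk(90), mk(60)))
  gr <- global_range(ens, a)
  # uniform members: totals scale linearly with the level
  unit <- global_integral(mk(1), a)
  expect_equal(as.numeric(gr), c(60, 30, 90) * unit, tolerance = 1e-12)
  expect_lte(gr[["total_min"]], gr[["total_max"]])
  # single member: min = max = mean
  gr1 <- global_range(ensemble_mean(list(mk(42))), a)
  expect_equal(gr1[["total_min"]], gr1[["total_max"]])
  expect_equal(gr1[["total_min"]], gr1[["total_mean"]], tolerance = 1e-12)
  # duplicating a member leaves the range unchanged
  gr2 <- global_range(ensemble_mean(list(mk(30), mk(90), mk(90))), a)
  expect_equal(gr2[["total_min"]], 30 * unit, tolerance = 1e-12)
  expect_equal(gr2[["total_max"]], 90 * unit, tolerance = 1e-12)
})

test_that("sequestered scales export by the fraction and its bounds", {
  s <- sequestered(7.6)
  expect_equal(unname(s), c(7.6 * 0.15, 7.6 * 0.05, 7.6 * 0.50))
  expect_equal(unname(s), c(1.14, 0.38, 3.80), tolerance = 1e-12)
  expect_equal(unname(sequestered(0)), c(0, 0, 0))
  expect_equal(sequestered(5, fraction = 1, bounds = c(1, 1))[["central"]], 5)
  expect_error(sequestered(5, bounds = c(0.5, 0.05)), "inverted")
  expect_error(sequestered(5, fraction = 0), "\\(0, 1\\]")
})
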