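#' Configuration for the synthetic world generator
#'
#' Parameters of the Gaussian-random-field world used to exercise and test
#' the pipeline without external data. Defaults describe a plausible 2-degree
#' annual-mean ocean: ~30% land, large-scale (6 degree) spatial
#' autocorrelation, a moderate positive coupling (rho = 0.6) between the
#' productivity driver and fishing (both depend on phytoplankton), doubled
#' intensity within one correlation length of the coast, satellite-style
#' export masking poleward of 70 degrees, and a 19-region partition
#' mirroring the FAO major fishing areas.
#'
#' @param resolution grid resolution, degrees (default 2).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param land_fraction fraction of the globe that is land, in \[0, 1).
#' @param correlation_length spatial autocorrelation scale, degrees (the
#'   sigma of the Gaussian smoothing kernel).
#' @param cross_correlation target log-space correlation rho in \[-1, 1\]
#'   between the shared productivity driver (log-NPP) and log-fishing.
#' @param coastal_boost multiplicative enhancement of NPP and fishing
#'   within one correlation length of land (default 2; 1 disables).
#' @param ice_mask_poleward_of latitude beyond which export drivers are
#'   invalid (ice/cloud analogue; default 70).
#' @param n_regions number of contiguous ocean regions (default 19).
#' @param sst_mean,sst_sd SST distribution, degC (a cosine-latitude gradient
#'   blended with smooth noise, so temperature declines poleward).
#' @param npp_log_mean,npp_log_sd log-NPP distribution (NPP is log-normal,
#'   mg C m-2 day-1).
#' @param fish_log_mean,fish_log_sd log-fishing distribution (h km-2 yr-1).
#' @param fishing_floor intensities below this are recorded as exact zeros
#'   (vessel-tracking absence = genuinely unfished), h km-2 yr-1.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(resolution = 2, seed = 1L,
                         land_fraction = 0.30,
                         correlation_length = 6,
                         cross_correlation = 0.6,
                         coastal_boost = 2,
                         ice_mask_poleward_of = 70,
                         n_regions = 19L,
                         sst_mean = 14, sst_sd = 9,
                         npp_log_mean = log(400), npp_log_sd = 0.7,
                         fish_log_mean = log(0.3), fish_log_sd = 1.2,
                         fishing_floor = 0.01) {
  stopifnot(land_fraction >= 0, land_fraction < 1,
            cross_correlation >= -1, cross_correlation <= 1,
            correlation_length > 0, coastal_boost > 0,
            ice_mask_poleward_of > 0, ice_mask_poleward_of <= 90,
            n_regions >= 1)
  structure(list(resolution = resolution, seed = as.integer(seed),
                 land_fraction = land_fraction,
                 correlation_length = correlation_length,
                 cross_correlation = cross_correlation,
                 coastal_boost = coastal_boost,
                 ice_mask_poleward_of = ice_mask_poleward_of,
                 n_regions = as.integer(n_regions),
                 sst_mean = sst_mean, sst_sd = sst_sd,
                 npp_log_mean = npp_log_mean, npp_log_sd = npp_log_sd,
                 fish_log_mean = fish_log_mean, fish_log_sd = fish_log_sd,
                 fishing_floor = fishing_floor),
            class = "synth_config")
}

# Separable Gaussian smoothing, kernel truncated at +/-3 sigma; circular in
# longitude, renormalized (truncated) at the poles.
smooth_gauss <- function(mat, sigma_cells) {
  if (sigma_cells <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_cells))
  k <- exp(-((-r:r)^2) / (2 * sigma_cells^2))
  k <- k / sum(k)
  nlat <- nrow(mat); nlon <- ncol(mat)
  # latitude pass (truncate + renormalize at edges)
  out <- matrix(0, nlat, nlon); wt <- numeric(nlat)
  for (d in -r:r) {
    i_dst <- max(1L, 1L - d):min(nlat, nlat - d)
    i_src <- i_dst + d
    w <- k[d + r + 1L]
    out[i_dst, ] <- out[i_dst, ] + w * mat[i_src, ]
    wt[i_dst] <- wt[i_dst] + w
  }
  out <- out / wt
  # longitude pass (circular)
  res <- matrix(0, nlat, nlon)
  for (d in -r:r) {
    j_src <- ((seq_len(nlon) - 1L + d) %% nlon) + 1L
    res <- res + k[d + r + 1L] * out[, j_src]
  }
  res
}

# standardized smoothed white-noise field
smooth_noise <- function(nlat, nlon, sigma_cells) {
  z <- smooth_gauss(matrix(stats::rnorm(nlat * nlon), nlat, nlon), sigma_cells)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic world
#'
#' Builds spatially autocorrelated, positive-valued SST / NPP / fishing
#' fields with the statistical structure the overlap analysis assumes:
#'
#' * smoothed Gaussian random fields at the configured correlation length;
#' * land as thresholded smooth noise (irregular coastlines);
#' * log-normal NPP and fishing; log-fishing is constructed as
#'   `rho * Z + sqrt(1 - rho^2) * W` against the standardized log-NPP
#'   driver `Z`, so the configured cross-correlation is the population
#'   log-space correlation;
#' * NPP and fishing multiplied by `coastal_boost` within one correlation
#'   length of land;
#' * export drivers invalid poleward of the ice line; fishing is valid over
#'   all ocean with sub-floor intensities recorded as true zeros;
#' * a model-derived export member (a perturbed smooth export ratio times
#'   NPP) for the pass-through slot of the ensemble.
#'
#' Identical config (including its seed) reproduces bit-identical output.
#'
#' @param config a [synth_config()].
#' @return List: `inputs` ([export_inputs()] with `sst`, `npp`, `zeu`,
#'   `model_export`), `fishing` ([gridded_field()]), `ocean` (logical
#'   matrix, TRUE = ocean), `coastal` (logical matrix, ocean cells within
#'   one correlation length of land), `grid`, `config`.
#' @export
gen_fields <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  grid <- geo_grid(config$resolution)
  nlat <- grid$nlat; nlon <- grid$nlon
  sig <- config$correlation_length / config$resolution

  # land: thresholded smooth noise
  L <- smooth_noise(nlat, nlon, sig)
  land <- L < stats::quantile(L, config$land_fraction)
  ocean <- !land
  if (!any(ocean)) stop("land_fraction leaves no ocean cells")

  # coastal band: ocean cells within one correlation length of land
  r_cells <- max(1L, round(sig))
  near <- land
  dil8 <- function(m) {  # 8-neighbour (Chebyshev) dilation
    up <- rbind(m[-1L, , drop = FALSE], m[nlat, , drop = FALSE])
    dn <- rbind(m[1L, , drop = FALSE], m[-nlat, , drop = FALSE])
    v <- m | up | dn
    v | v[, c(2:nlon, 1L), drop = FALSE] | v[, c(nlon, 1:(nlon - 1L)), drop = FALSE]
  }
  for (step in seq_len(r_cells)) near <- dil8(near)
  coastal <- near & ocean

  # drivers
  Z <- smooth_noise(nlat, nlon, sig)                    # shared productivity driver
  W <- smooth_noise(nlat, nlon, sig)                    # independent fishing noise
  S <- smooth_noise(nlat, nlon, sig)                    # SST anomaly
  latgrad <- matrix(cos(grid$lat_centers * pi / 180), nlat, nlon)
  latgrad <- (latgrad - mean(latgrad)) / stats::sd(latgrad)
  sst_z <- (0.85 * latgrad + 0.5 * S)
  sst_z <- (sst_z - mean(sst_z)) / stats::sd(sst_z)
  sst <- config$sst_mean + config$sst_sd * sst_z

  rho <- config$cross_correlation
  log_npp <- config$npp_log_mean + config$npp_log_sd * Z
  log_fish <- config$fish_log_mean +
    config$fish_log_sd * (rho * Z + sqrt(1 - rho^2) * W)
  npp <- exp(log_npp)
  fish <- exp(log_fish)

  boost <- matrix(1, nlat, nlon)
  boost[coastal] <- config$coastal_boost
  npp <- npp * boost
  fish <- fish * boost
  fish[fish < config$fishing_floor] <- 0

  ice <- abs(matrix(grid$lat_centers, nlat, nlon)) >= config$ice_mask_poleward_of
  export_valid <- ocean & !ice

  zeu <- 45 + 30 * stats::plogis(-Z)  # deeper euphotic layer where oligotrophic
  M <- smooth_noise(nlat, nlon, sig)
  model_ratio <- pmin(pmax(0.15 + 0.06 * M, 0.02), 0.8)
  model_export <- model_ratio * npp

  blank <- function(v, ok) { v[!ok] <- NA_real_; v }
  inputs <- export_inputs(
    sst = gridded_field(grid, blank(sst, export_valid), "degC", export_valid),
    npp = gridded_field(grid, blank(npp, export_valid), "mg C m-2 day-1", export_valid),
    zeu = gridded_field(grid, blank(zeu, export_valid), "m", export_valid),
    model_export = gridded_field(grid, blank(model_export, export_valid),
                                 "mg C m-2 day-1", export_valid)
  )
  fishing <- gridded_field(grid, blank(fish, ocean), "h km-2 yr-1", ocean)
  list(inputs = inputs, fishing = fishing, ocean = ocean, coastal = coastal,
       grid = grid, config = config)
}

#' Generate a contiguous region partition of the ocean
#'
#' Partitions ocean cells into `n_regions` regions by nearest seed point in
#' great-circle distance (spherical Voronoi restricted to the ocean). Seed
#' points are drawn from the ocean cells, so every region contains at least
#' its own seed cell.
#'
#' @param grid a [geo_grid()].
#' @param ocean logical matrix, TRUE for ocean cells.
#' @param n_regions number of regions (<= number of ocean cells).
#' @param seed RNG seed.
#' @return A [region_mask()] with codes `1..n_regions`.
#' @export
gen_regions <- function(grid, ocean, n_regions, seed = 1L) {
  check_grid(grid)
  oc <- which(ocean)
  if (n_regions > length(oc))
    stop("n_regions exceeds the number of ocean cells")
  set.seed(seed)
  seeds <- sample(oc, n_regions)
  lat <- matrix(grid$lat_centers, grid$nlat, grid$nlon)[oc] * pi / 180
  lon <- matrix(grid$lon_centers, grid$nlat, grid$nlon, byrow = TRUE)[oc] * pi / 180
  si <- match(seeds, oc)
  # great-circle (cosine of central angle); assign to nearest seed
  best <- rep(1L, length(oc)); bestcos <- rep(-2, length(oc))
  for (s in seq_len(n_regions)) {
    cosd <- sin(lat) * sin(lat[si[s]]) +
      cos(lat) * cos(lat[si[s]]) * cos(lon - lon[si[s]])
    upd <- cosd > bestcos
    best[upd] <- s
    bestcos[upd] <- cosd[upd]
  }
  id <- matrix(0L, grid$nlat, grid$nlon)
  id[oc] <- best
  region_mask(grid, id, data.frame(code = seq_len(n_regions),
                                   name = paste("Region", seq_len(n_regions))))
}

#' Generate synthetic catch records
#'
#' Draws per-region catch tonnage split across the FAO-style gear and group
#' vocabularies by a Dirichlet allocation. Low `concentration` produces one
#' dominant category per region (like the single-gear polar fisheries);
#' high values approach uniform shares.
#'
#' @param regions a [region_mask()] (its codes name the regions) or a
#'   vector of region codes.
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration parameter (default 0.5).
#' @param gears,groups category vocabularies.
#' @return data.frame of catch records: `region`, `gear`, `group`, `tonnes`.
#' @export
gen_catch <- function(regions, seed = 1L, concentration = 0.5,
                      gears = c("T", "PS", "D", "SG", "LL", "UG"),
                      groups = c("GF", "SP", "LP", "DF", "UF", "PC", "BC",
                                 "UC", "UM", "B", "S")) {
  codes <- if (inherits(regions, "region_mask")) regions$codes$code else regions
  if (!length(codes)) stop("gen_catch: no regions")
  set.seed(seed)
  rdirichlet <- function(k, a) {
    g <- stats::rgamma(k, shape = a)
    if (sum(g) <= 0) { g <- numeric(k); g[sample.int(k, 1L)] <- 1 }
    g / sum(g)
  }
  out <- lapply(codes, function(code) {
    total <- exp(stats::rnorm(1L, mean = log(5e5), sd = 1))
    gs <- rdirichlet(length(gears), concentration)
    hs <- rdirichlet(length(groups), concentration)
    tons <- total * outer(gs, hs)
    data.frame(region = code,
               gear = rep(gears, times = length(groups)),
               group = rep(groups, each = length(gears)),
               tonnes = as.vector(tons))
  })
  do.call(rbind, out)
}
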