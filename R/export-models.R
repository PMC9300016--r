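#' Export-ratio algorithm registry
#'
#' Empirical export-ratio (e-ratio) parameterizations map sea-surface
#' temperature (SST, degrees C), net primary production (NPP, mg C m^-2
#' day^-1) and optionally euphotic depth (Z_eu, m) to the fraction of NPP
#' exported out of the upper ocean. Three classical parameterizations are
#' registered by default:
#'
#' * `henson`: \eqn{0.23 e^{-0.08\,SST}} — temperature-only decay.
#' * `laws`: \eqn{0.04756\,(0.78 - 0.43\,SST/30)\,NPP^{0.307}}; negative
#'   ratios at extreme SST are clipped to 0.
#' * `dunne`: \eqn{-0.0101\,SST + 0.0582\ln(NPP/Z_{eu}) + 0.419}, clipped to
#'   \[0.04, 0.72\]; at NPP = 0 the ratio is set to the lower clip (the
#'   export member is 0 regardless).
#'
#' A fourth ensemble member, `model`, is a model-derived export field passed
#' through unchanged (no ratio). All ratios are clipped to \[0, 1\].
#' Alternative parameterizations can be added with
#' `register_export_algorithm()`; the registry is data, not fixed logic.
#'
#' @param algorithm registry name (case-insensitive).
#' @param sst,npp,zeu numeric vectors (recycled to a common length).
#' @return `e_ratio()` returns a numeric vector of ratios in \[0, 1\].
#' @examples
#' e_ratio("henson", sst = 0)             # 0.23
#' e_ratio("dunne", sst = 20, npp = 100, zeu = 100)  # 0.217
#' @export
e_ratio <- function(algorithm, sst = NULL, npp = NULL, zeu = NULL) {
  alg <- get_export_algorithm(algorithm)
  alg$fn(sst = sst, npp = npp, zeu = zeu)
}

.export_registry <- new.env(parent = emptyenv())

#' @rdname e_ratio
#' @param name registry name for the new algorithm.
#' @param fn function of `(sst, npp, zeu)` returning ratios (clipped by the
#'   caller's contract to \[0, 1\]).
#' @param needs character vector of required drivers among
#'   `c("sst", "npp", "zeu")`.
#' @export
register_export_algorithm <- function(name, fn, needs = character()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(tolower(name), list(fn = fn, needs = needs), envir = .export_registry)
  invisible(name)
}

get_export_algorithm <- function(name) {
  key <- tolower(name)
  if (!exists(key, envir = .export_registry, inherits = FALSE))
    stop(sprintf("unknown export algorithm '%s'; registered: %s", name,
                 paste(sort(ls(.export_registry)), collapse = ", ")))
  get(key, envir = .export_registry, inherits = FALSE)
}

.need <- function(x, alg, driver) {
  if (is.null(x))
    stop(sprintf("algorithm '%s' requires the '%s' driver", alg, driver))
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

local({
  register_export_algorithm("henson", function(sst, npp, zeu) {
    sst <- .need(sst, "henson", "sst")
    clip01(0.23 * exp(-0.08 * sst))
  }, needs = "sst")

  register_export_algorithm("laws", function(sst, npp, zeu) {
    sst <- .need(sst, "laws", "sst")
    npp <- .need(npp, "laws", "npp")
    clip01(0.04756 * (0.78 - 0.43 * sst / 30) * npp^0.307)
  }, needs = c("sst", "npp"))

  register_export_algorithm("dunne", function(sst, npp, zeu) {
    sst <- .need(sst, "dunne", "sst")
    npp <- .need(npp, "dunne", "npp")
    zeu <- .need(zeu, "dunne", "zeu")
    ratio <- ifelse(npp > 0,
                    -0.0101 * sst + 0.0582 * log(npp / zeu) + 0.419,
                    0.04)
    clip01(pmin(pmax(ratio, 0.04), 0.72))
  }, needs = c("sst", "npp", "zeu"))
})

#' Bundle of export-model driver fields
#'
#' Collects the gridded drivers on one shared grid: SST (degC), NPP
#' (mg C m-2 day-1), optional euphotic depth Z_eu (m) and an optional
#' model-derived export field used as the pass-through ensemble member.
#'
#' @param sst,npp [gridded_field()]s on one grid.
#' @param zeu,model_export optional [gridded_field()]s on the same grid.
#' @return Object of class `export_inputs`.
#' @export
export_inputs <- function(sst, npp, zeu = NULL, model_export = NULL) {
  stopifnot(inherits(sst, "gridded_field"), inherits(npp, "gridded_field"))
  for (f in Filter(Negate(is.null), list(npp, zeu, model_export)))
    if (!same_grid(sst$grid, f$grid))
      stop("all export input fields must share one grid")
  structure(list(sst = sst, npp = npp, zeu = zeu, model_export = model_export),
            class = "export_inputs")
}

#' Compute one export member field
#'
#' Applies a registered e-ratio algorithm cell-wise and multiplies by NPP to
#' obtain an export field (mg C m-2 day-1). The `model` member returns the
#' pass-through model export field. A cell is valid only where all required
#' drivers are valid.
#'
#' @param inputs an [export_inputs()] bundle.
#' @param algorithm registry name or `"model"`.
#' @return A [gridded_field()] of export, units `"mg C m-2 day-1"`.
#' @export
export_member <- function(inputs, algorithm) {
  stopifnot(inherits(inputs, "export_inputs"))
  if (tolower(algorithm) == "model") {
    if (is.null(inputs$model_export))
      stop("member 'model' requires a model_export field in the inputs")
    return(inputs$model_export)
  }
  alg <- get_export_algorithm(algorithm)
  need <- alg$needs
  if ("zeu" %in% need && is.null(inputs$zeu))
    stop(sprintf("algorithm '%s' requires the 'zeu' driver", algorithm))
  fields <- list(sst = inputs$sst, npp = inputs$npp, zeu = inputs$zeu)
  valid <- Reduce(`&`, lapply(fields[need], function(f) f$valid))
  getv <- function(nm) if (nm %in% need) fields[[nm]]$values else NULL
  ratio <- alg$fn(sst = getv("sst"), npp = getv("npp"), zeu = getv("zeu"))
  out <- ratio * inputs$npp$values
  out[!valid] <- NA_real_
  out[valid & !is.finite(out)] <- NA_real_
  valid <- valid & !is.na(out)
  gridded_field(inputs$sst$grid, out, "mg C m-2 day-1", valid)
}

#' Ensemble of export fields and their cell-wise mean
#'
#' The ensemble mean is the arithmetic mean over the members valid at each
#' cell; a cell is valid in the mean when at least one member is valid.
#' Cells covered by fewer than the full member count are flagged in the
#' `n_members` matrix.
#'
#' @param members named list of export [gridded_field()]s on one grid.
#' @return Object of class `export_ensemble`: `members`, `mean_export`,
#'   `member_names`, `n_members`.
#' @export
ensemble_mean <- function(members) {
  if (!length(members)) stop("ensemble requires at least one member")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- paste0("member", seq_along(members))
  g <- members[[1L]]$grid
  for (m in members) {
    stopifnot(inherits(m, "gridded_field"))
    if (!same_grid(g, m$grid)) stop("ensemble members are on mismatched grids")
  }
  vsum <- matrix(0, g$nlat, g$nlon)
  n <- matrix(0L, g$nlat, g$nlon)
  for (m in members) {
    v <- m$values; v[!m$valid] <- 0
    vsum <- vsum + v
    n <- n + m$valid
  }
  mean_v <- vsum / n
  valid <- n > 0L
  mean_v[!valid] <- NA_real_
  structure(list(
    members = members,
    mean_export = gridded_field(g, mean_v, "mg C m-2 day-1", valid),
    member_names = names(members),
    n_members = n
  ), class = "export_ensemble")
}

#' Build the default four-member export ensemble
#'
#' Convenience wrapper: computes the `henson`, `laws` and `dunne` members
#' (the last only when Z_eu is supplied) plus the `model` pass-through when
#' present, then forms the ensemble mean.
#'
#' @param inputs an [export_inputs()] bundle.
#' @param algorithms member names to compute; defaults to every member the
#'   supplied drivers support.
#' @return An `export_ensemble`.
#' @export
export_ensemble_from_inputs <- function(inputs, algorithms = NULL) {
  stopifnot(inherits(inputs, "export_inputs"))
  if (is.null(algorithms)) {
    algorithms <- c("henson", "laws")
    if (!is.null(inputs$zeu)) algorithms <- c(algorithms, "dunne")
    if (!is.null(inputs$model_export)) algorithms <- c(algorithms, "model")
  }
  members <- lapply(algorithms, function(a) export_member(inputs, a))
  names(members) <- algorithms
  ensemble_mean(members)
}

#' Global export total with per-member range
#'
#' Integrates the ensemble-mean export field and every member field to
#' annual global totals; the range is the min/max over members.
#'
#' @param ensemble an `export_ensemble`.
#' @param areas matching [cell_areas()].
#' @return Named vector `c(total_mean, total_min, total_max)` in Gt C yr^-1,
#'   with per-member totals in attribute `"members"`.
#' @export
global_range <- function(ensemble, areas) {
  stopifnot(inherits(ensemble, "export_ensemble"))
  per <- vapply(ensemble$members, global_integral, numeric(1L), areas = areas)
  out <- c(total_mean = global_integral(ensemble$mean_export, areas),
           total_min = min(per), total_max = max(per))
  attr(out, "members") <- per
  out
}

#' Sequestered fraction of exported carbon
#'
#' Of the carbon exported from the surface ocean, only a fraction (central
#' estimate ~15%, temperature-dependent range 5%-50%) is locked away in deep
#' water masses or sediments on centennial timescales. This scales a global
#' export total to a sequestration estimate.
#'
#' @param total_export global export, Gt C yr^-1.
#' @param fraction central sequestered fraction (default 0.15).
#' @param bounds length-2 low/high fractions (default `c(0.05, 0.50)`).
#' @return Named vector `c(central, low, high)` in Gt C yr^-1.
#' @examples
#' sequestered(7.6)  # ~1.1 Gt C yr^-1 central
#' @export
sequestered <- function(total_export, fraction = 0.15, bounds = c(0.05, 0.50)) {
  stopifnot(is.numeric(total_export), length(bounds) == 2L)
  if (fraction <= 0 || fraction > 1 || any(bounds <= 0) || any(bounds > 1))
    stop("fraction and bounds must lie in (0, 1]")
  if (bounds[1L] > bounds[2L]) stop("bounds are inverted")
  c(central = total_export * fraction,
    low = total_export * bounds[1L],
    high = total_export * bounds[2L])
}
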