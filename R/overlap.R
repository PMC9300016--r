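#' Quantile threshold over valid cells
#'
#' Linear-interpolation sample quantile (position `1 + (n-1) q` on the
#' sorted values, i.e. the type-7 rule), computed unweighted over the
#' supplied values. Deterministic under permutation of input order.
#'
#' @param values numeric vector (NAs removed); must be non-empty.
#' @param q quantile in (0, 1); default 0.75, the upper quartile.
#' @param weights optional positive weights (e.g. cell areas) for an
#'   area-weighted threshold: linear interpolation of the value against the
#'   centered cumulative normalized weight. Default `NULL` = unweighted.
#' @return The threshold value.
#' @examples
#' quantile_threshold(1:8)         # 6.25
#' quantile_threshold(c(0, 100))   # 75
#' @export
quantile_threshold <- function(values, q = 0.75, weights = NULL) {
  values <- as.numeric(values)
  keep <- !is.na(values)
  values <- values[keep]
  if (!length(values)) stop("quantile_threshold: no valid values")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("`q` must be a single number in (0, 1)")
  if (is.null(weights))
    return(unname(stats::quantile(values, probs = q, type = 7)))
  weights <- as.numeric(weights)[keep]
  if (length(weights) != length(values) || any(weights <= 0))
    stop("`weights` must be positive and match `values`")
  o <- order(values)
  v <- values[o]; w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2  # centered cumulative weight
  if (q <= p[1L]) return(v[1L])
  if (q >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = q, ties = "ordered")$y
}

#' Dual upper-quartile overlap mask
#'
#' The core overlap statistic: cells where POC export and fishing intensity
#' are both strictly above their respective quantile thresholds. The
#' analysis domain is the set of cells valid in the export field (fishing
#' zeros are genuine observations); both thresholds are computed
#' independently over that single domain, so the area, export and effort
#' fractions are commensurable. Ties at a threshold are excluded (strict
#' `>`), which is deterministic and conservative.
#'
#' @param export a [gridded_field()] of POC export (mg C m-2 day-1).
#' @param fishing a [gridded_field()] of fishing intensity (h km-2 yr-1) on
#'   the same grid.
#' @param q quantile defining "high" for both services (default 0.75).
#' @param areas optional [cell_areas()]; when supplied the fractions are
#'   filled in via [overlap_fractions()].
#' @param weighted_thresholds if `TRUE`, thresholds are area-weighted
#'   quantiles (requires `areas`). Default `FALSE`: each valid cell is one
#'   observation, while reported fractions are always area-weighted.
#' @return Object of class `overlap_result`: `q_export`, `q_fishing`,
#'   `mask` (logical matrix), `domain`, `q`, and (when `areas` given)
#'   `area_fraction`, `export_fraction`, `effort_fraction`.
#' @export
overlap_mask <- function(export, fishing, q = 0.75, areas = NULL,
                         weighted_thresholds = FALSE) {
  stopifnot(inherits(export, "gridded_field"), inherits(fishing, "gridded_field"))
  if (!same_grid(export$grid, fishing$grid))
    stop("export and fishing fields are on different grids")
  domain <- export$valid & fishing$valid
  if (!any(domain))
    stop("export and fishing have disjoint validity domains")
  wts <- NULL
  if (weighted_thresholds) {
    if (is.null(areas)) stop("weighted thresholds require `areas`")
    wts <- areas$area[domain]
  }
  qe <- quantile_threshold(export$values[domain], q, weights = wts)
  qf <- quantile_threshold(fishing$values[domain], q, weights = wts)
  mask <- domain & export$values > qe & fishing$values > qf
  mask[is.na(mask)] <- FALSE
  res <- structure(list(q_export = qe, q_fishing = qf, q = q,
                        mask = mask, domain = domain,
                        grid = export$grid), class = "overlap_result")
  if (!is.null(areas)) {
    fr <- overlap_fractions(res, export, fishing, areas)
    res[names(fr)] <- fr
  }
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: q = %.2f, thresholds E > %.4g, F > %.4g, %d/%d cells\n",
              x$q, x$q_export, x$q_fishing, sum(x$mask), sum(x$domain)))
  if (!is.null(x$area_fraction))
    cat(sprintf("  fractions: area %.3f, export %.3f, effort %.3f\n",
                x$area_fraction, x$export_fraction, x$effort_fraction))
  invisible(x)
}

#' Area, export and effort fractions inside the overlap zone
#'
#' Area-weighted shares of the analysis domain captured by the overlap
#' mask: ocean surface area, total carbon export (E x area), and total
#' fishing effort (F x area, i.e. hours).
#'
#' @param result an [overlap_mask()] result.
#' @param export,fishing the fields used to build the mask.
#' @param areas matching [cell_areas()].
#' @return Named list `area_fraction`, `export_fraction`, `effort_fraction`,
#'   each in \[0, 1\].
#' @export
overlap_fractions <- function(result, export, fishing, areas) {
  stopifnot(inherits(result, "overlap_result"), inherits(areas, "cell_areas"))
  d <- result$domain; m <- result$mask
  a <- areas$area
  tot_a <- sum(a[d])
  tot_e <- sum(export$values[d] * a[d])
  tot_f <- sum(fishing$values[d] * a[d])
  if (tot_a <= 0 || tot_e <= 0 || tot_f <= 0)
    stop("overlap_fractions: a domain total is zero; fractions undefined")
  list(area_fraction = sum(a[m]) / tot_a,
       export_fraction = sum(export$values[m] * a[m]) / tot_e,
       effort_fraction = sum(fishing$values[m] * a[m]) / tot_f)
}

#' Per-algorithm sensitivity of the overlap statistics
#'
#' Recomputes the overlap mask and fractions for each ensemble member in
#' turn (each member paired with the same fishing field) and reports the
#' min-max envelope across members, the sensitivity range quoted alongside
#' the headline fractions.
#'
#' @param ensemble an `export_ensemble`.
#' @param fishing fishing-intensity [gridded_field()].
#' @param areas matching [cell_areas()].
#' @param q quantile (default 0.75).
#' @return Object of class `overlap_sensitivity`: data.frame `per_member`
#'   (member, area/export/effort fraction) and matrix `range` with `min`
#'   and `max` rows.
#' @export
overlap_sensitivity <- function(ensemble, fishing, areas, q = 0.75) {
  stopifnot(inherits(ensemble, "export_ensemble"))
  per <- lapply(ensemble$members, function(m) {
    r <- overlap_mask(m, fishing, q = q, areas = areas)
    c(area_fraction = r$area_fraction,
      export_fraction = r$export_fraction,
      effort_fraction = r$effort_fraction)
  })
  tab <- do.call(rbind, per)
  structure(list(
    per_member = data.frame(member = rownames(tab), tab, row.names = NULL),
    range = rbind(min = apply(tab, 2L, min), max = apply(tab, 2L, max))
  ), class = "overlap_sensitivity")
}

#' Full overlap analysis for an ensemble
#'
#' Headline numbers of the analysis: the overlap of the ensemble-mean
#' export field with fishing, plus the per-member sensitivity envelope.
#'
#' @inheritParams overlap_sensitivity
#' @return List with `overlap` (an `overlap_result` for the ensemble mean)
#'   and `sensitivity` (an `overlap_sensitivity`).
#' @export
overlap_analysis <- function(ensemble, fishing, areas, q = 0.75) {
  list(overlap = overlap_mask(ensemble$mean_export, fishing, q = q, areas = areas),
       sensitivity = overlap_sensitivity(ensemble, fishing, areas, q = q))
}
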