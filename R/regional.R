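#' Gridded region partition
#'
#' Assigns every grid cell an integer region label (0 = no region), with a
#' code table naming each region — the gridded analogue of the 19 FAO major
#' fishing areas (codes 18..88) used for catch statistics. Official FAO
#' polygons are not bundled; users rasterize boundaries themselves or use
#' [gen_regions()] for synthetic partitions.
#'
#' @param grid a [geo_grid()].
#' @param region_id integer matrix `nlat x nlon`; 0 means unassigned.
#' @param codes data.frame with columns `code` (the labels used in
#'   `region_id`) and `name`.
#' @return Object of class `region_mask`.
#' @export
region_mask <- function(grid, region_id, codes) {
  check_grid(grid)
  region_id <- as.matrix(region_id)
  if (!all(dim(region_id) == c(grid$nlat, grid$nlon)))
    stop("`region_id` must be an nlat x nlon matrix")
  if (!all(c("code", "name") %in% names(codes)))
    stop("`codes` must have columns code and name")
  used <- setdiff(unique(as.vector(region_id)), 0L)
  if (!all(used %in% codes$code))
    stop("region ids present in the grid are missing from the code table")
  structure(list(grid = grid, region_id = region_id,
                 codes = codes[order(codes$code), , drop = FALSE]),
            class = "region_mask")
}

#' Per-region area-weighted means
#'
#' For each region, the area-weighted mean of the field over its valid
#' cells, `sum(value * area) / sum(area)`. Regions with no valid cells get
#' `NA` and are flagged absent.
#'
#' @param field a [gridded_field()].
#' @param mask a [region_mask()] on the same grid.
#' @param areas matching [cell_areas()].
#' @return data.frame with columns `code`, `name`, `mean`, `area_km2`,
#'   `n_valid`.
#' @export
region_means <- function(field, mask, areas) {
  stopifnot(inherits(field, "gridded_field"), inherits(mask, "region_mask"),
            inherits(areas, "cell_areas"))
  if (!same_grid(field$grid, mask$grid))
    stop("field and region mask are on different grids")
  if (!nrow(mask$codes)) stop("region mask has an empty region set")
  out <- mask$codes
  out$mean <- NA_real_; out$area_km2 <- 0; out$n_valid <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- mask$region_id == out$code[i] & field$valid
    out$n_valid[i] <- sum(sel)
    if (out$n_valid[i] > 0L) {
      a <- areas$area[sel]
      out$area_km2[i] <- sum(a)
      out$mean[i] <- sum(field$values[sel] * a) / sum(a)
    }
  }
  out
}

#' Descending dense-style ranks (1 = highest)
#'
#' Ranks region values with 1 for the largest; tied values share the
#' minimum rank of the tied block.
#'
#' @param values numeric vector.
#' @return Integer ranks.
#' @examples
#' rank_regions(c(5, 3, 3, 1))  # 1 2 2 4
#' @export
rank_regions <- function(values) {
  if (!length(values)) stop("rank_regions: no values")
  as.integer(rank(-values, ties.method = "min", na.last = "keep"))
}

#' Flag anomalously high regions (mean + k * SD rule)
#'
#' A region is flagged when its value exceeds the across-region mean plus
#' `k` sample standard deviations (n-1 denominator). With the default
#' k = 2 this is the rule that singles out the Mediterranean's enclosed-sea
#' fishing intensity from the FAO-area fishing column.
#'
#' @param values numeric vector, length >= 3.
#' @param k number of standard deviations (default 2).
#' @return List `mean`, `sd`, `threshold`, `flagged` (logical vector).
#' @export
flag_outliers <- function(values, k = 2) {
  values <- as.numeric(values)
  if (sum(!is.na(values)) < 3L)
    stop("flag_outliers requires at least 3 values")
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  thr <- m + k * s
  list(mean = m, sd = s, threshold = thr,
       flagged = !is.na(values) & values > thr)
}

#' Pearson correlation with region exclusions
#'
#' Pearson r between per-region export and fishing intensity after removing
#' an exclusion set (typically the outliers from [flag_outliers()]); the
#' two-sided p-value comes from the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors (per-region annual means).
#' @param exclude logical vector (or integer indices) of pairs to drop.
#' @return List `r`, `p`, `n` (retained pairs), `excluded` (count dropped).
#' @export
corr_excluding <- function(x, y, exclude = NULL) {
  stopifnot(length(x) == length(y))
  drop <- rep(FALSE, length(x))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) drop <- exclude
    else drop[exclude] <- TRUE
  }
  keep <- !drop & !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) stop("corr_excluding requires at least 3 retained pairs")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    stop("corr_excluding: zero variance in a retained vector")
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep),
       excluded = sum(drop))
}

#' Regional summary: means, ranks, outliers, correlation
#'
#' Runs the full FAO-area level analysis on a per-region table: ranks both
#' services (1 = highest), applies the mean + k SD outlier rule to fishing
#' intensity, and computes the Pearson correlation between export and
#' fishing with the flagged regions excluded.
#'
#' @param regions data.frame with columns `code`, `name`, `mean_export`,
#'   `mean_fishing` (e.g. from two [region_means()] calls, or the packaged
#'   [fao_area_summary()] fixture).
#' @param k outlier rule multiplier (default 2).
#' @return Object of class `region_summary`: the input table with
#'   `export_rank`, `fishing_rank`, `outlier` columns added, plus scalars
#'   `fishing_mean`, `fishing_sd`, `r`, `p`, and `excluded_codes`.
#' @export
region_summary <- function(regions, k = 2) {
  need <- c("code", "name", "mean_export", "mean_fishing")
  if (!all(need %in% names(regions)))
    stop("`regions` must have columns ", paste(need, collapse = ", "))
  tab <- regions[order(regions$code), , drop = FALSE]
  tab$export_rank <- rank_regions(tab$mean_export)
  tab$fishing_rank <- rank_regions(tab$mean_fishing)
  fl <- flag_outliers(tab$mean_fishing, k = k)
  tab$outlier <- fl$flagged
  ct <- corr_excluding(tab$mean_export, tab$mean_fishing, exclude = fl$flagged)
  structure(list(table = tab,
                 fishing_mean = fl$mean, fishing_sd = fl$sd,
                 r = ct$r, p = ct$p, n_retained = ct$n,
                 excluded_codes = tab$code[fl$flagged]),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("region_summary: %d regions; fishing mean %.2f, SD %.2f h km-2\n",
              nrow(x$table), x$fishing_mean, x$fishing_sd))
  cat(sprintf("  excluded: %s; Pearson r = %.2f (p = %.3g, n = %d)\n",
              if (length(x$excluded_codes)) paste(x$excluded_codes, collapse = ", ")
              else "none", x$r, x$p, x$n_retained))
  invisible(x)
}

#' Table-style regional report
#'
#' One row per region (sorted by code): code, name, mean export (2 dp),
#' export rank, mean fishing (2 dp), fishing rank, % of global catch
#' (integer), dominant gear and dominant fished groups — the layout of the
#' standard per-FAO-area summary table. Rounding happens only here, at
#' presentation.
#'
#' @param summary a [region_summary()].
#' @param profiles optional list of [catch_profile()]s (one per region) to
#'   fill the catch columns.
#' @return data.frame report.
#' @export
table_report <- function(summary, profiles = NULL) {
  stopifnot(inherits(summary, "region_summary"))
  tab <- summary$table
  rep_tab <- data.frame(
    code = tab$code, name = tab$name,
    poc_export = round(tab$mean_export, 2), export_rank = tab$export_rank,
    fishing = round(tab$mean_fishing, 2), fishing_rank = tab$fishing_rank,
    catch_pct = NA_integer_, main_gear = NA_character_,
    main_groups = NA_character_
  )
  if (!is.null(profiles)) {
    idx <- match(rep_tab$code, sapply(profiles, function(p) p$region))
    fmt <- function(p) paste(sprintf("%s (%d)", p$category,
                                     as.integer(round(p$pct))), collapse = ", ")
    for (i in seq_len(nrow(rep_tab))) {
      if (is.na(idx[i])) next
      p <- profiles[[idx[i]]]
      rep_tab$catch_pct[i] <- as.integer(round(p$global_share))
      rep_tab$main_gear[i] <- fmt(p$dominant_gear)
      rep_tab$main_groups[i] <- fmt(p$dominant_groups)
    }
  }
  rep_tab[order(rep_tab$code), , drop = FALSE]
}

#' Published per-FAO-area summary fixture
#'
#' The packaged 19-row table of per-area annual means compiled in a
#' published global overlap analysis: POC export and rank, fishing
#' intensity and rank, % of global catch, and the dominant gear/group
#' strings (codes as in FAO capture-production data: T trawl, PS purse
#' seine, D dredge, SG set gillnet, LL longline, UG unknown gear; groups
#' GF groundfish, SP small pelagics, LP large pelagics, DF deep-water fish,
#' UF unspecified fish, PC/BC/UC pelagic/benthic/unspecified crustaceans,
#' UM molluscs, B bivalves, S squid).
#'
#' @return data.frame with one row per FAO major fishing area.
#' @export
fao_area_summary <- function() {
  path <- system.file("extdata", "fao_area_summary.csv", package = "fishsink",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Parse a composition string like "T (36), PS (32)"
#'
#' @param x character vector of composition strings.
#' @return List of data.frames with columns `category`, `pct`.
#' @export
parse_composition <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(category = character(), pct = numeric()))
    parts <- strsplit(s, ",\\s*")[[1L]]
    m <- regmatches(parts, regexec("^([A-Za-z]+)\\s*\\((\\d+)\\)$", parts))
    data.frame(category = vapply(m, `[`, character(1L), 2L),
               pct = as.numeric(vapply(m, `[`, character(1L), 3L)))
  })
}
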