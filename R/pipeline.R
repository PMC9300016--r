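#' Run the full overlap pipeline on a synthetic world
#'
#' End-to-end orchestration: generate (or accept) a world, build the
#' export-algorithm ensemble, compute the dual upper-quartile overlap with
#' per-algorithm sensitivity, aggregate both services to regions, summarize
#' catch composition, and write the report bundle: the overlap mask as a
#' CSV grid dump, a one-row fractions CSV (with ranges), the per-region
#' table-style CSV, global totals with sequestration, and a JSON run
#' manifest recording the seed, thresholds and exclusion decisions.
#' Identical config and seed give byte-identical CSV outputs.
#'
#' @param config a [synth_config()] describing the world.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and returns results only.
#' @param q overlap quantile (default 0.75).
#' @param k outlier-rule multiplier (default 2).
#' @param fraction,bounds sequestration fraction and range (see
#'   [sequestered()]).
#' @param world optional pre-generated [gen_fields()] world (the config is
#'   then only consulted for regions/catch seeds).
#' @return List: `overlap`, `sensitivity`, `totals` (global export
#'   mean/min/max + sequestration), `regional` (a [region_summary()]),
#'   `report` (the table-style data.frame), `manifest`.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL, q = 0.75,
                         k = 2, fraction = 0.15, bounds = c(0.05, 0.50)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  world <- stage("synthetic_data", gen_fields(config))
  areas <- cell_areas(world$grid)
  ens <- stage("export_models", export_ensemble_from_inputs(world$inputs))
  totals <- stage("export_models", {
    gr <- global_range(ens, areas)
    c(gr, sequestered(gr[["total_mean"]], fraction, bounds))
  })
  ov <- stage("overlap_analysis",
              overlap_analysis(ens, world$fishing, areas, q = q))
  regions <- stage("regional_stats",
                   gen_regions(world$grid, world$ocean, config$n_regions,
                               seed = config$seed))
  rm_e <- region_means(ens$mean_export, regions, areas)
  rm_f <- region_means(world$fishing, regions, areas)
  regional_tab <- data.frame(code = rm_e$code, name = rm_e$name,
                             mean_export = rm_e$mean, mean_fishing = rm_f$mean)
  regional_tab <- regional_tab[!is.na(regional_tab$mean_export) &
                                 !is.na(regional_tab$mean_fishing), ]
  summ <- stage("regional_stats", region_summary(regional_tab, k = k))
  records <- stage("catch_composition", gen_catch(regions, seed = config$seed))
  profiles <- lapply(summ$table$code, function(code)
    catch_profile(records, code))
  report <- table_report(summ, profiles)

  manifest <- list(
    seed = config$seed, resolution = config$resolution, quantile = q,
    outlier_k = k, sequestration_fraction = fraction,
    q_export = ov$overlap$q_export, q_fishing = ov$overlap$q_fishing,
    excluded_regions = summ$excluded_codes,
    fractions = ov$overlap[c("area_fraction", "export_fraction",
                             "effort_fraction")],
    totals = as.list(totals),
    package_version = as.character(utils::packageVersion("fishsink"))
  )
  res <- list(overlap = ov$overlap, sensitivity = ov$sensitivity,
              totals = totals, regional = summ, report = report,
              manifest = manifest, world = world)
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ov <- res$overlap
  mask_field <- gridded_field(ov$grid, ov$mask + 0, "overlap", ov$domain)
  write_field_csv(mask_field, file.path(out_dir, "overlap_mask.csv"))
  rng <- res$sensitivity$range
  fr <- data.frame(
    quantile = ov$q, q_export = ov$q_export, q_fishing = ov$q_fishing,
    area_fraction = ov$area_fraction, export_fraction = ov$export_fraction,
    effort_fraction = ov$effort_fraction,
    area_min = rng["min", "area_fraction"], area_max = rng["max", "area_fraction"],
    export_min = rng["min", "export_fraction"], export_max = rng["max", "export_fraction"],
    effort_min = rng["min", "effort_fraction"], effort_max = rng["max", "effort_fraction"]
  )
  utils::write.csv(fr, file.path(out_dir, "overlap_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report, file.path(out_dir, "regional_report.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(quantity = names(res$totals),
                              gt_c_yr = as.numeric(res$totals)),
                   file.path(out_dir, "global_totals.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Regional-only analysis from a per-area table
#'
#' Runs just the region-level analysis (ranks, outlier rule, correlation
#' with exclusions, table report) on a pre-aggregated per-region table such
#' as the packaged [fao_area_summary()] fixture — the desk-reproducible
#' level of the analysis, requiring no gridded inputs.
#'
#' @param regions data.frame with `code`, `name`, `mean_export`,
#'   `mean_fishing` (extra columns are ignored).
#' @param k outlier-rule multiplier (default 2).
#' @param out_dir optional output directory for the report CSV.
#' @return A [region_summary()].
#' @examples
#' tab <- fao_area_summary()
#' run_regional(data.frame(code = tab$area, name = tab$name,
#'                         mean_export = tab$poc_export,
#'                         mean_fishing = tab$fishing))
#' @export
run_regional <- function(regions, k = 2, out_dir = NULL) {
  summ <- region_summary(regions, k = k)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table_report(summ),
                     file.path(out_dir, "regional_report.csv"),
                     row.names = FALSE)
  }
  summ
}
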