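#' Catch shares by gear or fished group
#'
#' Percentage of a region's total catch tonnage per category, sorted
#' descending. Percentages are exact fractions times 100; rounding to
#' integer percent happens only in the report layer so the >=50% dominance
#' rule never suffers rounding artifacts.
#'
#' @param records data.frame of catch records with columns `region`, `gear`,
#'   `group`, `tonnes` (FAO capture-production layout; tonnes >= 0).
#' @param region region code to summarize.
#' @param by `"gear"` or `"group"`.
#' @return data.frame `category`, `pct`, descending by `pct` (ties by
#'   category code).
#' @export
catch_shares <- function(records, region, by = c("gear", "group")) {
  by <- match.arg(by)
  need <- c("region", "gear", "group", "tonnes")
  if (!all(need %in% names(records)))
    stop("`records` must have columns ", paste(need, collapse = ", "))
  if (any(records$tonnes < 0)) stop("tonnage must be non-negative")
  rows <- records[records$region == region, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("region '%s' not present in records", region))
  tot <- sum(rows$tonnes)
  if (tot <= 0) stop(sprintf("region '%s' has zero total tonnage", region))
  agg <- stats::aggregate(tonnes ~ cat, data.frame(cat = rows[[by]],
                                                   tonnes = rows$tonnes), sum)
  out <- data.frame(category = agg$cat, pct = 100 * agg$tonnes / tot)
  out[order(-out$pct, out$category), , drop = FALSE]
}

#' Dominant categories: minimal prefix reaching a cumulative share
#'
#' The shortest descending-share prefix whose cumulative share meets the
#' threshold (default 50% of catch). Ties in share are broken by category
#' code (lexicographic), so the selection is deterministic.
#'
#' @param shares data.frame `category`, `pct` as from [catch_shares()].
#' @param threshold cumulative share to reach, as a fraction (default 0.5).
#' @return The selected rows of `shares` (descending share order).
#' @export
dominant_categories <- function(shares, threshold = 0.5) {
  if (!nrow(shares)) stop("dominant_categories: empty share table")
  s <- shares[order(-shares$pct, shares$category), , drop = FALSE]
  cum <- cumsum(s$pct)
  k <- which(cum >= threshold * 100)[1L]
  if (is.na(k)) k <- nrow(s)  # shares short of threshold: report everything
  s[seq_len(k), , drop = FALSE]
}

#' Per-region share of the world catch
#'
#' @param records catch records data.frame (see [catch_shares()]).
#' @return data.frame `region`, `pct` with percentages of world tonnage.
#' @export
global_catch_share <- function(records) {
  if (!nrow(records)) stop("global_catch_share: no records")
  tot <- sum(records$tonnes)
  if (tot <= 0) stop("global_catch_share: zero world total")
  agg <- stats::aggregate(tonnes ~ region,
                          records[c("region", "tonnes")], sum)
  data.frame(region = agg$region, pct = 100 * agg$tonnes / tot)
}

#' Catch profile for one region
#'
#' Bundles the region's share of world catch with its dominant gear types
#' and dominant fished groups (each the minimal set cumulatively holding
#' >= `threshold` of the regional catch).
#'
#' @inheritParams catch_shares
#' @param threshold dominance threshold (default 0.5).
#' @return Object of class `catch_profile`: `region`, `global_share`,
#'   `dominant_gear`, `dominant_groups` (data.frames `category`, `pct`).
#' @export
catch_profile <- function(records, region, threshold = 0.5) {
  gshare <- global_catch_share(records)
  structure(list(
    region = region,
    global_share = gshare$pct[match(region, gshare$region)],
    dominant_gear = dominant_categories(catch_shares(records, region, "gear"),
                                        threshold),
    dominant_groups = dominant_categories(catch_shares(records, region, "group"),
                                          threshold)
  ), class = "catch_profile")
}

#' @export
print.catch_profile <- function(x, ...) {
  fmt <- function(p) paste(sprintf("%s (%.0f)", p$category, p$pct),
                           collapse = ", ")
  cat(sprintf("catch_profile region %s: %.1f%% of world catch\n",
              format(x$region), x$global_share))
  cat("  gear:  ", fmt(x$dominant_gear), "\n  groups:", fmt(x$dominant_groups), "\n")
  invisible(x)
}
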