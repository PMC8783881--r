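# Whole-grain modification: dry-matter percentage and the 0..-5 point
# sliding scale for solid foods.

#' Whole-grain content as a percentage of food dry matter
#'
#' Whole-grain ingredients are stored in grams on a dry basis per 100 g of
#' food as consumed; the scale the modification uses is their share of the
#' food's dry matter: `100 * wholegrain_g / (100 - water_g)`, capped at 100
#' to absorb rounding in the source composition data.
#'
#' @param foods foods data frame (needs `wholegrain_g`, `water_g`).
#' @return numeric vector of percentages in \[0, 100\].
#' @export
ns_wg_dry_pct <- function(foods) {
  dry <- 100 - foods$water_g
  if (any(foods$wholegrain_g > 0 & dry <= 0))
    stop("food with whole-grain content but zero dry matter")
  pct <- ifelse(foods$wholegrain_g > 0, 100 * foods$wholegrain_g / dry, 0)
  pmin(pct, 100)
}

#' Whole-grain points
#'
#' Maps whole-grain percentage of dry matter to 0..-5 points on a
#' non-linear sliding scale anchored to the Whole Grain Initiative
#' definition cut-offs: below 25\% (the minimum for any front-of-pack
#' whole-grain claim) no points; 100\% always earns the full -5; the
#' steeper step sits at 50\%, the "whole-grain food" threshold. The default
#' band set (`"wgi"` preset) is >=25\% -> -1, >=50\% -> -3, 100\% -> -5.
#' Points apply to solid foods only; beverages, cheese and added fats
#' always receive 0.
#'
#' @param wg_pct whole-grain \% of dry matter (vector).
#' @param category food category (vector, recycled).
#' @param config configuration list; `config$wholegrain` selects the bands.
#' @return integer points in `{0, -1, ..., -5}`.
#' @export
ns_wg_points <- function(wg_pct, category = "solid_food",
                         config = ns_default_config()) {
  n <- max(length(wg_pct), length(category))
  wg_pct <- rep_len(wg_pct, n)
  category <- rep_len(category, n)
  stopifnot(all(wg_pct >= 0 & wg_pct <= 100))
  bands <- ns_resolve_wg_bands(config)
  idx <- rowSums(outer(wg_pct, bands$min_pct_dry, ">="))
  pts <- c(0, bands$points)[idx + 1L]
  apply_to <- config$wholegrain$apply_to %||% "solid_food"
  ifelse(category %in% apply_to, pts, 0)
}
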