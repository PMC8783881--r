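# Original points-based algorithm: component points, protein-counting rule,
# final score and A-E class.

ns_band_lookup <- function(value, bt) {
  # band index = number of thresholds passed; points monotone with index
  idx <- switch(bt$comparison,
    strictly_greater = ,
    at_most = rowSums(outer(value, bt$thresholds, ">")),
    strictly_less = rowSums(outer(value, bt$thresholds, ">=")),
    stop("unknown comparison: ", bt$comparison))
  c(0, bt$points)[idx + 1L]
}

#' Points for one component of one food category
#'
#' Looks the nutrient content up in the category's band table: the points of
#' the deepest band whose threshold test passes are returned, 0 if the
#' content reaches no band. Categories without a table of their own (cheese,
#' added fat except its saturated-fat ratio; fibre and protein for
#' beverages) fall back to the solid-food table, mirroring the published
#' category scheme where only beverages (energy, sugar, FVNLO) and added
#' fats (saturated fat) deviate.
#'
#' @param value nutrient content per 100 g (numeric vector).
#' @param component one of `"energy"`, `"satfat"`, `"sugar"`, `"sodium"`,
#'   `"fibre"`, `"protein"`, `"fvnlo"`, `"satfat_ratio"`.
#' @param category a single [ns_categories] value.
#' @param config configuration from [ns_load_config()].
#' @return integer points, same length as `value`.
#' @export
ns_component_points <- function(value, component,
                                category = "solid_food",
                                config = ns_default_config()) {
  stopifnot(length(category) == 1L, category %in% ns_categories)
  comp <- component
  if (comp == "fibre")
    comp <- paste0("fibre_", config$fibre_method %||% "aoac")
  bt <- config$bands[[category]][[comp]]
  if (is.null(bt)) bt <- config$bands[["solid_food"]][[comp]]
  if (is.null(bt))
    stop("no band table configured for component '", component,
         "' (category ", category, ")")
  ns_band_lookup(value, bt)
}

#' Saturated-fat points for added fats
#'
#' Added fats are scored on the ratio of saturated to total fat,
#' `100 * satfat_g / totalfat_g`, instead of absolute saturated-fat
#' content: below 10 scores 0, then one point per 6-unit band up to 10
#' points at a ratio of 64 or more.
#'
#' @param satfat_g saturated fat, g/100 g.
#' @param totalfat_g total fat, g/100 g; must be positive.
#' @param config configuration list.
#' @return integer points 0-10.
#' @export
ns_satfat_ratio_points <- function(satfat_g, totalfat_g,
                                   config = ns_default_config()) {
  if (any(!(totalfat_g > 0)))
    stop("satfat ratio points require totalfat_g > 0 (added-fat category)")
  ns_band_lookup(100 * satfat_g / totalfat_g,
                 config$bands$added_fat$satfat_ratio)
}

#' Protein-counting rule
#'
#' Protein points are dropped from the favourable side for foods that score
#' highly on the unfavourable side: when the unfavourable total reaches 11
#' points, protein counts only if the food earns the category-maximum FVNLO
#' points (5 for foods, 10 for beverages). Cheese is exempt and always keeps
#' its protein points.
#'
#' @param a_total unfavourable points total (0-40).
#' @param fvnlo_pts FVNLO points awarded.
#' @param category a single food category.
#' @return logical: does protein count towards the favourable total?
#' @export
ns_protein_rule <- function(a_total, fvnlo_pts, category = "solid_food") {
  stopifnot(length(category) == 1L, category %in% ns_categories)
  fvnlo_max <- if (category == "beverage") 10 else 5
  a_total < 11 | category == "cheese" | fvnlo_pts >= fvnlo_max
}

#' Assign the five-class label from a nutritional score
#'
#' Food boundaries: A \eqn{\le} -1, B 0-2, C 3-10, D 11-18, E \eqn{\ge} 19.
#' Beverage boundaries: A is reserved for water, B \eqn{\le} 1, C 2-5,
#' D 6-9, E \eqn{\ge} 10.
#'
#' @param score integer nutritional score(s).
#' @param category food category (vector, recycled).
#' @param is_water logical (vector, recycled); water is always class A.
#' @param config configuration list.
#' @return character vector of classes `"A"`..`"E"`.
#' @export
ns_assign_class <- function(score, category = "solid_food",
                            is_water = FALSE,
                            config = ns_default_config()) {
  n <- max(length(score), length(category), length(is_water))
  score <- rep_len(score, n)
  category <- rep_len(category, n)
  is_water <- rep_len(is_water, n)
  th <- config$class_thresholds
  food_cls <- ns_class_levels[1L +
    (score > th$food[["A"]]) + (score > th$food[["B"]]) +
    (score > th$food[["C"]]) + (score > th$food[["D"]])]
  bev_cls <- ns_class_levels[2L +
    (score > th$beverage[["B"]]) + (score > th$beverage[["C"]]) +
    (score > th$beverage[["D"]])]
  out <- ifelse(category == "beverage", bev_cls, food_cls)
  out[is_water] <- "A"
  out
}

#' Score a food-composition table
#'
#' Applies the full points algorithm to every row: unfavourable points for
#' energy, saturated fat (ratio-based for added fats), total sugar and
#' sodium (up to 10 each); favourable points for FVNLO, fibre and protein
#' (up to 5 each, FVNLO up to 10 for beverages) with the protein-counting
#' rule; the whole-grain modification (0 to -5 points for solid foods, see
#' [ns_wg_points()]); and the A-E class for both the original score
#' (`a_total - c_total`, range -15..40) and the modified score
#' (`original + wg_pts`, range -20..40).
#'
#' @param foods validated foods data frame (see [ns_validate_foods()]).
#' @param config configuration list.
#' @param validate validate `foods` first (default `TRUE`).
#' @return data frame with one row per food: `food_id`, `group`, `category`,
#'   `is_water`, per-component points, `a_total`, `protein_counted`,
#'   `c_total`, `wg_pct_dry`, `wg_pts`, `original_score`, `modified_score`,
#'   `original_class`, `modified_class`.
#' @export
ns_score_foods <- function(foods, config = ns_default_config(),
                           validate = TRUE) {
  if (validate) {
    v <- ns_validate_foods(foods)
    if (nrow(v$rejections))
      warning(nrow(v$rejections), " invalid food row(s) dropped before ",
              "scoring")
    foods <- v$foods
  }
  n <- nrow(foods)
  cat <- foods$category
  is_bev <- cat == "beverage"
  is_fat <- cat == "added_fat"

  pts_by_cat <- function(value, component) {
    out <- numeric(n)
    for (cc in unique(cat)) {
      i <- cat == cc
      out[i] <- ns_component_points(value[i], component, cc, config)
    }
    out
  }

  energy_pts <- pts_by_cat(foods$energy_kj, "energy")
  sugar_pts  <- pts_by_cat(foods$sugar_g, "sugar")
  sodium_pts <- pts_by_cat(foods$sodium_mg, "sodium")
  satfat_pts <- numeric(n)
  if (any(!is_fat))
    satfat_pts[!is_fat] <- pts_by_cat(foods$satfat_g, "satfat")[!is_fat]
  if (any(is_fat))
    satfat_pts[is_fat] <- ns_satfat_ratio_points(
      foods$satfat_g[is_fat], foods$totalfat_g[is_fat], config)
  fvnlo_pts  <- pts_by_cat(foods$fvnlo_pct, "fvnlo")
  fibre_pts  <- pts_by_cat(foods$fibre_g, "fibre")
  protein_pts <- pts_by_cat(foods$protein_g, "protein")

  a_total <- energy_pts + satfat_pts + sugar_pts + sodium_pts
  fvnlo_max <- ifelse(is_bev, 10, 5)
  protein_counted <- a_total < 11 | cat == "cheese" | fvnlo_pts >= fvnlo_max
  c_total <- fvnlo_pts + fibre_pts + ifelse(protein_counted, protein_pts, 0)
  original_score <- as.integer(a_total - c_total)

  wg_pct <- ns_wg_dry_pct(foods)
  wg_pts <- ns_wg_points(wg_pct, cat, config)
  modified_score <- as.integer(original_score + wg_pts)

  data.frame(
    food_id = foods$food_id, group = foods$group, category = cat,
    is_water = foods$is_water,
    energy_pts = as.integer(energy_pts), satfat_pts = as.integer(satfat_pts),
    sugar_pts = as.integer(sugar_pts), sodium_pts = as.integer(sodium_pts),
    fvnlo_pts = as.integer(fvnlo_pts), fibre_pts = as.integer(fibre_pts),
    protein_pts = as.integer(protein_pts),
    a_total = as.integer(a_total), protein_counted = protein_counted,
    c_total = as.integer(c_total),
    wg_pct_dry = wg_pct, wg_pts = as.integer(wg_pts),
    original_score = original_score, modified_score = modified_score,
    original_class = ns_assign_class(original_score, cat, foods$is_water,
                                     config),
    modified_class = ns_assign_class(modified_score, cat, foods$is_water,
                                     config),
    stringsAsFactors = FALSE)
}
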