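#' @keywords internal
"_PACKAGE"

# Categories recognised by the scoring engine. `is_water` is a separate flag
# carried by beverage records.
ns_categories <- c("solid_food", "beverage", "cheese", "added_fat")

ns_class_levels <- c("A", "B", "C", "D", "E")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a component band table
#'
#' A band table maps a nutrient content (per 100 g) to integer points by a
#' sequence of thresholds. Under `"strictly_greater"` the points of band `i`
#' are awarded once the content strictly exceeds threshold `i` (a content
#' exactly equal to a threshold stays in the lower-points band, so printed
#' thresholds are inclusive upper edges). `"at_most"` uses the same inclusive
#' upper-edge reading and exists to mirror tables published in that form
#' (e.g. beverage energy). `"strictly_less"` inverts the edge: band `i` is
#' entered once the content reaches threshold `i` (used for the added-fat
#' saturated-fat ratio, published as "< 10 -> 0" etc.).
#'
#' @param component component name, e.g. `"sugar"`.
#' @param thresholds strictly increasing numeric vector of band edges.
#' @param points integer points per band, same length as `thresholds`,
#'   monotone in band index. Points below the first band are always 0.
#' @param comparison one of `"strictly_greater"`, `"at_most"`,
#'   `"strictly_less"`.
#' @return a `ns_band_table` list.
#' @export
ns_band_table <- function(component, thresholds, points,
                          comparison = c("strictly_greater", "at_most",
                                         "strictly_less")) {
  comparison <- match.arg(comparison)
  bt <- structure(
    list(component = component,
         thresholds = as.numeric(thresholds),
         points = as.numeric(points),
         comparison = comparison),
    class = "ns_band_table")
  ns_check_band_table(bt)
  bt
}

ns_check_band_table <- function(bt) {
  if (length(bt$thresholds) != length(bt$points))
    stop("band table '", bt$component,
         "': thresholds and points differ in length")
  if (length(bt$thresholds) == 0L)
    stop("band table '", bt$component, "': empty")
  if (any(diff(bt$thresholds) <= 0))
    stop("band table '", bt$component,
         "': thresholds must be strictly increasing")
  d <- diff(bt$points)
  if (!(all(d >= 0) || all(d <= 0)))
    stop("band table '", bt$component,
         "': points must be monotone in band index")
  invisible(bt)
}

#' Default scoring configuration
#'
#' Band tables for the 2017-era Nutri-Score points algorithm, per published
#' category-specific tables: unfavourable components (energy, saturated fat,
#' total sugar, sodium) award up to 10 points each, favourable components
#' (fibre, protein, FVNLO) up to 5 (FVNLO up to 10 for beverages). Added
#' fats replace the saturated-fat table with bands on the ratio
#' 100*satfat/totalfat. Two fibre band sets are provided: AOAC (default) and
#' NSP/Englyst, selectable via `fibre_method`. The whole-grain modification
#' bands map whole-grain percentage of food dry matter to 0..-5 points
#' (solid foods only); two presets encode the sliding scale anchored at
#' <25\% -> 0 and 100\% -> -5, with the steeper jump at the 50\%
#' whole-grain-food cut-off:
#' `"wgi"` (default): >=25 -> -1, >=50 -> -3, 100 -> -5;
#' `"wgi_steep"`: >=25 -> -2, >=50 -> -4, 100 -> -5.
#'
#' @return nested list with elements `fibre_method`, `bands` (per category),
#'   `class_thresholds`, and `wholegrain`.
#' @export
ns_default_config <- function() {
  solid <- list(
    energy = ns_band_table("energy", seq(335, 3350, by = 335), 1:10),
    satfat = ns_band_table("satfat", 1:10, 1:10),
    sugar  = ns_band_table("sugar",
                           c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
                           1:10),
    sodium = ns_band_table("sodium", seq(90, 900, by = 90), 1:10),
    fibre_aoac = ns_band_table("fibre", c(0.9, 1.9, 2.8, 3.7, 4.7), 1:5),
    fibre_nsp  = ns_band_table("fibre", c(0.7, 1.4, 2.1, 2.8, 3.5), 1:5),
    protein = ns_band_table("protein", c(1.6, 3.2, 4.8, 6.4, 8.0), 1:5),
    fvnlo   = ns_band_table("fvnlo", c(40, 60, 80), c(1, 2, 5))
  )
  beverage <- list(
    energy = ns_band_table("energy", seq(0, 270, by = 30), 1:10,
                           comparison = "at_most"),
    sugar  = ns_band_table("sugar", seq(0, 13.5, by = 1.5), 1:10,
                           comparison = "at_most"),
    fvnlo  = ns_band_table("fvnlo", c(40, 60, 80), c(2, 4, 10))
  )
  added_fat <- list(
    satfat_ratio = ns_band_table("satfat_ratio",
                                 c(10, 16, 22, 28, 34, 40, 46, 52, 58, 64),
                                 1:10, comparison = "strictly_less")
  )
  list(
    fibre_method = "aoac",
    bands = list(solid_food = solid, beverage = beverage,
                 added_fat = added_fat),
    class_thresholds = list(
      # inclusive upper score bound of classes A..D; E is everything above
      food = c(A = -1, B = 2, C = 10, D = 18),
      beverage = c(B = 1, C = 5, D = 9)  # A is reserved for water
    ),
    wholegrain = list(
      preset = "wgi",
      presets = list(
        wgi = data.frame(min_pct_dry = c(25, 50, 100),
                         points = c(-1, -3, -5)),
        wgi_steep = data.frame(min_pct_dry = c(25, 50, 100),
                               points = c(-2, -4, -5))
      ),
      bands = NULL,          # resolved from preset unless overridden
      apply_to = "solid_food"
    )
  )
}

ns_resolve_wg_bands <- function(config) {
  wg <- config$wholegrain
  bands <- wg$bands %||% wg$presets[[wg$preset %||% "wgi"]]
  if (is.null(bands))
    stop("unknown whole-grain preset: ", wg$preset)
  bands <- as.data.frame(bands)
  if (!all(c("min_pct_dry", "points") %in% names(bands)))
    stop("wholegrain bands need columns min_pct_dry, points")
  bands <- bands[order(bands$min_pct_dry), , drop = FALSE]
  if (any(diff(bands$points) > 0))
    stop("wholegrain points must be non-increasing in min_pct_dry")
  if (any(bands$points > 0))
    stop("wholegrain points must be <= 0")
  if (min(bands$min_pct_dry) < 25)
    stop("whole-grain content below 25% of dry matter never scores")
  bands
}

ns_deep_merge <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base)) return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (nm %in% names(base))
      ns_deep_merge(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

ns_as_band_table <- function(x, component) {
  if (inherits(x, "ns_band_table")) return(x)
  ns_band_table(component, x$thresholds, x$points,
                x$comparison %||% "strictly_greater")
}

#' Load a scoring configuration
#'
#' Reads a YAML (or JSON) configuration file and deep-merges it over
#' [ns_default_config()]. Band tables given in the file as lists with
#' `thresholds`/`points` (and optionally `comparison`) replace the defaults
#' for that component; `wholegrain$bands` may be given as a list of
#' `min_pct_dry`/`points` pairs.
#'
#' @param path path to a YAML/JSON file, or `NULL` for the defaults.
#' @param fibre_method `"aoac"` or `"nsp"`; overrides the file if given.
#' @return validated configuration list.
#' @export
ns_load_config <- function(path = NULL, fibre_method = NULL) {
  config <- ns_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    override <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    config <- ns_deep_merge(config, override)
  }
  if (!is.null(fibre_method)) config$fibre_method <- fibre_method
  config$fibre_method <- match.arg(config$fibre_method, c("aoac", "nsp"))
  for (cat in names(config$bands))
    for (comp in names(config$bands[[cat]]))
      config$bands[[cat]][[comp]] <-
        ns_as_band_table(config$bands[[cat]][[comp]], comp)
  if (!is.null(config$wholegrain$bands) &&
      !is.data.frame(config$wholegrain$bands))
    config$wholegrain$bands <-
      do.call(rbind, lapply(config$wholegrain$bands, as.data.frame))
  ns_resolve_wg_bands(config)  # validates
  config
}
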