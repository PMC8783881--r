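# Food-composition and intake table schemas, validation, CSV i/o.

ns_foods_cols <- c(
  food_id = "character", name = "character", group = "character",
  category = "character", is_water = "logical",
  energy_kj = "numeric", satfat_g = "numeric", totalfat_g = "numeric",
  sugar_g = "numeric", sodium_mg = "numeric", fibre_g = "numeric",
  protein_g = "numeric", fvnlo_pct = "numeric", wholegrain_g = "numeric",
  water_g = "numeric")

ns_intakes_cols <- c(
  person_id = "character", food_id = "character",
  grams_consumed = "numeric", energy_kj_consumed = "numeric")

#' Validate a food-composition table
#'
#' Checks each row of a food table against the schema invariants: known
#' category; `is_water` only on beverages; non-negative nutrient contents;
#' `fvnlo_pct` and `water_g` within \[0, 100\]; saturated fat not exceeding
#' total fat; whole-grain grams (dry basis) not exceeding the food's dry
#' matter (`100 - water_g`); added fats must contain fat. Rows violating any
#' rule are removed and reported.
#'
#' @param foods data frame with the `foods.csv` columns.
#' @return list with `foods` (the accepted rows) and `rejections`
#'   (data frame `row`, `food_id`, `reason`; zero rows when all pass).
#' @export
ns_validate_foods <- function(foods) {
  missing <- setdiff(names(ns_foods_cols), names(foods))
  if (length(missing))
    stop("foods table is missing columns: ", paste(missing, collapse = ", "))
  foods <- foods[names(ns_foods_cols)]
  foods$is_water <- as.logical(foods$is_water)
  foods$is_water[is.na(foods$is_water)] <- FALSE
  num_cols <- names(ns_foods_cols)[ns_foods_cols == "numeric"]
  for (cc in num_cols) foods[[cc]] <- as.numeric(foods[[cc]])

  reason <- rep(NA_character_, nrow(foods))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- msg
  }
  nonneg <- c("energy_kj", "satfat_g", "totalfat_g", "sugar_g", "sodium_mg",
              "fibre_g", "protein_g", "wholegrain_g")
  for (cc in nonneg) flag(foods[[cc]] < 0, paste0("negative ", cc))
  flag(!(foods$category %in% ns_categories), "unknown category")
  flag(foods$is_water & foods$category != "beverage",
       "is_water requires category beverage")
  flag(foods$fvnlo_pct < 0 | foods$fvnlo_pct > 100,
       "fvnlo_pct outside [0,100]")
  flag(foods$water_g < 0 | foods$water_g > 100, "water_g outside [0,100]")
  flag(foods$satfat_g > foods$totalfat_g + 1e-9,
       "satfat_g exceeds totalfat_g")
  flag(foods$wholegrain_g > 100 - foods$water_g + 1e-9,
       "wholegrain_g exceeds dry matter (100 - water_g)")
  flag(foods$category == "added_fat" & !(foods$totalfat_g > 0),
       "added_fat requires totalfat_g > 0")

  bad <- !is.na(reason)
  rejections <- data.frame(row = which(bad),
                           food_id = as.character(foods$food_id[bad]),
                           reason = reason[bad],
                           stringsAsFactors = FALSE)
  list(foods = foods[!bad, , drop = FALSE], rejections = rejections)
}

#' Read and validate a foods.csv table
#'
#' Expects the documented header
#' `food_id,name,group,category,is_water,energy_kj,satfat_g,totalfat_g,sugar_g,sodium_mg,fibre_g,protein_g,fvnlo_pct,wholegrain_g,water_g`
#' (UTF-8, "." decimal separator). Rejected rows are dropped with a warning
#' naming the row numbers.
#'
#' @param path CSV file path.
#' @param validate drop invalid rows (default) or return the raw table.
#' @return validated foods data frame; rejections in attribute
#'   `"rejections"`.
#' @export
ns_read_foods <- function(path, validate = TRUE) {
  foods <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           fileEncoding = "UTF-8")
  missing <- setdiff(names(ns_foods_cols), names(foods))
  if (length(missing))
    stop("malformed foods.csv header; missing columns: ",
         paste(missing, collapse = ", "))
  for (cc in names(ns_foods_cols)) {
    foods[[cc]] <- switch(ns_foods_cols[[cc]],
      numeric = suppressWarnings(as.numeric(foods[[cc]])),
      logical = as.logical(foods[[cc]]) |
        foods[[cc]] %in% c("1", "true", "True"),
      foods[[cc]])
  }
  if (!validate) return(foods)
  v <- ns_validate_foods(foods)
  if (nrow(v$rejections))
    warning(nrow(v$rejections), " food row(s) rejected: ",
            paste0("row ", v$rejections$row, " (", v$rejections$reason, ")",
                   collapse = "; "))
  structure(v$foods, rejections = v$rejections)
}

#' Read a dietary-intake table
#'
#' Expects header `person_id,food_id,grams_consumed,energy_kj_consumed`,
#' one row per (person, consumed food) from a single survey day.
#' Zero-energy rows are kept here; they are excluded later by
#' [ns_score_diets()].
#'
#' @param path CSV file path.
#' @return intakes data frame.
#' @export
ns_read_intakes <- function(path) {
  intakes <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  missing <- setdiff(names(ns_intakes_cols), names(intakes))
  if (length(missing))
    stop("malformed intakes.csv header; missing columns: ",
         paste(missing, collapse = ", "))
  intakes$person_id <- as.character(intakes$person_id)
  intakes$food_id <- as.character(intakes$food_id)
  intakes$grams_consumed <- as.numeric(intakes$grams_consumed)
  intakes$energy_kj_consumed <- as.numeric(intakes$energy_kj_consumed)
  bad <- !is.finite(intakes$grams_consumed) |
    !is.finite(intakes$energy_kj_consumed) | intakes$grams_consumed <= 0
  if (any(bad)) {
    warning(sum(bad), " intake row(s) rejected (non-positive grams or ",
            "unparseable numbers)")
    intakes <- intakes[!bad, , drop = FALSE]
  }
  intakes
}

#' Write a table as UTF-8 CSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
ns_write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = which(vapply(x, is.character, logical(1))))
  invisible(path)
}
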