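# Shared fixtures and independent oracles.

# one valid food row with overridable fields
make_food <- function(...) {
  f <- data.frame(
    food_id = "f1", name = "test food", group = "test",
    category = "solid_food", is_water = FALSE,
    energy_kj = 0, satfat_g = 0, totalfat_g = 0, sugar_g = 0,
    sodium_mg = 0, fibre_g = 0, protein_g = 0, fvnlo_pct = 0,
    wholegrain_g = 0, water_g = 0, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) f[[nm]] <- over[[nm]]
  f
}

# random valid foods, independent of the package's own generator
random_foods <- function(n) {
  category <- sample(c("solid_food", "beverage", "cheese", "added_fat"),
                     n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  totalfat <- round(runif(n, 0, 100), 2)
  totalfat[category == "added_fat"] <-
    pmax(totalfat[category == "added_fat"], 1)
  water <- round(runif(n, 0, 99), 1)
  f <- data.frame(
    food_id = paste0("r", seq_len(n)), name = "rnd", group = "rnd",
    category = category, is_water = FALSE,
    energy_kj = round(runif(n, 0, 3700), 1),
    satfat_g = round(totalfat * runif(n), 2),
    totalfat_g = totalfat,
    sugar_g = round(runif(n, 0, 100), 2),
    sodium_mg = round(runif(n, 0, 2500), 1),
    fibre_g = round(runif(n, 0, 15), 2),
    protein_g = round(runif(n, 0, 40), 2),
    fvnlo_pct = round(runif(n, 0, 100), 1),
    wholegrain_g = 0, water_g = water, stringsAsFactors = FALSE)
  f$wholegrain_g <- round(runif(n) * (100 - water) *
                            rbinom(n, 1, 0.5), 2)
  f
}

# brute-force oracle: walk the thresholds one by one
scan_points <- function(value, thresholds, points, comparison) {
  vapply(value, function(v) {
    if (comparison == "at_most") {
      # published form: "<= t1 -> 0, <= t2 -> p1, ..., > tn -> pn"
      i <- which(v <= thresholds)[1]
      if (is.na(i)) return(points[length(points)])
      return(if (i == 1L) 0 else points[i - 1L])
    }
    best <- 0
    for (i in seq_along(thresholds)) {
      hit <- switch(comparison,
                    strictly_greater = v > thresholds[i],
                    strictly_less = v >= thresholds[i])
      if (hit) best <- points[i]
    }
    best
  }, numeric(1))
}

# brute-force energy-weighted mean
brute_diet_score <- function(scores, energies) {
  sum(scores * energies) / sum(energies)
}
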