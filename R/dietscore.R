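# Whole-diet nutritional score (energy-weighted mean of food scores) and
# whole-grain intake density per person-day.

#' Whole-diet nutritional scores for a single survey day
#'
#' For each person the whole-diet nutritional score is the energy-weighted
#' mean of the nutritional scores of the foods consumed:
#' `sum(FS_i * E_i) / sum(E_i)`, with `FS_i` the food score and `E_i` the
#' energy consumed from that food. Zero-energy items (water and other
#' energy-free foods, plus any food flagged `excluded` in the composition
#' table) are removed first; persons left with no energy-contributing items
#' are dropped from the output and reported in the `"excluded_persons"`
#' attribute. Whole-grain intake is summarised as grams of whole grain
#' (dry basis) scaled to a 10 MJ energy intake day.
#'
#' @param intakes intake data frame (`person_id`, `food_id`,
#'   `grams_consumed`, `energy_kj_consumed`).
#' @param scored scored foods from [ns_score_foods()].
#' @param foods composition table carrying `wholegrain_g` per 100 g (and
#'   optionally a logical `excluded` column for items such as alcohol or
#'   medical beverages that the data provider removes from diet scoring).
#' @return data frame `person_id`, `whole_diet_original`,
#'   `whole_diet_modified`, `energy_kj`, `wg_g`, `wg_per_10mj`,
#'   `consumer_flag`; attribute `"excluded_persons"` lists persons whose
#'   reported items were all zero-energy.
#' @export
ns_score_diets <- function(intakes, scored, foods) {
  stopifnot(all(c("person_id", "food_id", "energy_kj_consumed",
                  "grams_consumed") %in% names(intakes)))
  unknown <- setdiff(intakes$food_id, scored$food_id)
  if (length(unknown))
    stop("intake rows reference unscored food_ids, e.g. ", unknown[[1]])

  all_persons <- unique(as.character(intakes$person_id))
  keep <- intakes$energy_kj_consumed > 0
  if (!is.null(foods$excluded)) {
    excl_ids <- foods$food_id[as.logical(foods$excluded) %in% TRUE]
    keep <- keep & !(intakes$food_id %in% excl_ids)
  }
  intakes <- intakes[keep, , drop = FALSE]

  i <- match(intakes$food_id, scored$food_id)
  j <- match(intakes$food_id, foods$food_id)
  if (anyNA(j)) stop("intake rows reference food_ids absent from foods")
  e <- intakes$energy_kj_consumed
  pid <- factor(intakes$person_id)
  tot_e <- tapply(e, pid, sum)
  res <- data.frame(
    person_id = levels(pid),
    whole_diet_original =
      as.numeric(tapply(scored$original_score[i] * e, pid, sum) / tot_e),
    whole_diet_modified =
      as.numeric(tapply(scored$modified_score[i] * e, pid, sum) / tot_e),
    energy_kj = as.numeric(tot_e),
    wg_g = as.numeric(tapply(intakes$grams_consumed *
                               foods$wholegrain_g[j] / 100, pid, sum)),
    stringsAsFactors = FALSE)
  # 10 MJ = 10000 kJ
  res$wg_per_10mj <- res$wg_g / (res$energy_kj / 10000)
  res$consumer_flag <- res$wg_g > 0
  excluded <- setdiff(all_persons, res$person_id)
  if (length(excluded))
    message(length(excluded), " person(s) excluded: only zero-energy items")
  structure(res, excluded_persons = excluded)
}
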