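# Comparison statistics between the original and the modified algorithm:
# component-score rank correlations, class-transition tables, correlation
# with an external diet-quality index, and whole-grain quantile analysis.

ns_eval_components <- c(
  wholegrain = "wholegrain_g", fibre = "fibre_g", protein = "protein_g",
  fvnlo = "fvnlo_pct", energy = "energy_kj", satfat = "satfat_g",
  sugar = "sugar_g", sodium = "sodium_mg")

# Spearman rho as rank-then-Pearson (average ranks for ties). p-value by the
# t approximation, or exact permutation of one margin for n below `exact_n`.
ns_spearman <- function(x, y, exact_n = 10L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(n = n, rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < exact_n) {
    perms <- ns_permutations(n)
    stat <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(stat) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    if (abs(rho) >= 1) p <- 0
  }
  c(n = n, rho = rho, p = p)
}

ns_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- ns_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Rank correlations between component content and nutritional score
#'
#' Spearman correlations of each scored component's content (whole grain in
#' g dry weight, fibre/protein in g, FVNLO in \%, energy in kJ, saturated
#' fat and sugar in g, sodium in mg) with the original and the modified food
#' nutritional score, overall and per food group. Water items are excluded.
#'
#' @param foods composition table.
#' @param scored scored foods from [ns_score_foods()] (matched by
#'   `food_id`).
#' @param by_group also compute correlations within each `group` level.
#' @param alpha significance level for the `significant` flag.
#' @return data frame `group`, `component`, `score`
#'   (`"original"`/`"modified"`), `n`, `rho`, `p`, `significant`; `rho` is
#'   `NA` for constant columns.
#' @export
ns_component_correlations <- function(foods, scored, by_group = FALSE,
                                      alpha = 0.05) {
  i <- match(scored$food_id, foods$food_id)
  if (anyNA(i)) stop("scored foods missing from the composition table")
  dat <- cbind(foods[i, , drop = FALSE],
               scored[c("original_score", "modified_score")])
  dat <- dat[!dat$is_water, , drop = FALSE]
  groups <- list(`all foods` = rep(TRUE, nrow(dat)))
  if (by_group)
    for (g in sort(unique(dat$group))) groups[[g]] <- dat$group == g
  out <- list()
  for (gname in names(groups)) {
    sub <- dat[groups[[gname]], , drop = FALSE]
    if (nrow(sub) < 3L) next
    for (comp in names(ns_eval_components)) {
      x <- sub[[ns_eval_components[[comp]]]]
      for (sc in c("original", "modified")) {
        r <- ns_spearman(x, sub[[paste0(sc, "_score")]])
        out[[length(out) + 1L]] <- data.frame(
          group = gname, component = comp, score = sc,
          n = as.integer(r[["n"]]), rho = r[["rho"]], p = r[["p"]],
          significant = !is.na(r[["p"]]) & r[["p"]] < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Class-transition table under the whole-grain modification
#'
#' Cross-tabulates original against modified Nutri-Score class and counts
#' foods whose score, and whose class, changed. Water items are excluded
#' from counts and percentage denominators.
#'
#' @param scored scored foods from [ns_score_foods()].
#' @param group optional vector of group labels aligned with `scored`; when
#'   given, a summary row per group is returned and `transitions` is a list
#'   of matrices.
#' @return list with `transitions` (5x5 original x modified count matrix,
#'   or a named list of them) and `summary` (data frame `group`, `n`,
#'   `n_score_changed`, `pct_score_changed`, `n_class_changed`,
#'   `pct_class_changed`).
#' @export
ns_class_transition <- function(scored, group = NULL) {
  keep <- !scored$is_water
  scored <- scored[keep, , drop = FALSE]
  group <- if (is.null(group)) rep("all foods", nrow(scored))
           else as.character(group)[keep]
  one <- function(sub) {
    tab <- table(factor(sub$original_class, ns_class_levels),
                 factor(sub$modified_class, ns_class_levels),
                 dnn = c("original", "modified"))
    n <- nrow(sub)
    nsc <- sum(sub$modified_score != sub$original_score)
    ncl <- sum(sub$modified_class != sub$original_class)
    list(tab = unclass(tab),
         row = data.frame(n = n, n_score_changed = nsc,
                          pct_score_changed = 100 * nsc / n,
                          n_class_changed = ncl,
                          pct_class_changed = 100 * ncl / n))
  }
  if (length(unique(group)) == 1L) {
    r <- one(scored)
    return(list(transitions = r$tab,
                summary = cbind(group = group[[1]], r$row)))
  }
  parts <- lapply(split(scored, group), one)
  list(transitions = lapply(parts, `[[`, "tab"),
       summary = do.call(rbind, Map(function(g, p) cbind(group = g, p$row),
                                    names(parts), parts)))
}

#' Correlation of whole-diet nutritional scores with a diet-quality index
#'
#' Pearson correlation between per-person whole-diet nutritional scores
#' (original and modified) and an external diet-quality score in which
#' higher values mean a better diet; the expected sign is therefore
#' negative.
#'
#' @param diets output of [ns_score_diets()].
#' @param dq data frame `person_id`, `dq_score`.
#' @return data frame `score`, `n`, `r`, `p`; `r` is `NA` when either
#'   column has zero variance.
#' @export
ns_diet_quality_correlation <- function(diets, dq) {
  i <- match(diets$person_id, as.character(dq$person_id))
  d <- cbind(diets, dq_score = dq$dq_score[i])
  d <- d[is.finite(d$dq_score), , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 matched persons")
  one <- function(x) {
    if (stats::sd(x) == 0 || stats::sd(d$dq_score) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, d$dq_score, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  ro <- one(d$whole_diet_original); rm <- one(d$whole_diet_modified)
  data.frame(score = c("original", "modified"), n = nrow(d),
             r = c(ro[["r"]], rm[["r"]]), p = c(ro[["p"]], rm[["p"]]),
             stringsAsFactors = FALSE)
}

#' Quantile analysis of whole-grain intake density
#'
#' Splits persons into non-consumers and quartiles of whole-grain intake per
#' 10 MJ of energy per day (type-7 quantiles among consumers; a density
#' exactly on a cut point goes to the lower quartile), reports per-group
#' means of the original and modified whole-diet nutritional scores (and the
#' diet-quality score when supplied), and a one-way ANOVA of each whole-diet
#' score across the groups.
#'
#' @param diets output of [ns_score_diets()].
#' @param dq optional data frame `person_id`, `dq_score`.
#' @return list with `groups` (data frame `group`, `n`, `mean_wg_per_10mj`,
#'   `mean_original`, `mean_modified`, and `mean_dq` when available),
#'   `cuts` (the three quartile cut points), and `anova` (data frame
#'   `score`, `F`, `p`; `NA` with a degenerate grouping).
#' @export
ns_wg_quantile_analysis <- function(diets, dq = NULL) {
  d <- diets
  if (!is.null(dq)) {
    i <- match(d$person_id, as.character(dq$person_id))
    d$dq_score <- dq$dq_score[i]
  }
  cons <- d$consumer_flag
  if (sum(cons) < 4L) stop("need at least 4 whole-grain consumers")
  x <- d$wg_per_10mj
  cuts <- stats::quantile(x[cons], c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
  q <- 1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
  grp <- ifelse(!cons, "NC", paste0("Q", q))
  grp <- factor(grp, levels = c("NC", "Q1", "Q2", "Q3", "Q4"))
  grp <- droplevels(grp)
  agg <- function(v) as.numeric(tapply(v, grp, mean))
  groups <- data.frame(group = levels(grp),
                       n = as.integer(table(grp)),
                       mean_wg_per_10mj = agg(x),
                       mean_original = agg(d$whole_diet_original),
                       mean_modified = agg(d$whole_diet_modified),
                       stringsAsFactors = FALSE)
  if (!is.null(dq)) groups$mean_dq <- agg(d$dq_score)
  anova_one <- function(v) {
    if (nlevels(grp) < 2L || all(tapply(v, grp, stats::sd) %in% c(0, NA)))
      return(c(F = NA_real_, p = NA_real_))
    a <- stats::anova(stats::lm(v ~ grp))
    c(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
  }
  ao <- anova_one(d$whole_diet_original)
  am <- anova_one(d$whole_diet_modified)
  list(groups = groups, cuts = cuts,
       anova = data.frame(score = c("original", "modified"),
                          F = c(ao[["F"]], am[["F"]]),
                          p = c(ao[["p"]], am[["p"]]),
                          stringsAsFactors = FALSE))
}
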