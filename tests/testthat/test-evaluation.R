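scored_from <- function(foods) ns_score_foods(foods, validate = FALSE)

test_that("spearman correlations match a rank-then-pearson oracle", {
  set.seed(506)
  # small table of 5 foods: brute force rank + Pearson, exact permutation p
  x <- c(3.2, 1.1, 8.4, 0.5, 5.5)
  y <- c(10, 2, 7, 1, 9)
  r <- ns_spearman(x, y)
  expect_equal(r[["rho"]], cor(rank(x), rank(y)), tolerance = 1e-12)
  perms <- ns_permutations(5)
  stats_all <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(r[["p"]], mean(abs(stats_all) >= abs(r[["rho"]]) - 1e-12))
  # larger n: t-approximation agrees with cor.test's AS89-free path
  x <- rnorm(200); y <- 0.4 * x + rnorm(200)
  r <- ns_spearman(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r[["rho"]], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r[["p"]], ct$p.value, tolerance = 0.02)
})

test_that("component correlations behave at the rank extremes", {
  set.seed(507)
  foods <- random_foods(300)
  foods$is_water <- FALSE
  sc <- scored_from(foods)
  # perfect rank agreement: a strictly monotone transform of the score
  foods2 <- foods
  foods2$sugar_g <- exp(sc$original_score / 10)
  tab <- ns_component_correlations(foods2, sc)
  row <- tab[tab$component == "sugar" & tab$score == "original", ]
  expect_equal(row$rho, 1, tolerance = 1e-12)
  expect_true(row$significant)
  # an independent component: near-zero rho, not significant on average
  foods2$sodium_mg <- runif(300, 0, 1000)
  tab <- ns_component_correlations(foods2, sc)
  row <- tab[tab$component == "sodium" & tab$score == "original", ]
  expect_lt(abs(row$rho), 0.15)
  # constant column: undefined, reported missing
  foods2$fibre_g <- 2
  tab <- ns_component_correlations(foods2, sc)
  expect_true(all(is.na(tab$rho[tab$component == "fibre"])))
  # water rows are excluded from n
  foods2$is_water[1:10] <- TRUE
  foods2$category[1:10] <- "beverage"
  tab <- ns_component_correlations(foods2, scored_from(foods2))
  expect_equal(unique(tab$n), 290L)
})

test_that("class transitions count score and class changers", {
  # no whole grain: identity transitions, zero changers
  set.seed(508)
  foods <- random_foods(100)
  foods$wholegrain_g <- 0
  sc <- scored_from(foods)
  tr <- ns_class_transition(sc)
  expect_equal(sum(tr$transitions), 100)
  expect_equal(sum(diag(tr$transitions)), 100)
  expect_equal(tr$summary$n_score_changed, 0)

  # constructed fixture: 5 of 100 foods move B -> A
  foods <- do.call(rbind, replicate(100, make_food(), simplify = FALSE))
  foods$food_id <- paste0("f", 1:100)
  foods$wholegrain_g[1:5] <- 30   # 30% dry -> -1 point, 0 -> -1 is B -> A
  sc <- scored_from(foods)
  tr <- ns_class_transition(sc)
  expect_equal(tr$transitions["B", "A"], 5)
  expect_equal(tr$summary$n_class_changed, 5)
  expect_equal(tr$summary$pct_class_changed, 5)
  # all off-diagonal mass sits below the diagonal (towards better classes)
  expect_equal(sum(tr$transitions[upper.tri(tr$transitions)]), 0)

  # grouped summaries and water exclusion from denominators
  grp <- rep(c("grain", "other"), each = 50)
  tr <- ns_class_transition(sc, group = grp)
  expect_equal(tr$summary$n_class_changed[tr$summary$group == "grain"], 5)
  expect_equal(tr$summary$n_class_changed[tr$summary$group == "other"], 0)
})

test_that("diet-quality correlations recover exact and null structure", {
  set.seed(509)
  diets <- data.frame(person_id = as.character(1:50),
                      whole_diet_original = rnorm(50, 8, 3))
  diets$whole_diet_modified <- diets$whole_diet_original - runif(50, 0, 1)
  diets$consumer_flag <- TRUE
  diets$wg_per_10mj <- runif(50)
  # dq exactly the negated score: r = -1
  dq <- data.frame(person_id = diets$person_id,
                   dq_score = -diets$whole_diet_original)
  res <- ns_diet_quality_correlation(diets, dq)
  expect_equal(res$r[res$score == "original"], -1, tolerance = 1e-12)
  expect_lt(res$p[res$score == "original"], 1e-10)
  # permuted dq: near-zero correlation
  set.seed(1); dq$dq_score <- sample(dq$dq_score)
  res <- ns_diet_quality_correlation(diets, dq)
  expect_lt(abs(res$r[res$score == "original"]), 0.3)
  # zero variance: undefined
  dq$dq_score <- 1
  res <- ns_diet_quality_correlation(diets, dq)
  expect_true(all(is.na(res$r)))
  expect_error(ns_diet_quality_correlation(diets[1:2, ], dq), "at least 3")
})

test_that("quantile analysis matches a brute-force split on a toy cohort", {
  # 12 persons: 4 non-consumers, 8 consumers with known densities
  dens <- c(0, 0, 0, 0, 10, 20, 30, 40, 50, 60, 70, 80)
  diets <- data.frame(person_id = as.character(1:12),
                      whole_diet_original = 12 - dens / 10,
                      whole_diet_modified = 11 - dens / 8,
                      wg_per_10mj = dens, consumer_flag = dens > 0)
  qa <- ns_wg_quantile_analysis(diets)
  cons <- dens[dens > 0]
  expect_equal(qa$cuts, quantile(cons, c(.25, .5, .75), type = 7,
                                 names = FALSE))
  # brute-force group assignment: sorted split with ties to the lower group
  expect_equal(qa$groups$n, c(4L, 2L, 2L, 2L, 2L))
  expect_equal(qa$groups$mean_wg_per_10mj, c(0, 15, 35, 55, 75))
  expect_equal(qa$groups$mean_original,
               c(12, mean(12 - c(10, 20) / 10), mean(12 - c(30, 40) / 10),
                 mean(12 - c(50, 60) / 10), mean(12 - c(70, 80) / 10)))
  # a density exactly on a cut point goes to the lower quartile
  expect_equal(qa$cuts[2], 45)
  diets2 <- diets
  diets2$wg_per_10mj[5] <- qa$cuts[1]
  qa2 <- ns_wg_quantile_analysis(diets2)
  expect_equal(qa2$groups$n[2], 2L)
  # ANOVA agrees with lm on the same grouping
  grp <- c(rep("NC", 4), rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  a <- anova(lm(diets$whole_diet_original ~ grp))
  expect_equal(qa$anova$F[qa$anova$score == "original"],
               a[["F value"]][1], tolerance = 1e-12)
  expect_equal(qa$anova$p[qa$anova$score == "original"],
               a[["Pr(>F)"]][1], tolerance = 1e-12)
})

test_that("degenerate quantile analyses are reported as undefined", {
  diets <- data.frame(person_id = as.character(1:8),
                      whole_diet_original = rep(5, 8),
                      whole_diet_modified = rep(4, 8),
                      wg_per_10mj = rep(33, 8),
                      consumer_flag = TRUE)
  qa <- ns_wg_quantile_analysis(diets)
  expect_equal(nrow(qa$groups), 1L)  # all consumers collapse into Q1
  expect_true(all(is.na(qa$anova$F)))
  expect_error(ns_wg_quantile_analysis(diets[1:3, ]), "at least 4")
})
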