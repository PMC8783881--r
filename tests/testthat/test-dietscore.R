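# helpers building a minimal scored-food table without running the scorer
fake_scored <- function(ids, orig, mod = orig) {
  data.frame(food_id = ids, original_score = orig, modified_score = mod,
             stringsAsFactors = FALSE)
}
fake_foods <- function(ids, wg = 0, excluded = NULL) {
  f <- data.frame(food_id = ids, wholegrain_g = rep_len(wg, length(ids)),
                  stringsAsFactors = FALSE)
  if (!is.null(excluded)) f$excluded <- excluded
  f
}
intake <- function(pid, fid, grams, energy) {
  data.frame(person_id = pid, food_id = fid, grams_consumed = grams,
             energy_kj_consumed = energy, stringsAsFactors = FALSE)
}

test_that("whole-diet score is the energy-weighted mean of food scores", {
  # one food: the score itself
  d <- ns_score_diets(intake("p", "a", 100, 1234),
                      fake_scored("a", 7), fake_foods("a"))
  expect_equal(d$whole_diet_original, 7)
  # two foods, equal energies
  d <- ns_score_diets(intake("p", c("a", "b"), c(10, 10), c(1000, 1000)),
                      fake_scored(c("a", "b"), c(0, 10)),
                      fake_foods(c("a", "b")))
  expect_equal(d$whole_diet_original, 5)
  # three foods, hand-computed: (-5*500 + 0*1000 + 20*500) / 2000
  d <- ns_score_diets(intake("p", c("a", "b", "c"), c(1, 1, 1),
                             c(500, 1000, 500)),
                      fake_scored(c("a", "b", "c"), c(-5, 0, 20)),
                      fake_foods(c("a", "b", "c")))
  expect_equal(d$whole_diet_original, 3.75)
})

test_that("diet scores match a brute-force oracle on random toy cohorts", {
  set.seed(404)
  for (rep in 1:50) {
    k <- sample(1:12, 1)
    ids <- paste0("f", 1:k)
    orig <- sample(-15:40, k, replace = TRUE)
    sc <- fake_scored(ids, orig, orig + sample(-5:0, k, replace = TRUE))
    en <- round(runif(k, 10, 4000), 1)
    d <- ns_score_diets(intake("p", ids, runif(k, 10, 300), en), sc,
                        fake_foods(ids))
    expect_equal(d$whole_diet_original,
                 brute_diet_score(sc$original_score, en),
                 tolerance = 1e-12)
    expect_equal(d$whole_diet_modified,
                 brute_diet_score(sc$modified_score, en),
                 tolerance = 1e-12)
    # convex hull of the consumed foods' scores
    expect_gte(d$whole_diet_original, min(sc$original_score) - 1e-12)
    expect_lte(d$whole_diet_original, max(sc$original_score) + 1e-12)
    expect_lte(d$whole_diet_modified, d$whole_diet_original + 1e-12)
  }
})

test_that("splitting an intake row never changes the diet score", {
  set.seed(405)
  for (rep in 1:1000) {
    k <- sample(2:8, 1)
    ids <- paste0("f", 1:k)
    sc <- fake_scored(ids, sample(-15:40, k, replace = TRUE))
    en <- runif(k, 100, 3000)
    gr <- runif(k, 20, 300)
    base <- ns_score_diets(intake("p", ids, gr, en), sc, fake_foods(ids))
    # split the first row into two with the same food, summed energy/grams
    w <- runif(1, 0.1, 0.9)
    split <- intake("p", c(ids[1], ids),
                    c(gr[1] * w, gr[1] * (1 - w), gr[-1]),
                    c(en[1] * w, en[1] * (1 - w), en[-1]))
    after <- ns_score_diets(split, sc, fake_foods(ids))
    expect_equal(after$whole_diet_original, base$whole_diet_original,
                 tolerance = 1e-12)
    expect_equal(after$wg_per_10mj, base$wg_per_10mj, tolerance = 1e-12)
  }
})

test_that("zero-energy items and water-only persons are excluded", {
  sc <- fake_scored(c("food", "water"), c(10, 0))
  fd <- fake_foods(c("food", "water"))
  ik <- rbind(intake("p1", c("food", "water"), c(100, 500), c(2000, 0)),
              intake("p2", "water", 800, 0))
  expect_message(d <- ns_score_diets(ik, sc, fd), "excluded")
  expect_equal(d$person_id, "p1")
  expect_equal(d$whole_diet_original, 10)  # water row carries no weight
  expect_equal(d$energy_kj, 2000)
  expect_equal(attr(d, "excluded_persons"), "p2")

  # provider-flagged exclusions (e.g. alcohol) are honoured too
  fd2 <- fake_foods(c("food", "beer"), excluded = c(FALSE, TRUE))
  sc2 <- fake_scored(c("food", "beer"), c(4, 30))
  d <- ns_score_diets(intake("p", c("food", "beer"), c(100, 330),
                             c(1000, 800)), sc2, fd2)
  expect_equal(d$whole_diet_original, 4)

  expect_error(ns_score_diets(intake("p", "nope", 1, 1),
                              fake_scored("a", 1), fake_foods("a")),
               "unscored")
})

test_that("whole-grain density scales to a 10 MJ day", {
  # 100 g of a 50 g/100 g whole-grain food over a 10 MJ (10000 kJ) day
  d <- ns_score_diets(intake("p", "a", 100, 10000),
                      fake_scored("a", 1), fake_foods("a", wg = 50))
  expect_equal(d$wg_per_10mj, 50)
  expect_true(d$consumer_flag)
  # 60 g whole grain over a 5 MJ day scales to 120 g / 10 MJ
  d <- ns_score_diets(intake("p", "a", 120, 5000),
                      fake_scored("a", 1), fake_foods("a", wg = 50))
  expect_equal(d$wg_per_10mj, 120)
  # non-consumer flagged
  d <- ns_score_diets(intake("p", "a", 100, 8000),
                      fake_scored("a", 1), fake_foods("a", wg = 0))
  expect_equal(d$wg_per_10mj, 0)
  expect_false(d$consumer_flag)
})
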