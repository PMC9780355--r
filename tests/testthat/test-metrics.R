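test_that("auroc matches hand-computed and brute-force values", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auroc(c(3, 1, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")

  # exact agreement with the all-pairs oracle, including ties
  withr::with_seed(71, {
    for (rep in 1:20) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- sample(round(rnorm(n), 1))  # rounding induces ties
      expect_equal(auroc(scores, labels), auc_pairwise(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("auroc is rank-invariant and complement-symmetric", {
  withr::with_seed(72, {
    s <- rnorm(200)
    y <- rbinom(200, 1, 0.5)
  })
  a <- auroc(s, y)
  expect_equal(auroc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auroc(-s, y), 1 - a, tolerance = 1e-12)
  # and agrees with an independent ROC implementation
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                 direction = "<"))),
               tolerance = 1e-12)
})

test_that("mae matches arithmetic and the folded-Gaussian closed form", {
  expect_equal(mae(c(60, 70), c(60, 70)), 0)
  expect_equal(mae(c(60, 70), c(65, 65)), 5.0)
  withr::with_seed(73, x <- rnorm(50000, 66, 16))
  expect_lt(abs(mae(rep(66, 50000), x) - 16 * sqrt(2 / pi)),
            4 * 16 * sqrt(1 - 2 / pi) / sqrt(50000))
})

test_that("bootstrap interval brackets the estimate and is stable in n_boot", {
  gs <- gaussian_scores(500, separation_for_auc(0.84), seed = 74)
  est <- auroc(gs$scores, gs$labels)
  ci_small <- bootstrap_ci(gs$scores, gs$labels, "auroc", n_boot = 1000,
                           seed = 1)
  ci_big <- bootstrap_ci(gs$scores, gs$labels, "auroc", n_boot = 10000,
                         seed = 2)
  expect_lte(ci_small[["ci_low"]], est)
  expect_gte(ci_small[["ci_high"]], est)
  expect_lt(max(abs(ci_small - ci_big)), 0.01)
})

test_that("perfectly separated scores collapse the interval at 1", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  ci <- bootstrap_ci(scores, labels, "auroc", n_boot = 200, seed = 5)
  expect_equal(as.numeric(ci), c(1, 1))
})

test_that("eval_result returns one tidy row with a contained estimate", {
  gs <- gaussian_scores(400, 1.2, seed = 75)
  df <- tibble::tibble(truth = gs$labels, score = gs$scores)
  res <- eval_result(df, "truth", "score", "auroc", n_boot = 500, seed = 3)
  expect_identical(nrow(res), 1L)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  expect_identical(res$n, 400L)
})

test_that("cohort summary reports exact counts and one-decimal percentages", {
  pop <- tibble::tibble(
    patient_id = as.character(1:1000),
    sex = rep(c(1L, 0L), c(552, 448)),
    age = rep(c(70, 50), c(600, 400)),
    age_group = rep(c(1L, 0L), c(600, 400)),
    race = rep(c(1L, 0L), c(687, 313))
  )
  s <- cohort_summary(pop)
  expect_identical(s$count[s$statistic == "male"], 552L)
  expect_identical(s$pct[s$statistic == "male"], 55.2)
  expect_identical(s$pct[s$statistic == "white"], 68.7)
  # empty stratum: zero count, 0.0%
  s0 <- cohort_summary(dplyr::mutate(pop, race = 0L))
  expect_identical(s0$count[s0$statistic == "white"], 0L)
  expect_identical(s0$pct[s0$statistic == "white"], 0)
  expect_error(cohort_summary(pop[0, ]), "empty")
})
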