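test_that("classifier separates a linearly separable toy exactly", {
  toy <- tibble::tibble(
    toy_f1 = c(-1, -1, 1, 1),
    toy_f2 = c(-1, 1, -1, 1),
    y = c(0, 0, 1, 1)
  )
  sc <- suppressWarnings(fit_classifier(toy, "y"))  # glmnet small-class note
  expect_equal(auroc(predict(sc, toy), toy$y), 1.0)
})

test_that("classifier is at chance on zero-signal features", {
  train <- small_population(4000, seed = 31)
  test <- small_population(4000, seed = 32)
  sc <- fit_classifier(train, "race")
  emp <- auroc(predict(sc, test), test$race)
  se <- hanley_se(0.52, sum(test$race == 1), sum(test$race == 0))
  expect_lt(abs(emp - 0.5), 3 * se)
})

test_that("classifier recovers the calibrated sex AUROC on unbiased cohorts", {
  d <- separation_for_auc(0.84)
  train <- small_population(4000, d_sex = d, seed = 33)
  test <- small_population(4000, d_sex = d, seed = 34)
  sc <- fit_classifier(train, "sex")
  expect_lt(abs(auroc(predict(sc, test), test$sex) - 0.84), 0.02)
})

test_that("fitted direction aligns with the true signal direction", {
  train <- small_population(10000, d_sex = 1.0, seed = 35)
  sc <- fit_classifier(train, "sex")
  w <- unname(sc$coef)
  truth <- c(1, rep(0, length(w) - 1))  # sex occupies axis 1
  cosine <- sum(w * truth) / sqrt(sum(w^2))
  expect_gt(cosine, 0.95)
})

test_that("classifier training is deterministic and rejects bad input", {
  train <- small_population(500, d_sex = 1, seed = 36)
  expect_identical(fit_classifier(train, "sex"), fit_classifier(train, "sex"))
  one_class <- dplyr::mutate(train, sex = 1L)
  expect_error(fit_classifier(one_class, "sex"), "each class")
  bad <- train
  bad$a4c_f1[1] <- Inf
  expect_error(fit_classifier(bad, "sex"), "finite")
})

test_that("regressor attains the analytic MAE limits", {
  # noiseless linear target -> essentially zero error
  withr::with_seed(41, {
    n <- 2000
    df <- tibble::tibble(v_f1 = rnorm(n), v_f2 = rnorm(n), v_f3 = rnorm(n))
    df$age <- 50 + 4 * df$v_f1 - 2 * df$v_f3
  })
  rg <- fit_regressor(df[1:1000, ], "age")
  expect_lt(mae(predict(rg, df[1001:2000, ]), df$age[1001:2000]), 0.05)

  # Gaussian residual sigma -> test MAE near sigma * sqrt(2 / pi)
  sigma <- 5
  withr::with_seed(42, {
    n <- 20000
    df <- tibble::tibble(v_f1 = rnorm(n), v_f2 = rnorm(n), v_f3 = rnorm(n))
    df$age <- 60 + 3 * df$v_f1 + rnorm(n, sd = sigma)
  })
  rg <- fit_regressor(df[1:10000, ], "age")
  got <- mae(predict(rg, df[10001:20000, ]), df$age[10001:20000])
  limit <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(10000)
  expect_lt(abs(got - limit), 4 * se)

  # no signal -> no better than predicting the training mean
  withr::with_seed(43, {
    df <- tibble::tibble(v_f1 = rnorm(4000), v_f2 = rnorm(4000),
                         v_f3 = rnorm(4000), age = rnorm(4000, 66, 16))
  })
  rg <- fit_regressor(df[1:2000, ], "age")
  test <- df[2001:4000, ]
  got <- mae(predict(rg, test), test$age)
  const <- mae(rep(mean(df$age[1:2000]), 2000), test$age)
  expect_lt(abs(got - const), 0.5)
})

test_that("view ensemble combines independent views as theory predicts", {
  d <- 0.7
  withr::with_seed(51, {
    n <- 20000
    y <- rep(0:1, each = n / 2)
    scores <- tibble::as_tibble(
      stats::setNames(lapply(1:4, function(v) d * (y - 0.5) + rnorm(n)),
                      paste0("view", 1:4)))
    scores$y <- y
  })
  half <- seq(1, nrow(scores), by = 2)  # interleave so both halves see both classes
  ens <- fit_view_ensemble(scores[half, ], "y", paste0("view", 1:4))
  emp <- auroc(predict(ens, scores[-half, ]), scores$y[-half])
  # four independent unit-noise copies halve the noise SD: separation doubles
  truth <- auc_for_separation(2 * d)
  expect_lt(abs(emp - truth), 3 * hanley_se(truth, 5000, 5000))

  # one informative view plus pure noise views adds nothing
  withr::with_seed(52, {
    scores2 <- tibble::tibble(
      view1 = d * (y - 0.5) + rnorm(n),
      view2 = rnorm(n), view3 = rnorm(n), view4 = rnorm(n), y = y)
  })
  ens2 <- fit_view_ensemble(scores2[half, ], "y", paste0("view", 1:4))
  emp2 <- auroc(predict(ens2, scores2[-half, ]), scores2$y[-half])
  single <- auroc(scores2$view1[-half], scores2$y[-half])
  expect_lt(abs(emp2 - single), 3 * hanley_se(single, 5000, 5000))

  # a single-view ensemble is a monotone transform: identical AUROC
  ens3 <- fit_view_ensemble(scores2[half, ], "y", "view1")
  expect_equal(auroc(predict(ens3, scores2[-half, ]), scores2$y[-half]),
               single, tolerance = 1e-12)
})

test_that("scorers survive a JSON round trip", {
  train <- small_population(500, d_sex = 1, seed = 61)
  sc <- fit_classifier(train, "sex")
  path <- withr::local_tempfile(fileext = ".json")
  write_scorer(sc, path)
  back <- read_scorer(path)
  expect_equal(predict(back, train), predict(sc, train), tolerance = 1e-12)
  expect_identical(back$target, "sex")
  td <- tidy(sc)
  expect_identical(td$term[1], "(Intercept)")
  expect_identical(nrow(td), length(sc$features) + 1L)
  expect_identical(glance(sc)$kind, "classifier")
})
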