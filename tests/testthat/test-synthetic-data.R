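test_that("separation/AUC calibration is the Gaussian closed form and inverts", {
  expect_identical(separation_for_auc(0.5), 0)
  expect_equal(separation_for_auc(0.84), 1.4064, tolerance = 1e-4)
  expect_equal(separation_for_auc(0.85), 1.4657, tolerance = 1e-4)
  expect_equal(auc_for_separation(0), 0.5)
  expect_gt(auc_for_separation(6), 0.999)
  # monotone and mutually inverse on a grid
  grid <- seq(0.5, 0.99, by = 0.01)
  d <- separation_for_auc(grid)
  expect_true(all(diff(d) > 0))
  expect_equal(auc_for_separation(d), grid, tolerance = 1e-10)
  expect_error(separation_for_auc(1.0), "0.5")
  expect_error(separation_for_auc(0.4), "0.5")
  expect_error(auc_for_separation(-0.1), "nonnegative")
})

test_that("regeneration with the same spec is bit-identical", {
  spec <- population_spec(500, d_sex = 1.2, seed = 42)
  expect_identical(generate_population(spec), generate_population(spec))
  # a different seed changes the draw
  spec2 <- population_spec(500, d_sex = 1.2, seed = 43)
  expect_false(identical(generate_population(spec2),
                         generate_population(spec)))
})

test_that("demographic marginals and the age binarization are honoured", {
  n <- 20000
  pop <- generate_population(
    population_spec(n, p_male = 0.557, p_old = 0.53, seed = 9),
    comorbidities = FALSE
  )
  expect_identical(pop$age_group, as.integer(pop$age >= 65))
  expect_true(all(pop$age >= 18 & pop$age <= 100))
  expect_false(anyDuplicated(pop$patient_id) > 0)
  sd_male <- sqrt(0.557 * 0.443 / n)
  expect_lt(abs(mean(pop$sex) - 0.557), 3 * sd_male)
  expect_lt(abs(mean(pop$age_group) - 0.53), 3 * sqrt(0.53 * 0.47 / n))
})

test_that("oracle projection hits the calibrated AUROC across separations", {
  n <- 20000
  for (d in c(0, 0.5, 1.0, 1.4064, 2.0)) {
    pop <- generate_population(
      population_spec(n, d_sex = d, views = "a4c", seed = 100 + round(d * 10)),
      comorbidities = FALSE
    )
    emp <- auroc(oracle_score(pop, "sex"), pop$sex)
    truth <- auc_for_separation(d)
    se <- hanley_se(max(truth, 0.52), sum(pop$sex == 1), sum(pop$sex == 0))
    expect_lt(abs(emp - truth), 3 * se)
  }
})

test_that("zero-separation features carry no demographic signal", {
  pop <- small_population(8000, seed = 5)
  # even the oracle direction is at chance when d = 0
  for (attr in c("sex", "age_group", "race")) {
    emp <- auroc(oracle_score(pop, attr), pop[[attr]])
    se <- hanley_se(0.52, sum(pop[[attr]] == 1), sum(pop[[attr]] == 0))
    expect_lt(abs(emp - 0.5), 3 * se)
  }
})

test_that("comorbidity draws match the stratum prevalences", {
  tab <- comorbidity_prevalences()
  expect_identical(nrow(tab), 17L)
  expect_true(all(tab$p_white >= 0 & tab$p_white <= 1))

  n <- 1e5
  whites <- tibble::tibble(patient_id = as.character(seq_len(n)),
                           race = rep(1L, n))
  cw <- generate_comorbidities(whites, tab, seed = 21)
  # hypertension is condition 3 in the packaged table
  expect_identical(tab$condition[3], "hypertension")
  expect_lt(abs(mean(cw$c03) - 0.5996), 3 * sqrt(0.5996 * 0.4004 / n))
  # law of large numbers across every condition in the white stratum
  for (k in seq_len(nrow(tab))) {
    p <- tab$p_white[k]
    tol <- 3 * sqrt(p * (1 - p) / n) + 1e-12
    expect_lt(abs(mean(cw[[sprintf("c%02d", k)]]) - p), tol)
  }

  blacks <- tibble::tibble(patient_id = as.character(seq_len(n)),
                           race = rep(0L, n),
                           stratum = "black")
  cb <- generate_comorbidities(blacks, tab, seed = 22)
  expect_identical(tab$condition[14], "chronic_kidney_disease")
  expect_lt(abs(mean(cb$c14) - 0.4110), 3 * sqrt(0.411 * 0.589 / n))
})

test_that("zero prevalence yields an all-zero condition column", {
  tab <- comorbidity_prevalences()
  tab$p_white[1] <- 0
  pop <- tibble::tibble(patient_id = as.character(1:200), race = 1L)
  out <- generate_comorbidities(pop, tab, seed = 3)
  expect_true(all(out$c01 == 0))
})

test_that("population spec rejects invalid parameters", {
  expect_error(population_spec(100, feature_dim = 2), "feature_dim")
  expect_error(population_spec(100, p_male = 1.2), "probability")
  expect_error(population_spec(0), "n_patients")
  expect_error(population_spec(100, d_sex = -1), "nonnegative")
})
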