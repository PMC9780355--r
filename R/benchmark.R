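#' Benchmark race prediction from comorbidity data alone
#'
#' Population-level comorbidity rates differ by race, so a model that can
#' detect comorbidities can "shortcut" to race without any race-specific
#' signal.  This benchmark quantifies that ceiling from a prevalence table:
#' it simulates a cohort whose comorbidities are drawn at the
#' race-stratified marginal prevalences (independently across conditions,
#' since only marginals are recorded), fits a logistic regression
#' predicting white vs non-white, and reports the held-out AUROC with a
#' percentile bootstrap interval.  Age and sex can be included as
#' additional covariates; by default they are simulated independently of
#' race and therefore contribute no signal.
#'
#' Because real comorbidities are correlated while the simulation is
#' independent given race, the result brackets rather than reproduces the
#' AUROC obtainable on real records.
#'
#' @param prevalence Prevalence table as from [comorbidity_prevalences()].
#' @param n Cohort size (at least 1000).
#' @param p_white Fraction of the simulated cohort that is white.
#' @param p_black Probability a non-white patient is in the black stratum.
#' @param include_age_sex Add age and sex as covariates (default `TRUE`).
#' @param p_male,age_mean,age_sd Marginals used to simulate sex and age.
#' @param train_frac Fraction of the cohort used for fitting.
#' @param n_boot,level Bootstrap replicates and confidence level.
#' @param seed Integer seed.
#'
#' @return A one-row tibble as from [eval_result()], with additional
#'   columns `n_train`, `n_test`, `include_age_sex`.
#' @export
#' @examples
#' run_comorbidity_benchmark(n = 5000, n_boot = 200, seed = 7)
run_comorbidity_benchmark <- function(prevalence = comorbidity_prevalences(),
                                      n = 50000,
                                      p_white = 0.688,
                                      p_black = 4058 / (4058 + 2162),
                                      include_age_sex = TRUE,
                                      p_male = 0.552,
                                      age_mean = 66.5,
                                      age_sd = 16.5,
                                      train_frac = 0.7,
                                      n_boot = 1000,
                                      level = 0.95,
                                      seed = 1L) {
  n <- check_count(n, "n", min = 1000L)
  check_prob(p_white, "p_white")
  if (p_white <= 0 || p_white >= 1) {
    stop("`p_white` must be strictly inside (0, 1): both race classes ",
         "must be possible.", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 4L)
  cohort <- withr::with_seed(seeds[1], {
    tibble::tibble(
      patient_id = sprintf("P%07d", seq_len(n)),
      race = stats::rbinom(n, 1L, p_white),
      sex = stats::rbinom(n, 1L, p_male),
      age = rtruncnorm(n, age_mean, age_sd, 18, 100)
    )
  })
  if (length(unique(cohort$race)) < 2L) {
    stop("simulated cohort is single-race; increase `n` or adjust ",
         "`p_white`.", call. = FALSE)
  }
  cohort <- generate_comorbidities(cohort, prevalence = prevalence,
                                   p_black = p_black, seed = seeds[2])
  cols <- sprintf("c%02d", seq_len(nrow(prevalence)))
  if (include_age_sex) cols <- c(cols, "age", "sex")

  split <- split_by_patient(cohort,
                            c(train = train_frac, test = 1 - train_frac),
                            seed = seeds[3])
  cohort <- dplyr::left_join(cohort, split, by = "patient_id")
  train <- dplyr::filter(cohort, .data$partition == "train")
  test <- dplyr::filter(cohort, .data$partition == "test")

  fml <- stats::reformulate(cols, response = "race")
  fit <- stats::glm(fml, data = train, family = stats::binomial())
  test$score <- stats::predict(fit, newdata = test, type = "link")

  res <- eval_result(test, truth = "race", estimate = "score",
                     metric = "auroc", n_boot = n_boot, level = level,
                     seed = seeds[4])
  user_seed <- as.integer(seed)
  dplyr::mutate(res, n_train = nrow(train), n_test = nrow(test),
                include_age_sex = include_age_sex, seed = user_seed)
}
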