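#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties credited one half — computed from midranks,
#' which is exactly the normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(3, 1, 2, 4), c(0, 0, 1, 1))  # 0.75
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("missing values.", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1.", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present.", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean absolute error
#'
#' @param predictions,actuals Equal-length numeric vectors (years, for the
#'   age task).
#' @return Mean of absolute residuals.
#' @export
mae <- function(predictions, actuals) {
  stopifnot(length(predictions) == length(actuals), length(actuals) > 0)
  if (anyNA(predictions) || anyNA(actuals)) {
    stop("missing values.", call. = FALSE)
  }
  mean(abs(predictions - actuals))
}

#' Percentile bootstrap confidence interval for a test-set metric
#'
#' Resamples test records (patients) with replacement `n_boot` times,
#' recomputes the metric on each replicate, and returns the percentile
#' interval.  For AUROC, a replicate that happens to contain a single class
#' is redrawn (up to `max_retries` attempts per replicate); the number of
#' redraws is recorded in the `"n_redrawn"` attribute.
#'
#' @param scores Scores (or predictions, for `mae`).
#' @param labels Binary labels (or actual values, for `mae`).
#' @param metric `"auroc"` or `"mae"`.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param max_retries Redraw cap per single-class replicate.
#' @return Named numeric `c(ci_low, ci_high)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(scores, labels, metric = c("auroc", "mae"),
                         n_boot = 10000, level = 0.95, seed = 1L,
                         max_retries = 100L) {
  metric <- match.arg(metric)
  n <- length(labels)
  stopifnot(length(scores) == n, n > 0)
  fn <- if (metric == "auroc") auroc else mae
  fn(scores, labels)  # validate once on the full sample
  redrawn <- 0L
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      for (try in seq_len(max_retries)) {
        i <- sample.int(n, n, replace = TRUE)
        if (metric == "mae" ||
            (any(labels[i] == 1) && any(labels[i] == 0))) {
          if (try > 1L) redrawn <<- redrawn + (try - 1L)
          return(fn(scores[i], labels[i]))
        }
      }
      stop("could not draw a two-class bootstrap replicate.", call. = FALSE)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(c(ci_low = ci[1], ci_high = ci[2]), n_redrawn = redrawn)
}

#' Evaluate scores against truth with a bootstrap interval
#'
#' Convenience wrapper producing one tidy row: the point estimate on the
#' full test set plus its percentile bootstrap interval.
#'
#' @param data Data frame of test records.
#' @param truth,estimate Column names (strings) of the true labels/values
#'   and the scores/predictions.
#' @param metric `"auroc"` or `"mae"`.
#' @inheritParams bootstrap_ci
#' @return One-row tibble: `metric`, `estimate`, `ci_low`, `ci_high`,
#'   `n`, `n_boot`, `seed`.
#' @export
eval_result <- function(data, truth, estimate, metric = c("auroc", "mae"),
                        n_boot = 10000, level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(data), truth %in% names(data),
            estimate %in% names(data))
  y <- data[[truth]]
  s <- data[[estimate]]
  fn <- if (metric == "auroc") auroc else mae
  point <- fn(s, y)
  ci <- bootstrap_ci(s, y, metric = metric, n_boot = n_boot, level = level,
                     seed = seed)
  tibble::tibble(metric = metric, estimate = point,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 n = nrow(data), n_boot = as.integer(n_boot),
                 seed = as.integer(seed))
}

#' Demographic summary of a population or cohort
#'
#' A cohort-characteristics table in the style of a study's Table 1:
#' patient count, mean and SD of age, and counts with percentages for the
#' binary demographics.  Percentages are rounded to one decimal place;
#' counts are exact.
#'
#' @param data Population data frame with `sex`, `age`, `age_group`,
#'   `race` columns (missing columns are skipped).
#' @return A tibble `statistic`, `value`, `count`, `pct`.
#' @export
#' @examples
#' pop <- generate_population(population_spec(500))
#' cohort_summary(pop)
cohort_summary <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("population is empty.", call. = FALSE)
  n <- nrow(data)
  pct1 <- function(count) round(100 * count / n, 1)
  rows <- list(
    tibble::tibble(statistic = "n_patients", value = n,
                   count = n, pct = NA_real_)
  )
  if ("age" %in% names(data)) {
    rows <- c(rows, list(
      tibble::tibble(statistic = c("age_mean", "age_sd"),
                     value = c(mean(data$age), stats::sd(data$age)),
                     count = NA_integer_, pct = NA_real_)))
  }
  bin <- c(male = "sex", age_65_plus = "age_group", white = "race")
  for (nm in names(bin)) {
    col <- bin[[nm]]
    if (col %in% names(data)) {
      k <- sum(data[[col]] == 1)
      rows <- c(rows, list(
        tibble::tibble(statistic = nm, value = k / n, count = k,
                       pct = pct1(k))))
    }
  }
  dplyr::bind_rows(rows)
}
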