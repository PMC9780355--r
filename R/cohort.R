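#' Split a population into train/validation/test by patient
#'
#' Every patient lands in exactly one partition, so no patient contributes
#' records to more than one split (leakage control).  Allocation is
#' deterministic given the seed: patients are shuffled once and partition
#' sizes are fixed by largest-remainder apportionment of the fractions, so
#' sizes are exact, not merely expected.
#'
#' @param data Population data frame with a `patient_id` column.
#' @param fractions Numeric vector of partition fractions, named or in
#'   (train, val, test) order; must be nonnegative and sum to 1.
#' @param seed Integer seed.
#'
#' @return A tibble `patient_id`, `partition` (factor train/val/test).
#' @export
#' @examples
#' pop <- generate_population(population_spec(100))
#' split <- split_by_patient(pop, c(train = 0.8, val = 0.1, test = 0.1))
#' table(split$partition)
split_by_patient <- function(data, fractions = c(train = 0.7, val = 0.1,
                                                 test = 0.2),
                             seed = 1L) {
  stopifnot(is.data.frame(data), "patient_id" %in% names(data))
  if (nrow(data) == 0L) stop("population is empty.", call. = FALSE)
  if (anyDuplicated(data$patient_id)) {
    stop("`patient_id` values must be unique.", call. = FALSE)
  }
  if (is.null(names(fractions))) {
    names(fractions) <- c("train", "val", "test")[seq_along(fractions)]
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be nonnegative and sum to 1.", call. = FALSE)
  }
  sizes <- largest_remainder(fractions, nrow(data))
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(data$patient_id)
    tibble::tibble(
      patient_id = shuffled,
      partition = factor(rep(names(fractions), times = sizes),
                         levels = names(fractions))
    )
  })
}

#' Construct a fixed-size training cohort with controlled confounder bias
#'
#' Realizes the bias parameter `b` coupling a binary label to a binary
#' confounder: among label-positive members a fraction `b` has the
#' confounder's aligned value (confounder = 1), among label-negative
#' members that fraction is `1 - b`.  At `b = 0.5` the confounder is
#' balanced within both label groups; at `b = 1` the label and confounder
#' coincide on every cohort member.  The cohort size is exactly `n_train`
#' for every bias, label prevalence is `label_balance`, and fractional cell
#' counts are resolved by largest-remainder rounding so no count is off by
#' more than one.  Sampling within each (label, confounder) cell is uniform
#' without replacement.
#'
#' @param data Population data frame containing the label and confounder
#'   columns (binary 0/1).
#' @param label,confounder Column names, e.g. `"race"` and `"sex"`;
#'   must differ.
#' @param bias Real in `[0.5, 1]`.
#' @param n_train Exact cohort size.
#' @param label_balance Fraction of the cohort with label = 1 (default 0.5).
#' @param seed Integer seed.
#'
#' @return A tibble of the sampled rows of `data`, with a `"composition"`
#'   attribute (tibble of label level, confounder level, target count) and
#'   class `biased_cohort`.  If a cell of the population cannot supply its
#'   count, an error names the deficient cell.
#' @export
#' @examples
#' pop <- generate_population(population_spec(4000))
#' coh <- construct_biased_cohort(pop, "race", "sex", bias = 0.8,
#'                                n_train = 1000)
#' cohort_composition(coh)
construct_biased_cohort <- function(data, label, confounder, bias, n_train,
                                    label_balance = 0.5, seed = 1L) {
  stopifnot(is.data.frame(data))
  if (!is.character(label) || !is.character(confounder) ||
      !label %in% names(data) || !confounder %in% names(data)) {
    stop("`label` and `confounder` must name columns of `data`.",
         call. = FALSE)
  }
  if (identical(label, confounder)) {
    stop("`label` and `confounder` must differ.", call. = FALSE)
  }
  if (!is.numeric(bias) || length(bias) != 1L || bias < 0.5 || bias > 1) {
    stop("`bias` must lie in [0.5, 1].", call. = FALSE)
  }
  n_train <- check_count(n_train, "n_train")
  check_prob(label_balance, "label_balance")

  n_lab <- largest_remainder(c(label_balance, 1 - label_balance), n_train)
  # cells ordered (label, confounder): (1,1), (1,0), (0,1), (0,0)
  cells <- tibble::tibble(
    label_value = c(1L, 1L, 0L, 0L),
    confounder_value = c(1L, 0L, 1L, 0L),
    n = c(largest_remainder(c(bias, 1 - bias), n_lab[1]),
          largest_remainder(c(1 - bias, bias), n_lab[2]))
  )

  lab <- data[[label]]
  conf <- data[[confounder]]
  picked <- withr::with_seed(as.integer(seed), {
    idx <- purrr::pmap(cells, function(label_value, confounder_value, n) {
      pool <- which(lab == label_value & conf == confounder_value)
      if (length(pool) < n) {
        stop(sprintf(
          "cell %s=%d & %s=%d has %d patients but %d are required.",
          label, label_value, confounder, confounder_value, length(pool), n),
          call. = FALSE)
      }
      pool[sample.int(length(pool), n)]
    })
    unlist(idx)
  })
  out <- dplyr::slice(tibble::as_tibble(data), picked)
  attr(out, "composition") <- cells
  attr(out, "bias_spec") <- list(label = label, confounder = confounder,
                                 bias = bias, n_train = n_train,
                                 label_balance = label_balance,
                                 seed = as.integer(seed))
  class(out) <- c("biased_cohort", class(out))
  out
}

#' Target cell composition of a biased cohort
#'
#' @param cohort A cohort from [construct_biased_cohort()].
#' @return Tibble with columns `label_value`, `confounder_value`, `n`.
#' @export
cohort_composition <- function(cohort) {
  comp <- attr(cohort, "composition")
  if (is.null(comp)) stop("not a biased cohort.", call. = FALSE)
  comp
}
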