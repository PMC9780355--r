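#' Specify a synthetic echo-style patient population
#'
#' A `population_spec` fixes every parameter of the synthetic cohort
#' generator: the demographic marginals, the age distribution, and the
#' per-attribute Gaussian feature signal that stands in for whatever an
#' imaging model could learn about each attribute.  Signal strength is
#' expressed as the standardized separation `d` between the two
#' class-conditional feature means along a fixed direction, with unit
#' isotropic noise, so a linear scorer along that direction has
#' AUROC = pnorm(d / sqrt(2)).  `d = 0` means the attribute leaves no trace
#' in the features at all.
#'
#' @param n_patients Number of patients to generate.
#' @param p_male,p_white,p_old Marginal probabilities of `sex = 1` (male),
#'   `race = 1` (white), and `age_group = 1` (age 65 or older).
#' @param age_mean,age_sd Mean and SD (years) of the underlying Normal age
#'   distribution, truncated to `[18, 100]` and sampled conditionally on
#'   `age_group` so that `age_group == (age >= 65)` holds exactly.
#' @param feature_dim Length of the feature vector per view; at least 3 so
#'   sex, age and race can occupy orthogonal directions.
#' @param views Character vector of view names (echocardiographic windows);
#'   each view gets its own feature block.
#' @param d_sex,d_age,d_race Standardized signal separations, either a
#'   single value shared by all views or a vector named by view.
#' @param seed Integer seed; regeneration with the same spec is bit-identical.
#'
#' @return An object of class `population_spec`.
#' @seealso [generate_population()], [separation_for_auc()]
#' @export
#' @examples
#' spec <- population_spec(1000, d_sex = separation_for_auc(0.84))
#' pop <- generate_population(spec)
population_spec <- function(n_patients,
                            p_male = 0.5,
                            p_white = 0.5,
                            p_old = 0.5,
                            age_mean = 66.5,
                            age_sd = 16.4,
                            feature_dim = 8,
                            views = c("a4c", "a2c", "plax", "subcostal"),
                            d_sex = 0,
                            d_age = 0,
                            d_race = 0,
                            seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  check_prob(p_male, "p_male")
  check_prob(p_white, "p_white")
  check_prob(p_old, "p_old")
  feature_dim <- check_count(feature_dim, "feature_dim", min = 3L)
  stopifnot(is.character(views), length(views) >= 1L, !anyDuplicated(views))
  expand_d <- function(d, name) {
    if (length(d) == 1L && is.null(names(d))) {
      d <- stats::setNames(rep(as.numeric(d), length(views)), views)
    }
    if (!all(views %in% names(d))) {
      stop(sprintf("`%s` must be a scalar or named per view.", name),
           call. = FALSE)
    }
    d <- d[views]
    if (any(d < 0)) stop(sprintf("`%s` must be nonnegative.", name),
                         call. = FALSE)
    d
  }
  spec <- structure(
    list(
      n_patients = n_patients, p_male = p_male, p_white = p_white,
      p_old = p_old, age_mean = age_mean, age_sd = age_sd,
      feature_dim = feature_dim, views = views,
      d_sex = expand_d(d_sex, "d_sex"),
      d_age = expand_d(d_age, "d_age"),
      d_race = expand_d(d_race, "d_race"),
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
  spec
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat(sprintf("  n_patients: %d   p_male: %.3f  p_white: %.3f  p_old: %.3f\n",
              x$n_patients, x$p_male, x$p_white, x$p_old))
  cat(sprintf("  age: Normal(%.1f, %.1f) truncated [18, 100], cut at 65\n",
              x$age_mean, x$age_sd))
  cat(sprintf("  views: %s  (feature_dim %d)\n",
              paste(x$views, collapse = ", "), x$feature_dim))
  cat(sprintf("  d_sex: %s  d_age: %s  d_race: %s   seed: %d\n",
              paste(signif(x$d_sex, 4), collapse = "/"),
              paste(signif(x$d_age, 4), collapse = "/"),
              paste(signif(x$d_race, 4), collapse = "/"),
              x$seed))
  invisible(x)
}

# Normal(mean, sd) truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Attributes occupy fixed orthonormal directions within each view's feature
# block: sex -> axis 1, age_group -> axis 2, race -> axis 3.
signal_axis <- c(sex = 1L, age_group = 2L, race = 3L)

#' Generate a synthetic patient population
#'
#' Draws demographics independently at the specified marginals, ages from the
#' truncated Normal conditional on the age group (so the 65-year binarization
#' is exact), optional comorbidities from a race-stratified prevalence
#' table, and per-view feature vectors.  Within each view, the features are
#' `d_sex * s * e1 + d_age * a * e2 + d_race * r * e3` plus isotropic
#' standard Gaussian noise, where `s`, `a`, `r` are the plus/minus-half
#' codings of sex, age group and race and `e1..e3` are the first three
#' coordinate axes of the feature block.
#'
#' @param spec A [population_spec()].
#' @param comorbidities Logical; if `TRUE` (default) comorbidity columns
#'   `c01..c17` are drawn via [generate_comorbidities()].
#' @param prevalence Prevalence table passed on to
#'   [generate_comorbidities()]; defaults to the packaged table.
#'
#' @return A tibble with one row per patient: `patient_id`, `sex`, `age`,
#'   `age_group`, `race`, optional `c01..c17`, and `<view>_f1..fK` feature
#'   columns.
#' @export
generate_population <- function(spec,
                                comorbidities = TRUE,
                                prevalence = comorbidity_prevalences()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_patients
  seeds <- derive_seeds(spec$seed, 3L)
  pop <- withr::with_seed(seeds[1], {
    sex <- stats::rbinom(n, 1L, spec$p_male)
    race <- stats::rbinom(n, 1L, spec$p_white)
    age_group <- stats::rbinom(n, 1L, spec$p_old)
    age <- numeric(n)
    old <- age_group == 1L
    age[old] <- rtruncnorm(sum(old), spec$age_mean, spec$age_sd, 65, 100)
    age[!old] <- rtruncnorm(sum(!old), spec$age_mean, spec$age_sd, 18, 65)
    tibble::tibble(
      patient_id = sprintf("P%07d", seq_len(n)),
      sex = sex, age = age, age_group = age_group, race = race
    )
  })
  if (isTRUE(comorbidities)) {
    pop <- generate_comorbidities(pop, prevalence = prevalence,
                                  seed = seeds[2])
  }
  feats <- withr::with_seed(seeds[3], {
    s <- pop$sex - 0.5
    a <- pop$age_group - 0.5
    r <- pop$race - 0.5
    blocks <- lapply(spec$views, function(v) {
      X <- matrix(stats::rnorm(n * spec$feature_dim), n, spec$feature_dim)
      X[, 1] <- X[, 1] + spec$d_sex[[v]] * s
      X[, 2] <- X[, 2] + spec$d_age[[v]] * a
      X[, 3] <- X[, 3] + spec$d_race[[v]] * r
      colnames(X) <- sprintf("%s_f%d", v, seq_len(spec$feature_dim))
      X
    })
    do.call(cbind, blocks)
  })
  dplyr::bind_cols(pop, tibble::as_tibble(feats))
}

#' Race-stratified comorbidity prevalences
#'
#' The packaged table of 17 cardiovascular and systemic comorbidity
#' prevalences by race stratum (white / black / asian), as proportions.
#'
#' @return A tibble with columns `condition`, `p_white`, `p_black`, `p_asian`.
#' @export
comorbidity_prevalences <- function() {
  path <- system.file("extdata", "comorbidity_prevalence.csv",
                      package = "shortcutsim", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("condition", "p_white", "p_black", "p_asian") %in%
                  names(tab)))
  tab
}

#' Draw comorbidity indicators from race-stratified prevalences
#'
#' Each condition is drawn Bernoulli at the prevalence of the patient's
#' stratum, independently across conditions and patients (the table records
#' only marginals, so no dependence structure is imposed).  White patients
#' use the white stratum; non-white patients are assigned to the black or
#' asian stratum, by default at the relative frequency of those groups in
#' the source cohort.
#'
#' @param data A data frame with a binary `race` column (1 = white), and
#'   optionally a `stratum` column (`"white"`, `"black"` or `"asian"`) that
#'   overrides the random stratum assignment.
#' @param prevalence A prevalence table as from [comorbidity_prevalences()].
#' @param p_black Probability that a non-white patient belongs to the black
#'   stratum (the remainder is asian).  Default 4058 / (4058 + 2162), the
#'   relative group sizes in the source cohort.
#' @param seed Integer seed.
#'
#' @return `data` with binary columns `c01..cNN` appended, one per
#'   condition, in the prevalence table's row order.
#' @export
generate_comorbidities <- function(data,
                                   prevalence = comorbidity_prevalences(),
                                   p_black = 4058 / (4058 + 2162),
                                   seed = 1L) {
  stopifnot(is.data.frame(data), "race" %in% names(data))
  stopifnot(all(prevalence$p_white >= 0 & prevalence$p_white <= 1),
            all(prevalence$p_black >= 0 & prevalence$p_black <= 1),
            all(prevalence$p_asian >= 0 & prevalence$p_asian <= 1))
  n <- nrow(data)
  k <- nrow(prevalence)
  P <- rbind(white = prevalence$p_white,
             black = prevalence$p_black,
             asian = prevalence$p_asian)
  withr::with_seed(as.integer(seed), {
    if ("stratum" %in% names(data)) {
      stratum <- data$stratum
      if (!all(stratum %in% rownames(P))) {
        stop("`stratum` values must be white, black or asian.", call. = FALSE)
      }
    } else {
      stratum <- ifelse(data$race == 1L, "white",
                        ifelse(stats::runif(n) < p_black, "black", "asian"))
    }
    probs <- P[stratum, , drop = FALSE]
    M <- matrix(stats::rbinom(n * k, 1L, probs), n, k)
    colnames(M) <- sprintf("c%02d", seq_len(k))
    dplyr::bind_cols(data, tibble::as_tibble(M))
  })
}

#' Project features onto an attribute's true signal direction
#'
#' Oracle scorer for calibration checks: returns the component of each
#' patient's feature vector along the generative direction of `attribute`
#' in `view`.  When that attribute was generated with separation `d`, this
#' score has class-conditional unit-variance Gaussians with mean gap `d`,
#' hence AUROC `pnorm(d / sqrt(2))` — the best any scorer can do.
#'
#' @param data A population tibble from [generate_population()].
#' @param attribute One of `"sex"`, `"age_group"`, `"race"`.
#' @param view View name whose feature block to project.
#' @return Numeric score vector.
#' @export
oracle_score <- function(data, attribute = c("sex", "age_group", "race"),
                         view = "a4c") {
  attribute <- match.arg(attribute)
  col <- sprintf("%s_f%d", view, signal_axis[[attribute]])
  if (!col %in% names(data)) {
    stop(sprintf("column `%s` not found; was view '%s' generated?", col, view),
         call. = FALSE)
  }
  data[[col]]
}

#' Signal separation achieving a target AUROC
#'
#' Inverse of [auc_for_separation()]: the standardized mean gap `d` between
#' two unit-variance Gaussian score classes whose AUROC is `target_auc`,
#' i.e. `d = sqrt(2) * qnorm(target_auc)`.  Used to calibrate the synthetic
#' generator so a confounder task hits a prescribed AUROC.
#'
#' @param target_auc AUROC in `[0.5, 1)`.
#' @return Nonnegative separation in standardized units.
#' @export
#' @examples
#' separation_for_auc(0.84)  # 1.4064
separation_for_auc <- function(target_auc) {
  if (!is.numeric(target_auc) || any(is.na(target_auc)) ||
      any(target_auc < 0.5) || any(target_auc >= 1)) {
    stop("`target_auc` must lie in [0.5, 1).", call. = FALSE)
  }
  sqrt(2) * stats::qnorm(target_auc)
}
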