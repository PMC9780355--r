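#' Configure a bias-sweep experiment
#'
#' Fixes every parameter of a sweep in which a training cohort's
#' label-confounder bias is varied over a grid while the training-set size
#' is held constant, mirroring the design in which race prediction is
#' confounded by sex or age group.  The label may also be `"age"`, meaning
#' cohorts are biased on the 65-year age group but the model regresses
#' continuous age and is scored by MAE.
#'
#' @param label Task attribute: `"race"`, `"sex"`, `"age_group"` or
#'   `"age"`.
#' @param confounder Confounding attribute: `"race"`, `"sex"` or
#'   `"age_group"`; must differ from the (binarized) label.
#' @param bias_grid Bias values in `[0.5, 1]` (default 0.5 to 1 by 0.1).
#' @param n_train,n_test Exact cohort sizes, constant across the grid.
#' @param d_sex,d_age,d_race Feature signal separations (standardized
#'   units) for the generated population; see [population_spec()].
#' @param feature_dim,views Feature geometry of the generated population.
#' @param n_patients Population size to generate; default
#'   `6 * (n_train + n_test)`, large enough that every cell on the default
#'   marginals can fill the most extreme bias.
#' @param p_male,p_white,p_old Population marginals.
#' @param test_bias_mode `"same"` (test cohorts share the training bias;
#'   the closed-form shortcut prediction applies) or `"fixed"` (test
#'   cohorts always use `fixed_test_bias`).
#' @param fixed_test_bias Test bias used in `"fixed"` mode.
#' @param n_boot,level Bootstrap replicates and confidence level.
#' @param lambda Ridge penalty for the surrogate models.
#' @param seed Integer seed controlling every random draw in the sweep.
#'
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(label = "race",
                         confounder = "sex",
                         bias_grid = seq(0.5, 1, by = 0.1),
                         n_train = 4000,
                         n_test = 5000,
                         d_sex = 0,
                         d_age = 0,
                         d_race = 0,
                         feature_dim = 8,
                         views = "a4c",
                         n_patients = NULL,
                         p_male = 0.5,
                         p_white = 0.5,
                         p_old = 0.5,
                         test_bias_mode = c("same", "fixed"),
                         fixed_test_bias = 0.5,
                         n_boot = 1000,
                         level = 0.95,
                         lambda = 1e-3,
                         seed = 1L) {
  label <- match.arg(label, c("race", "sex", "age_group", "age"))
  confounder <- match.arg(confounder, c("race", "sex", "age_group"))
  bias_label <- if (label == "age") "age_group" else label
  if (identical(bias_label, confounder)) {
    stop("`label` and `confounder` must differ.", call. = FALSE)
  }
  if (any(bias_grid < 0.5) || any(bias_grid > 1) || length(bias_grid) < 1) {
    stop("`bias_grid` must lie within [0.5, 1].", call. = FALSE)
  }
  n_train <- check_count(n_train, "n_train")
  n_test <- check_count(n_test, "n_test")
  n_patients <- if (is.null(n_patients)) {
    6L * (n_train + n_test)
  } else {
    check_count(n_patients, "n_patients")
  }
  cfg <- list(
    label = label, confounder = confounder, bias_label = bias_label,
    bias_grid = as.numeric(bias_grid),
    n_train = n_train, n_test = n_test,
    d_sex = d_sex, d_age = d_age, d_race = d_race,
    feature_dim = check_count(feature_dim, "feature_dim", 3L),
    views = views, n_patients = n_patients,
    p_male = p_male, p_white = p_white, p_old = p_old,
    test_bias_mode = match.arg(test_bias_mode),
    fixed_test_bias = fixed_test_bias,
    n_boot = check_count(n_boot, "n_boot"), level = level,
    lambda = lambda, seed = as.integer(seed)
  )
  structure(cfg, class = "sweep_config")
}

#' Read a sweep configuration from a YAML file
#'
#' Fields map one-to-one onto the arguments of [sweep_config()]; unknown
#' fields are an error, and all domain checks of [sweep_config()] apply.
#'
#' @param path YAML file path.
#' @return A `sweep_config`.
#' @export
read_sweep_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configs.",
         call. = FALSE)
  }
  fields <- yaml::read_yaml(path)
  allowed <- names(formals(sweep_config))
  bad <- setdiff(names(fields), allowed)
  if (length(bad) > 0) {
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(sweep_config, fields)
}

# Signal separation of an attribute under a config.
config_d <- function(config, attribute) {
  switch(attribute, sex = config$d_sex, age_group = config$d_age,
         race = config$d_race,
         stop("no separation for attribute ", attribute, call. = FALSE))
}

#' Run a bias-sweep experiment
#'
#' For each bias on the grid: construct a training cohort of constant size
#' realizing that bias, fit the surrogate model for the label, score a
#' held-out test cohort (drawn from patients disjoint from training), and
#' record the metric with its bootstrap interval.  When the label carries
#' no direct feature signal and the test cohort shares the training bias,
#' the closed-form [shortcut_auc()] prediction is attached for comparison.
#' The whole sweep is deterministic given the config.
#'
#' @param config A [sweep_config()].
#' @param population Optional pre-generated population (a data frame); by
#'   default one is generated from the config.
#' @return A `shortcut_sweep` tibble: one row per bias with columns
#'   `bias`, `task`, `confounder`, `metric`, `estimate`, `ci_low`,
#'   `ci_high`, `predicted_auc`, `n_train`, `n_test`, `seed`.
#' @export
#' @examples
#' cfg <- sweep_config(n_train = 400, n_test = 400, n_boot = 100,
#'                     d_sex = separation_for_auc(0.84),
#'                     bias_grid = c(0.5, 1.0), seed = 3)
#' run_bias_sweep(cfg)
run_bias_sweep <- function(config, population = NULL) {
  stopifnot(inherits(config, "sweep_config"))
  nb <- length(config$bias_grid)
  seeds <- derive_seeds(config$seed, 2L + 3L * nb)
  if (is.null(population)) {
    spec <- population_spec(
      config$n_patients, p_male = config$p_male, p_white = config$p_white,
      p_old = config$p_old, feature_dim = config$feature_dim,
      views = config$views, d_sex = config$d_sex, d_age = config$d_age,
      d_race = config$d_race, seed = seeds[1]
    )
    population <- generate_population(spec, comorbidities = FALSE)
  }
  split <- split_by_patient(population, c(train = 0.5, test = 0.5),
                            seed = seeds[2])
  population <- dplyr::left_join(population, split, by = "patient_id")
  train_pool <- dplyr::filter(population, .data$partition == "train")
  test_pool <- dplyr::filter(population, .data$partition == "test")

  metric <- if (config$label == "age") "mae" else "auroc"
  d_conf <- config_d(config, config$confounder)
  d_label <- if (config$label == "age") NA_real_ else {
    config_d(config, config$bias_label)
  }

  rows <- purrr::map(seq_len(nb), function(i) {
    b <- config$bias_grid[i]
    s <- seeds[2L + 3L * (i - 1L) + 1:3]
    train <- construct_biased_cohort(
      train_pool, config$bias_label, config$confounder, b,
      config$n_train, seed = s[1])
    test_b <- if (config$test_bias_mode == "same") b else {
      config$fixed_test_bias
    }
    test <- construct_biased_cohort(
      test_pool, config$bias_label, config$confounder, test_b,
      config$n_test, seed = s[2])
    if (metric == "mae") {
      model <- fit_regressor(train, "age", lambda = config$lambda)
      test$.score <- predict(model, test)
      truth <- "age"
    } else {
      model <- fit_classifier(train, config$label, lambda = config$lambda)
      test$.score <- predict(model, test)
      truth <- config$label
    }
    res <- eval_result(test, truth = truth, estimate = ".score",
                       metric = metric, n_boot = config$n_boot,
                       level = config$level, seed = s[3])
    predicted <- if (metric == "auroc" && !is.na(d_label) && d_label == 0 &&
                     config$test_bias_mode == "same") {
      shortcut_auc(b, auc_for_separation(d_conf))
    } else {
      NA_real_
    }
    tibble::tibble(
      bias = b, task = config$label, confounder = config$confounder,
      metric = metric, estimate = res$estimate, ci_low = res$ci_low,
      ci_high = res$ci_high, predicted_auc = predicted,
      n_train = config$n_train, n_test = config$n_test,
      seed = config$seed
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("shortcut_sweep", class(out))
  out
}

#' @rdname run_bias_sweep
#' @param x A `shortcut_sweep`.
#' @param ... Unused.
#' @method tidy shortcut_sweep
#' @export
tidy.shortcut_sweep <- function(x, ...) {
  out <- x
  attr(out, "config") <- NULL
  class(out) <- setdiff(class(out), "shortcut_sweep")
  out
}

#' @rdname run_bias_sweep
#' @method glance shortcut_sweep
#' @export
glance.shortcut_sweep <- function(x, ...) {
  gap <- abs(x$estimate - x$predicted_auc)
  tibble::tibble(
    task = x$task[1], confounder = x$confounder[1], metric = x$metric[1],
    n_bias = nrow(x),
    min_estimate = min(x$estimate), max_estimate = max(x$estimate),
    spearman_bias = if (nrow(x) > 2) {
      suppressWarnings(stats::cor(x$bias, x$estimate, method = "spearman"))
    } else {
      NA_real_
    },
    max_abs_gap = if (all(is.na(gap))) NA_real_ else max(gap, na.rm = TRUE)
  )
}

#' Plot a bias sweep
#'
#' Line plot of the metric against training bias with the bootstrap
#' interval as a ribbon; when present, the closed-form shortcut prediction
#' is overlaid as a dashed curve.
#'
#' @param object A `shortcut_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shortcut_sweep
#' @export
autoplot.shortcut_sweep <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bias,
                                        y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "training bias",
      y = if (df$metric[1] == "mae") "MAE (years)" else "AUROC",
      title = sprintf("Predicting %s, confounded by %s",
                      df$task[1], df$confounder[1])
    )
  if (any(!is.na(df$predicted_auc))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$predicted_auc),
                                linetype = "dashed", colour = "black")
  }
  p
}

#' Write sweep results to disk
#'
#' Emits `sweep.csv` (one row per bias), `sweep_summary.json` (config plus
#' glance summary, including the maximum absolute gap to the shortcut
#' prediction where available), and `sweep.png` (the [autoplot] figure).
#' Re-running with the same sweep result reproduces identical CSV bytes.
#'
#' @param result A `shortcut_sweep`.
#' @param out_dir Output directory (created if absent).
#' @param plot Write the figure (default `TRUE`).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sweep_report <- function(result, out_dir, plot = TRUE) {
  stopifnot(inherits(result, "shortcut_sweep"), nrow(result) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(csv = file.path(out_dir, "sweep.csv"),
             json = file.path(out_dir, "sweep_summary.json"),
             png = file.path(out_dir, "sweep.png"))
  readr::write_csv(tidy(result), paths[["csv"]], progress = FALSE)
  cfg <- attr(result, "config")
  jsonlite::write_json(
    list(config = unclass(cfg), summary = as.list(glance(result))),
    paths[["json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(plot)) {
    ggplot2::ggsave(paths[["png"]], autoplot(result), width = 6, height = 4,
                    dpi = 150)
  } else {
    paths <- paths[c("csv", "json")]
  }
  invisible(paths)
}
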