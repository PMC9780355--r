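#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Columns holding view features, e.g. a4c_f1 ... subcostal_f8.
default_feature_cols <- function(data) {
  grep("_f[0-9]+$", names(data), value = TRUE)
}

check_features <- function(data, features) {
  if (is.null(features)) features <- default_feature_cols(data)
  if (length(features) == 0L || !all(features %in% names(data))) {
    stop("no valid feature columns found.", call. = FALSE)
  }
  X <- as.matrix(data[features])
  if (!all(is.finite(X))) stop("features must be finite.", call. = FALSE)
  X
}

new_scorer <- function(target, features, intercept, coef, lambda, kind) {
  structure(
    list(target = target, features = features,
         intercept = unname(intercept),
         coef = stats::setNames(as.numeric(coef), features),
         lambda = lambda, kind = kind),
    class = c(if (kind == "regressor") "shortcut_regressor",
              "shortcut_scorer")
  )
}

# Ridge fit via glmnet at one fixed lambda (deterministic); plain ML fit
# for a single predictor, where glmnet does not apply.
ridge_fit <- function(X, y, family, lambda, maxit, thresh) {
  if (ncol(X) >= 2L) {
    fit <- glmnet::glmnet(X, y, family = family, alpha = 0, lambda = lambda,
                          standardize = FALSE, maxit = maxit,
                          thresh = thresh)
    list(intercept = as.numeric(fit$a0),
         coef = as.numeric(fit$beta[, 1]))
  } else {
    fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
    fit <- stats::glm.fit(cbind(1, X), y, family = fam)
    list(intercept = fit$coefficients[1], coef = fit$coefficients[-1])
  }
}

#' Fit a regularized linear classifier on view features
#'
#' The trainable surrogate for a per-view imaging model on a binary
#' demographic target: a logistic (cross-entropy) scorer with a weak L2
#' penalty, fit to a fixed convergence tolerance.  The weak ridge
#' stabilizes the fit without biasing the zero-signal test AUROC away
#' from 0.5.  Training is deterministic given the data and hyperparameters.
#'
#' @param data Training data frame.
#' @param target Name of the binary (0/1) label column.
#' @param features Character vector of feature column names; default all
#'   `<view>_f<k>` columns.
#' @param lambda Ridge penalty (glmnet scale); default `1e-3`.
#' @param maxit,thresh Optimizer iteration cap and convergence tolerance.
#'
#' @return A `shortcut_scorer`: linear weights plus intercept, scored on
#'   the log-odds scale via [predict.shortcut_scorer()] (higher = more
#'   likely target = 1).
#' @export
#' @examples
#' pop <- generate_population(population_spec(
#'   2000, d_sex = separation_for_auc(0.84), views = "a4c"))
#' sc <- fit_classifier(pop, "sex")
#' auroc(predict(sc, pop), pop$sex)
fit_classifier <- function(data, target, features = NULL, lambda = 1e-3,
                           maxit = 1e5, thresh = 1e-9) {
  stopifnot(is.data.frame(data), is.character(target),
            target %in% names(data))
  y <- data[[target]]
  if (!all(y %in% c(0, 1))) stop("`target` must be binary 0/1.",
                                 call. = FALSE)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 examples of each class.", call. = FALSE)
  }
  if (is.null(features)) features <- default_feature_cols(data)
  X <- check_features(data, features)
  fit <- ridge_fit(X, y, "binomial", lambda, maxit, thresh)
  new_scorer(target, features, fit$intercept, fit$coef, lambda, "classifier")
}

#' Fit a regularized linear age regressor on view features
#'
#' Surrogate for the per-view age model: penalized least squares (L2 loss
#' with a weak ridge penalty) predicting continuous age in years.
#'
#' @inheritParams fit_classifier
#' @param target Name of the continuous outcome column (default `"age"`).
#' @return A `shortcut_regressor`; [predict.shortcut_scorer()] returns
#'   predicted years.
#' @export
fit_regressor <- function(data, target = "age", features = NULL,
                          lambda = 1e-3, maxit = 1e5, thresh = 1e-9) {
  stopifnot(is.data.frame(data), target %in% names(data))
  y <- data[[target]]
  if (length(y) < 2) stop("need at least 2 examples.", call. = FALSE)
  if (!all(is.finite(y))) stop("`target` must be finite.", call. = FALSE)
  if (is.null(features)) features <- default_feature_cols(data)
  X <- check_features(data, features)
  fit <- ridge_fit(X, y, "gaussian", lambda, maxit, thresh)
  new_scorer(target, features, fit$intercept, fit$coef, lambda, "regressor")
}

#' Combine per-view scores by logistic regression
#'
#' Stacks the held-out scores of several view models into one ensemble
#' scorer, exactly as an ensemble over imaging views: an unpenalized
#' logistic regression with the per-view scores as inputs.  The score
#' columns must have been computed on data disjoint from the data the view
#' models were trained on, otherwise the stacking weights overfit.
#'
#' @param data Data frame holding the per-view score columns and the label.
#' @param target Name of the binary label column.
#' @param score_cols Character vector of per-view score columns.
#' @return A `shortcut_scorer` over the score columns.
#' @export
fit_view_ensemble <- function(data, target, score_cols) {
  stopifnot(is.data.frame(data), target %in% names(data),
            length(score_cols) >= 1L, all(score_cols %in% names(data)))
  y <- data[[target]]
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 examples of each class.", call. = FALSE)
  }
  X <- check_features(data, score_cols)
  df <- data.frame(.y = y, X)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  new_scorer(target, score_cols, cf[1], cf[-1], 0, "ensemble")
}

#' Score new data with a trained scorer
#'
#' @param object A `shortcut_scorer` or `shortcut_regressor`.
#' @param data Data frame containing the scorer's feature columns.
#' @param ... Unused.
#' @return Numeric vector: log-odds-scale scores for classifiers and
#'   ensembles, predicted years for regressors.
#' @export
predict.shortcut_scorer <- function(object, data, ...) {
  X <- as.matrix(data[object$features])
  drop(X %*% object$coef) + object$intercept
}

#' @export
print.shortcut_scorer <- function(x, ...) {
  cat(sprintf("<shortcut_%s> target: %s  features: %d  lambda: %g\n",
              x$kind, x$target, length(x$features), x$lambda))
  invisible(x)
}

#' @rdname fit_classifier
#' @param x A `shortcut_scorer`.
#' @param ... Unused.
#' @method tidy shortcut_scorer
#' @export
tidy.shortcut_scorer <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(x$intercept, unname(x$coef)))
}

#' @rdname fit_classifier
#' @method glance shortcut_scorer
#' @export
glance.shortcut_scorer <- function(x, ...) {
  tibble::tibble(target = x$target, kind = x$kind,
                 n_features = length(x$features), lambda = x$lambda)
}

#' Serialize a scorer to JSON / read it back
#'
#' @param scorer A `shortcut_scorer`.
#' @param path File path.
#' @return `write_scorer()` returns `path` invisibly; `read_scorer()`
#'   returns the scorer.
#' @export
write_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "shortcut_scorer"))
  jsonlite::write_json(
    list(target = scorer$target, kind = scorer$kind,
         features = scorer$features, intercept = scorer$intercept,
         coef = unname(scorer$coef), lambda = scorer$lambda),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_scorer(obj$target, obj$features, obj$intercept, obj$coef, obj$lambda,
             obj$kind)
}
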