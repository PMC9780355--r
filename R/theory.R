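#' Expected AUROC achievable through a confounder alone
#'
#' Closed-form oracle for shortcut learning through a single binary
#' confounder.  Suppose a scorer carries no direct label signal but can
#' detect a binary confounder with quality `A` (the AUROC of the confounder
#' task), and both the training and the evaluation population couple label
#' and confounder at bias `b`: a fraction `b` of label-positives and
#' `1 - b` of label-negatives have confounder = 1.  Conditioning a random
#' positive-negative pair on the confounder cell of each member gives the
#' label AUROC
#'
#' \deqn{b^2 A + (1-b)^2 (1-A) + b(1-b).}
#'
#' At `b = 0.5` the confounder carries no label information and the value
#' is 0.5 exactly; at `b = 1` label and confounder coincide and the value
#' is `A`.  The curve is nondecreasing in `b` whenever `A > 0.5`.
#'
#' @param bias Bias value(s) in `[0.5, 1]`.
#' @param confounder_auc Confounder-task AUROC `A` in `[0.5, 1]`.
#' @return Expected label AUROC, vectorized over `bias`.
#' @export
#' @examples
#' shortcut_auc(0.8, 0.85)  # 0.710
#' shortcut_auc(1.0, 0.84)  # converges to the confounder task itself
shortcut_auc <- function(bias, confounder_auc) {
  if (!is.numeric(bias) || anyNA(bias) || any(bias < 0.5) || any(bias > 1)) {
    stop("`bias` must lie in [0.5, 1].", call. = FALSE)
  }
  if (!is.numeric(confounder_auc) || anyNA(confounder_auc) ||
      any(confounder_auc < 0.5) || any(confounder_auc > 1)) {
    stop("`confounder_auc` must lie in [0.5, 1].", call. = FALSE)
  }
  shortcut_auc_impl(bias, confounder_auc)
}

# Raw pairing formula, valid on the full b in [0, 1] extension (b < 0.5
# flips which confounder level aligns with the label, and the curve
# reflects: f(1 - b) = 1 - f(b)).
shortcut_auc_impl <- function(b, A) {
  b^2 * A + (1 - b)^2 * (1 - A) + b * (1 - b)
}

#' AUROC of a Gaussian-separated score
#'
#' For two unit-variance Gaussian score classes whose means differ by `d`,
#' the AUROC is `pnorm(d / sqrt(2))`.  Inverse of [separation_for_auc()].
#'
#' @param d Nonnegative standardized separation(s).
#' @return AUROC in `[0.5, 1)`.
#' @export
#' @examples
#' auc_for_separation(1.4064)  # 0.84
auc_for_separation <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0)) {
    stop("`d` must be nonnegative.", call. = FALSE)
  }
  stats::pnorm(d / sqrt(2))
}

#' Tabulate the shortcut-AUC curve over a bias grid
#'
#' @param confounder_auc Confounder-task AUROC `A` in `[0.5, 1]`.
#' @param bias_grid Vector of bias values (default 0.5 to 1 by 0.1).
#' @return A tibble `bias`, `predicted_auc` of class `shortcut_curve`.
#' @export
shortcut_curve <- function(confounder_auc, bias_grid = seq(0.5, 1, by = 0.1)) {
  out <- tibble::tibble(
    bias = bias_grid,
    predicted_auc = shortcut_auc(bias_grid, confounder_auc)
  )
  attr(out, "confounder_auc") <- confounder_auc
  class(out) <- c("shortcut_curve", class(out))
  out
}
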