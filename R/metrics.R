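# Evaluation metrics. Fold-error statistics (2/3/5-fold %, MFE, GMFE,
# ALB) and bias operate on the natural (antilogged) scale; RMSE and R^2
# on the modelling (log) scale.

#' Fold error between predicted and observed values
#'
#' `max(f/y, y/f)`: symmetric, equals 1 only for a perfect prediction.
#'
#' @param f Predicted values (natural scale, positive).
#' @param y Observed values (natural scale, positive).
#' @return Numeric vector of fold errors, each `>= 1`.
#' @export
fold_error <- function(f, y) {
  stopifnot(length(f) == length(y))
  if (any(f <= 0 | y <= 0, na.rm = TRUE)) {
    stop("fold_error requires strictly positive values", call. = FALSE)
  }
  pmax(f / y, y / f)
}

#' Geometric mean fold error
#'
#' `10 ^ mean(|log10 FE|)`: the canonical pharmacokinetic accuracy
#' summary, always `>= 1`. The signed companion statistic is
#' [alb_signed()].
#'
#' @inheritParams fold_error
#' @return Scalar GMFE.
#' @export
gmfe <- function(f, y) {
  10^mean(abs(log10(fold_error(f, y))))
}

#' Signed average logarithmic bias
#'
#' `mean(log10(f / y))` without absolute values, so systematic over- and
#' under-prediction cancel. `10^alb_signed()` is below 1 when the model
#' under-predicts on average.
#'
#' @inheritParams fold_error
#' @return Scalar signed ALB.
#' @export
alb_signed <- function(f, y) {
  stopifnot(length(f) == length(y))
  if (any(f <= 0 | y <= 0, na.rm = TRUE)) {
    stop("alb_signed requires strictly positive values", call. = FALSE)
  }
  mean(log10(f / y))
}

#' Median fold error
#' @inheritParams fold_error
#' @return Scalar MFE.
#' @export
mfe <- function(f, y) stats::median(fold_error(f, y))

#' Percentage of predictions within a k-fold band
#'
#' Boundary inclusive: a fold error exactly `k` counts as within k-fold.
#'
#' @inheritParams fold_error
#' @param k Fold band (2, 3 or 5 in routine reporting).
#' @return Percentage in `[0, 100]`.
#' @export
pct_within_fold <- function(f, y, k) 100 * mean(fold_error(f, y) <= k)

#' Median signed prediction error (bias)
#' @inheritParams fold_error
#' @return `median(f - y)` on the scale of the inputs.
#' @export
bias_median <- function(f, y) stats::median(f - y)

#' Root mean square error
#' @param y_true,y_pred Vectors on the modelling scale.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) sqrt(mean((y_true - y_pred)^2))

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` around the observed mean; can be negative for a
#' model worse than predicting the mean.
#'
#' @inheritParams rmse
#' @return Scalar R-squared; `NA` with a warning when `y_true` is
#'   constant.
#' @export
r_squared <- function(y_true, y_pred) {
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("R^2 undefined for constant observations", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Full evaluation report for one prediction set
#'
#' Computes the complete metric panel for one endpoint. For
#' log-modelled endpoints the inputs are on the log10 scale: RMSE and
#' R^2 are computed there, while the fold-error family and bias are
#' computed after decadic antilog back-transformation. For raw-scale
#' endpoints (`fu`) everything is computed on the raw scale, with a
#' small positive floor applied before fold-error division.
#'
#' @param y_true,y_pred Observed and predicted values on the modelling
#'   scale.
#' @param log_scale Are the inputs log10-transformed values?
#' @param floor Lower clip applied on the natural scale before
#'   fold-error computation (guards `fu` near 0).
#' @return One-row tibble: `n`, `pct_within_2fold`, `pct_within_3fold`,
#'   `pct_within_5fold`, `mfe`, `gmfe`, `alb`, `bias`, `rmse`, `r2`.
#' @export
pk_metrics <- function(y_true, y_pred, log_scale = TRUE, floor = 1e-4) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  keep <- !is.na(y_true) & !is.na(y_pred)
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  if (log_scale) {
    f_nat <- 10^y_pred
    y_nat <- 10^y_true
  } else {
    f_nat <- pmax(y_pred, floor)
    y_nat <- pmax(y_true, floor)
  }
  tibble::tibble(
    n = length(y_true),
    pct_within_2fold = pct_within_fold(f_nat, y_nat, 2),
    pct_within_3fold = pct_within_fold(f_nat, y_nat, 3),
    pct_within_5fold = pct_within_fold(f_nat, y_nat, 5),
    mfe = mfe(f_nat, y_nat),
    gmfe = gmfe(f_nat, y_nat),
    alb = alb_signed(f_nat, y_nat),
    bias = bias_median(f_nat, y_nat),
    rmse = rmse(y_true, y_pred),
    r2 = r_squared(y_true, y_pred)
  )
}

#' Paired t-test over per-fold GMFEs of two models
#'
#' Helper for comparing feature combinations evaluated on identical
#' cross-validation folds.
#'
#' @param gmfe_a,gmfe_b Per-fold GMFE vectors of equal length, fold-
#'   aligned.
#' @return Tidied one-row tibble with the mean paired difference and
#'   p-value.
#' @export
paired_gmfe_test <- function(gmfe_a, gmfe_b) {
  stopifnot(length(gmfe_a) == length(gmfe_b))
  tt <- stats::t.test(gmfe_a, gmfe_b, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_folds = length(gmfe_a))
}
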