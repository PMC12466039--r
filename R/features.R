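# Feature selection and scaling. Selection is fit once per species
# dataset and reused unchanged for any compounds predicted later; a
# feature_recipe bundles the fitted state.

#' Remove low-variance features
#'
#' Drops every column whose variance falls strictly below `threshold`,
#' computed on the raw (unscaled) values. Idempotent.
#'
#' @param x Numeric matrix (compounds x features).
#' @param threshold Variance cutoff (default 0.05).
#' @return The retained columns, with a logical attribute `mask` over
#'   the original columns.
#' @export
variance_filter <- function(x, threshold = 0.05) {
  if (!is.matrix(x) || ncol(x) == 0 || nrow(x) == 0) {
    stop("variance_filter needs a non-empty numeric matrix", call. = FALSE)
  }
  v <- apply(x, 2, stats::var)
  keep <- !is.na(v) & v >= threshold
  out <- x[, keep, drop = FALSE]
  attr(out, "mask") <- keep
  out
}

#' Remove one of each highly correlated feature pair
#'
#' Greedy left-to-right scan in stored column order: column `j` is
#' dropped if its Pearson correlation with any earlier retained column
#' exceeds `threshold`. Signed correlation by default (anti-correlated
#' pairs are both kept); set `use_abs = TRUE` for |r|.
#'
#' @param x Numeric matrix with no zero-variance columns (apply
#'   [variance_filter()] first).
#' @param threshold Correlation cutoff (default 0.95, strict `>`).
#' @param use_abs Compare `|r|` instead of signed `r`.
#' @return The retained columns with a logical attribute `mask`.
#' @export
correlation_filter <- function(x, threshold = 0.95, use_abs = FALSE) {
  stopifnot(is.matrix(x), ncol(x) >= 1)
  cors <- suppressWarnings(stats::cor(x))
  if (use_abs) cors <- abs(cors)
  p <- ncol(x)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)[-1]) {
    earlier <- which(keep[seq_len(j - 1)])
    if (length(earlier) && any(cors[earlier, j] > threshold, na.rm = TRUE)) {
      keep[j] <- FALSE
    }
  }
  out <- x[, keep, drop = FALSE]
  attr(out, "mask") <- keep
  out
}

#' Fit / apply per-column standardization
#'
#' `fit_scaler()` records each column's mean and standard deviation;
#' `apply_scaler()` centres and scales any matrix with matching columns
#' (column order enforced by name). Scaling the fitting set yields
#' column means 0 and SD 1.
#'
#' @param x Numeric matrix (no zero-variance columns).
#' @param drop_zero_variance Silently drop zero-variance columns from
#'   the scaler (used when a modelling subset is smaller than the
#'   selection-fitting set); default `FALSE`, which errors instead.
#' @return `fit_scaler()`: a `pk_scaler` with `mean` and `sd`;
#'   `apply_scaler()`: the transformed matrix.
#' @export
fit_scaler <- function(x, drop_zero_variance = FALSE) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (any(sd == 0)) {
    if (!drop_zero_variance) {
      stop("zero-variance column(s) cannot be scaled: ",
           paste(utils::head(colnames(x)[sd == 0], 3), collapse = ", "),
           call. = FALSE)
    }
    keep <- sd > 0
    mu <- mu[keep]; sd <- sd[keep]
  }
  structure(list(mean = mu, sd = sd, features = names(mu)),
            class = "pk_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `pk_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "pk_scaler"))
  if (!identical(colnames(x), scaler$features)) {
    if (!all(scaler$features %in% colnames(x))) {
      stop("matrix is missing scaler feature columns", call. = FALSE)
    }
    x <- x[, scaler$features, drop = FALSE]
  }
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Fit the structural + physicochemical feature recipe for a dataset
#'
#' Computes Morgan fingerprints and the 2D descriptor block for a
#' compound set and applies the selection protocol: fingerprints get a
#' variance filter; descriptors get a variance filter followed by the
#' pairwise-correlation filter. Descriptor columns with any missing
#' value across the fitting compounds are dropped first (and recorded);
#' at prediction time missing descriptor values are imputed with the
#' fitting-set column mean.
#'
#' @param std_smiles Standardized SMILES of the fitting compounds.
#' @param var_threshold Variance cutoff (default 0.05).
#' @param cor_threshold Correlation cutoff (default 0.95).
#' @param use_abs_cor Use `|r|` in the correlation filter.
#' @return A `feature_recipe` holding selected feature names and
#'   imputation means.
#' @export
fit_feature_recipe <- function(std_smiles, var_threshold = 0.05,
                               cor_threshold = 0.95, use_abs_cor = FALSE) {
  fp <- morgan_fingerprints(std_smiles)
  fp_sel <- variance_filter(fp, var_threshold)

  desc <- physchem_descriptors(std_smiles)
  complete <- colSums(is.na(desc)) == 0
  dropped_na <- colnames(desc)[!complete]
  desc <- desc[, complete, drop = FALSE]
  desc_v <- variance_filter(desc, var_threshold)
  desc_sel <- correlation_filter(desc_v, cor_threshold, use_abs = use_abs_cor)

  structure(list(
    morgan_bits = colnames(fp_sel),
    descriptors = colnames(desc_sel),
    descriptor_means = colMeans(desc[, colnames(desc_sel), drop = FALSE]),
    dropped_na_descriptors = dropped_na,
    var_threshold = var_threshold,
    cor_threshold = cor_threshold
  ), class = "feature_recipe")
}

#' Build the selected feature blocks for a compound list
#'
#' @param std_smiles Standardized SMILES.
#' @param recipe A fitted `feature_recipe`.
#' @return List with matrices `morgan` and `descriptors`, rows aligned
#'   to `std_smiles`.
#' @export
apply_feature_recipe <- function(std_smiles, recipe) {
  stopifnot(inherits(recipe, "feature_recipe"))
  fp <- morgan_fingerprints(std_smiles)[, recipe$morgan_bits, drop = FALSE]
  desc <- physchem_descriptors(std_smiles)
  missing_cols <- setdiff(recipe$descriptors, colnames(desc))
  if (length(missing_cols)) {
    stop("descriptor block lacks recipe columns: ",
         paste(utils::head(missing_cols, 3), collapse = ", "), call. = FALSE)
  }
  desc <- desc[, recipe$descriptors, drop = FALSE]
  for (j in seq_len(ncol(desc))) {
    nas <- is.na(desc[, j])
    if (any(nas)) desc[nas, j] <- recipe$descriptor_means[[j]]
  }
  list(morgan = fp, descriptors = desc)
}
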