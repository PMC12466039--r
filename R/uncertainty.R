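# Similarity-based fold-error estimation and applicability-domain
# alerting. A kernel ridge regressor (RBF + white-noise kernel, grid
# search by 10-fold CV maximizing R^2) maps the mean 5-nearest-
# neighbour Tanimoto similarity of a query compound to its expected
# fold error; queries below 0.25 similarity raise an out-of-domain
# alert.

AD_SIMILARITY_THRESHOLD <- 0.25

#' Mean Tanimoto similarity of the k nearest training neighbours
#'
#' @param query_fps Fingerprint matrix of query compounds.
#' @param train_fps Fingerprint matrix of the training set.
#' @param k Number of neighbours (default 5; capped at the training
#'   size).
#' @param exclude_self Drop one perfect self-match per query (use when
#'   queries are themselves training members).
#' @return Numeric vector: per query, the mean of the `k` largest
#'   similarities.
#' @export
knn_mean_similarity <- function(query_fps, train_fps, k = 5,
                                exclude_self = FALSE) {
  if (is.null(dim(train_fps)) || nrow(train_fps) == 0) {
    stop("empty training fingerprint set", call. = FALSE)
  }
  sims <- tanimoto_similarity(query_fps, train_fps)
  apply(sims, 1, function(s) {
    s <- sort(s, decreasing = TRUE)
    if (exclude_self) s <- s[-1]
    mean(utils::head(s, k))
  })
}

#' Similarity / mean-fold-error pairs from a nested cross-validation
#'
#' For every held-out prediction, computes the compound's mean 5-NN
#' Tanimoto similarity to that fold's own training portion and its
#' natural-scale fold error. Compounds whose similarity falls below
#' `mean - 1.5 * sd` of all similarities are dropped as low-similarity
#' outliers; the remainder are binned by similarity rounded to two
#' decimals and averaged.
#'
#' @param cv A `pk_cv` from [nested_cv()].
#' @param fingerprints 2048-bit fingerprint matrix, rows aligned with
#'   the modelling subset used for `cv`.
#' @param k Neighbours for the similarity (default 5).
#' @param sd_filter Drop compounds below `mean - sd_filter * sd`
#'   similarity (default 1.5; `Inf` disables).
#' @return Tibble with `similarity` (bin centre) and `mean_fe`,
#'   plus attribute `compound_pairs` holding the unbinned per-
#'   prediction pairs.
#' @export
collect_similarity_fe_pairs <- function(cv, fingerprints, k = 5,
                                        sd_filter = 1.5) {
  stopifnot(inherits(cv, "pk_cv"), nrow(fingerprints) >= cv$n)
  preds <- cv$predictions
  folds <- cv$folds
  sims <- numeric(nrow(preds))
  for (i in seq_len(nrow(folds))) {
    tr <- folds$train_rows[[i]]
    rows <- which(preds$repeat_ == folds$repeat_[[i]] &
                    preds$fold == folds$fold[[i]])
    sims[rows] <- knn_mean_similarity(
      fingerprints[preds$row[rows], , drop = FALSE],
      fingerprints[tr, , drop = FALSE], k = k)
  }
  if (cv$log_scale) {
    fe <- fold_error(10^preds$y_pred, 10^preds$y_true)
  } else {
    fe <- fold_error(pmax(preds$y_pred, 1e-4), pmax(preds$y_true, 1e-4))
  }
  pairs <- tibble::tibble(similarity = sims, fe = fe)
  if (is.finite(sd_filter)) {
    cutoff <- mean(sims) - sd_filter * stats::sd(sims)
    pairs <- pairs[pairs$similarity >= cutoff, ]
  }
  binned <- pairs |>
    dplyr::mutate(similarity = round(.data$similarity, 2)) |>
    dplyr::group_by(.data$similarity) |>
    dplyr::summarise(mean_fe = mean(.data$fe), n = dplyr::n(),
                     .groups = "drop")
  attr(binned, "compound_pairs") <- pairs
  binned
}

# Closed-form kernel ridge regression with an RBF + white-noise kernel:
# alpha = (K + (lambda + noise) I)^{-1} y, prediction k(x)' alpha.
krr_fit <- function(x, y, lengthscale, lambda, noise) {
  k <- exp(-outer(x, x, "-")^2 / (2 * lengthscale^2))
  alpha <- solve(k + diag(lambda + noise, length(x)), y)
  list(x = x, alpha = alpha, lengthscale = lengthscale,
       lambda = lambda, noise = noise)
}

krr_predict <- function(fit, x_new) {
  k <- exp(-outer(x_new, fit$x, "-")^2 / (2 * fit$lengthscale^2))
  as.vector(k %*% fit$alpha)
}

#' Fit the similarity-to-fold-error model
#'
#' Kernel ridge regression of binned mean fold error on structural
#' similarity, with a radial-basis-function kernel plus a white-noise
#' kernel. The RBF length-scale, ridge penalty and noise magnitude are
#' selected on log-spaced grids by 10-fold cross-validation maximizing
#' R^2.
#'
#' @param pairs Tibble from [collect_similarity_fe_pairs()]
#'   (`similarity`, `mean_fe`).
#' @param train_fingerprints Fingerprints of the final model's training
#'   set, stored for query-time similarity.
#' @param lengthscales,lambdas,noises Candidate grids (log-spaced
#'   defaults).
#' @param n_folds CV folds for the grid search (default 10).
#' @param ad_threshold Applicability-domain similarity floor
#'   (default 0.25).
#' @param seed Seed for the CV fold assignment.
#' @return A `fold_error_model`.
#' @export
fit_fold_error_model <- function(pairs, train_fingerprints = NULL,
                                 lengthscales = 10^seq(-2, 1, length.out = 6),
                                 lambdas = 10^seq(-3, 1, length.out = 5),
                                 noises = 10^seq(-3, 0, length.out = 4),
                                 n_folds = 10, ad_threshold =
                                   AD_SIMILARITY_THRESHOLD, seed = 1) {
  x <- pairs$similarity
  y <- pairs$mean_fe
  if (length(unique(x)) < 3) {
    stop("degenerate similarity values: cannot fit fold-error model",
         call. = FALSE)
  }
  n_folds <- min(n_folds, length(x))
  grid <- expand.grid(lengthscale = lengthscales, lambda = lambdas,
                      noise = noises)
  set.seed(seed)
  fold_id <- fold_assignment(length(x), n_folds)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    preds <- rep(NA_real_, length(x))
    for (k in seq_len(n_folds)) {
      tr <- fold_id != k
      if (sum(tr) < 3) return(-Inf)
      fit <- krr_fit(x[tr], y[tr], grid$lengthscale[[g]],
                     grid$lambda[[g]], grid$noise[[g]])
      preds[!tr] <- krr_predict(fit, x[!tr])
    }
    suppressWarnings(r_squared(y, preds))
  }, numeric(1))
  best <- grid[which.max(scores), ]
  fit <- krr_fit(x, y, best$lengthscale, best$lambda, best$noise)
  structure(list(fit = fit, pairs = pairs,
                 train_fingerprints = train_fingerprints,
                 ad_threshold = ad_threshold,
                 cv_r2 = max(scores),
                 grid_best = as.list(best), seed = seed),
            class = "fold_error_model")
}

#' @export
print.fold_error_model <- function(x, ...) {
  cat(sprintf(
    "<fold_error_model: %d bins, lengthscale %.3g, lambda %.3g, noise %.3g, CV R^2 %.2f>\n",
    nrow(x$pairs), x$fit$lengthscale, x$fit$lambda, x$fit$noise, x$cv_r2))
  invisible(x)
}

#' @method glance fold_error_model
#' @export
glance.fold_error_model <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$pairs), lengthscale = x$fit$lengthscale,
                 lambda = x$fit$lambda, noise = x$fit$noise,
                 cv_r2 = x$cv_r2, ad_threshold = x$ad_threshold)
}

#' Predicted fold-error curve over a similarity grid
#'
#' @param fe_model A `fold_error_model`.
#' @param similarity Similarity grid (default 0 to 1 by 0.01).
#' @return Tibble `similarity`, `fold_error` (clipped at 1 from below).
#' @export
fold_error_curve <- function(fe_model, similarity = seq(0, 1, 0.01)) {
  tibble::tibble(
    similarity = similarity,
    fold_error = pmax(krr_predict(fe_model$fit, similarity), 1))
}

#' Estimate fold error and applicability domain for query compounds
#'
#' @param query Fingerprint matrix, or a character vector of
#'   standardized SMILES (fingerprinted internally).
#' @param fe_model A `fold_error_model` holding the training
#'   fingerprints.
#' @return Tibble `similarity` (mean 5-NN Tanimoto to the training
#'   set), `fold_error` (regressor output, clipped at 1) and `ad_alert`
#'   (`TRUE` when similarity < the 0.25 threshold, strict).
#' @export
estimate_fold_error <- function(query, fe_model) {
  stopifnot(inherits(fe_model, "fold_error_model"),
            !is.null(fe_model$train_fingerprints))
  fps <- if (is.character(query)) morgan_fingerprints(query) else query
  sim <- knn_mean_similarity(fps, fe_model$train_fingerprints, k = 5)
  tibble::tibble(
    similarity = sim,
    fold_error = pmax(krr_predict(fe_model$fit, sim), 1),
    ad_alert = sim < fe_model$ad_threshold)
}
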