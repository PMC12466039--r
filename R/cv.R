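# Repeated nested cross-validation with grid-search model selection.
# The harness is shared by the animal-endpoint and human-endpoint
# stages; the mean-predictor baseline runs through the identical loop.

#' Random Forest hyperparameter grid
#'
#' Default candidate grid for the nested-CV grid search. `max_depth = 0`
#' means unlimited depth; `mtry_frac = NA` means the square-root
#' heuristic.
#'
#' @param num_trees,max_depth,min_node,mtry_frac Candidate values.
#' @return Tibble of all combinations, ordered simplest-first.
#' @export
default_rf_grid <- function(num_trees = c(100, 250, 500),
                            max_depth = c(8, 12, 0),
                            min_node = c(1, 3, 5),
                            mtry_frac = c(NA, 0.3)) {
  g <- tidyr::expand_grid(num_trees = num_trees, max_depth = max_depth,
                          min_node = min_node, mtry_frac = mtry_frac)
  g[order(g$num_trees, ifelse(g$max_depth == 0, Inf, g$max_depth),
          g$min_node), ]
}

#' Compact grid for quick runs
#'
#' A reduced grid for small studies and examples where the full grid
#' search is not warranted.
#' @export
small_rf_grid <- function() {
  tidyr::expand_grid(num_trees = c(100, 250), max_depth = c(0),
                     min_node = c(3, 5), mtry_frac = NA)
}

#' Nested cross-validation configuration
#'
#' @param n_repeats Number of repetitions of the outer split (default 5).
#' @param n_outer Outer folds per repeat (default 5); `n_repeats *
#'   n_outer` evaluation folds in total.
#' @param n_inner Inner folds for the hyperparameter grid search
#'   (default 4).
#' @param grid Hyperparameter candidate tibble (see
#'   [default_rf_grid()]).
#' @param seed Base seed; every stochastic component derives from it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_repeats = 5, n_outer = 5, n_inner = 4,
                      grid = default_rf_grid(), seed = 1) {
  stopifnot(n_repeats >= 1, n_outer >= 2, n_inner >= 2, nrow(grid) >= 1)
  structure(list(n_repeats = n_repeats, n_outer = n_outer,
                 n_inner = n_inner, grid = grid, seed = seed),
            class = "cv_config")
}

fold_assignment <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

fit_one_model <- function(x, y, params, seed) {
  if (identical(params$model, "mean")) {
    return(structure(list(mean = mean(y)), class = "pk_mean_model"))
  }
  mtry <- if (is.na(params$mtry_frac)) max(1L, floor(sqrt(ncol(x)))) else
    max(1L, floor(params$mtry_frac * ncol(x)))
  ranger::ranger(
    x = x, y = y,
    num.trees = params$num_trees,
    mtry = min(mtry, ncol(x)),
    min.node.size = params$min_node,
    max.depth = params$max_depth,
    seed = seed,
    num.threads = 1
  )
}

predict_one_model <- function(fit, x) {
  if (inherits(fit, "pk_mean_model")) return(rep(fit$mean, nrow(x)))
  stats::predict(fit, data = x, num.threads = 1)$predictions
}

# natural-scale GMFE used as the selection score throughout
selection_score <- function(y_true, y_pred, log_scale) {
  if (log_scale) gmfe(10^y_pred, 10^y_true)
  else gmfe(pmax(y_pred, 1e-4), pmax(y_true, 1e-4))
}

grid_search <- function(x, y, config, log_scale, inner_seed, model_seed) {
  grid <- config$grid
  set.seed(inner_seed)
  inner_id <- fold_assignment(length(y), config$n_inner)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    preds <- rep(NA_real_, length(y))
    for (k in seq_len(config$n_inner)) {
      tr <- inner_id != k
      fit <- fit_one_model(x[tr, , drop = FALSE], y[tr], params,
                           seed = model_seed + g)
      preds[!tr] <- predict_one_model(fit, x[!tr, , drop = FALSE])
    }
    selection_score(y, preds, log_scale)
  }, numeric(1))
  as.list(grid[which.min(scores), ])
}

#' Run repeated nested cross-validation
#'
#' For each repeat the data are split into `n_outer` folds; on each
#' training portion a grid search with `n_inner`-fold cross-validation
#' selects Random Forest hyperparameters by minimizing the natural-
#' scale geometric mean fold error, and a model with those parameters
#' predicts the held-out fold. All `n_repeats * n_outer` prediction
#' sets and per-fold metric panels are returned. The whole run is a
#' pure function of `(x, y, config)`.
#'
#' @param x Numeric feature matrix, rows aligned with `y` (subset to
#'   annotated compounds beforehand; scale first to follow the
#'   fit-before-splitting protocol).
#' @param y Numeric response on the modelling scale.
#' @param config A [cv_config()].
#' @param log_scale Is `y` on the log10 scale (`FALSE` for `fu`)?
#' @param model `"rf"` or `"mean"` (the baseline predictor, which
#'   ignores the grid).
#' @return A `pk_cv` object; see [tidy.pk_cv()] and [glance.pk_cv()].
#' @export
nested_cv <- function(x, y, config = cv_config(), log_scale = TRUE,
                      model = c("rf", "mean")) {
  model <- match.arg(model)
  stopifnot(is.matrix(x), nrow(x) == length(y), !anyNA(y))
  if (length(y) < config$n_outer) {
    stop("fewer samples (", length(y), ") than outer folds (",
         config$n_outer, ")", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    warning("constant response: R^2 is undefined for these folds",
            call. = FALSE)
  }

  # all randomness pre-drawn from the base seed
  set.seed(config$seed)
  outer_seeds <- sample.int(.Machine$integer.max, config$n_repeats)
  inner_seeds <- matrix(sample.int(.Machine$integer.max,
                                   config$n_repeats * config$n_outer),
                        nrow = config$n_repeats)
  model_seeds <- matrix(sample.int(.Machine$integer.max / 2,
                                   config$n_repeats * config$n_outer),
                        nrow = config$n_repeats)

  preds <- list()
  folds <- list()
  for (r in seq_len(config$n_repeats)) {
    set.seed(outer_seeds[[r]])
    outer_id <- fold_assignment(length(y), config$n_outer)
    for (k in seq_len(config$n_outer)) {
      tr <- outer_id != k
      stopifnot(!any(which(tr) %in% which(!tr)))  # leakage guard
      params <- if (model == "mean") list(model = "mean") else
        grid_search(x[tr, , drop = FALSE], y[tr], config, log_scale,
                    inner_seed = inner_seeds[r, k],
                    model_seed = model_seeds[r, k])
      fit <- fit_one_model(x[tr, , drop = FALSE], y[tr], params,
                           seed = model_seeds[r, k])
      y_hat <- predict_one_model(fit, x[!tr, , drop = FALSE])
      idx <- which(!tr)
      preds[[length(preds) + 1]] <- tibble::tibble(
        repeat_ = r, fold = k, row = idx, y_true = y[idx], y_pred = y_hat)
      m <- suppressWarnings(pk_metrics(y[idx], y_hat, log_scale = log_scale))
      folds[[length(folds) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = r, fold = k,
                       params = list(params),
                       train_rows = list(which(tr))), m)
    }
  }
  structure(list(predictions = dplyr::bind_rows(preds),
                 folds = dplyr::bind_rows(folds),
                 config = config, log_scale = log_scale,
                 model = model, n = length(y)),
            class = "pk_cv")
}

#' @export
print.pk_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<pk_cv: %d folds (%d x %d), n = %d, median R^2 = %.3f, median GMFE = %.2f>\n",
    nrow(x$folds), x$config$n_repeats, x$config$n_outer, x$n,
    g$median_r2, g$median_gmfe))
  invisible(x)
}

#' Per-fold metrics of a nested cross-validation
#'
#' @param x A `pk_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per evaluation fold: fold indices,
#'   selected hyperparameters (list column) and the full metric panel.
#' @method tidy pk_cv
#' @export
tidy.pk_cv <- function(x, ...) {
  dplyr::select(x$folds, -"train_rows")
}

#' One-row summary of a nested cross-validation
#'
#' Median and mean of the key metrics over all evaluation folds.
#'
#' @inheritParams tidy.pk_cv
#' @return One-row tibble.
#' @method glance pk_cv
#' @export
glance.pk_cv <- function(x, ...) {
  f <- x$folds
  tibble::tibble(
    n = x$n, n_folds = nrow(f),
    median_r2 = stats::median(f$r2), mean_r2 = mean(f$r2),
    median_gmfe = stats::median(f$gmfe), mean_gmfe = mean(f$gmfe),
    median_rmse = stats::median(f$rmse), mean_rmse = mean(f$rmse),
    median_pct2 = stats::median(f$pct_within_2fold),
    best_fold_gmfe = min(f$gmfe)
  )
}

#' Hyperparameters of the best evaluation fold
#'
#' Returns the hyperparameters of the fold with the lowest GMFE; ties
#' break toward the simpler model (fewer trees, then shallower depth,
#' then first fold).
#'
#' @param cv A `pk_cv` from [nested_cv()].
#' @return Named list of hyperparameters.
#' @export
select_best_fold <- function(cv) {
  stopifnot(inherits(cv, "pk_cv"))
  f <- cv$folds
  if (cv$model == "mean") return(list(model = "mean"))
  trees <- vapply(f$params, function(p) p$num_trees, numeric(1))
  depth <- vapply(f$params, function(p)
    ifelse(p$max_depth == 0, Inf, p$max_depth), numeric(1))
  ord <- order(f$gmfe, trees, depth, seq_len(nrow(f)))
  f$params[[ord[[1]]]]
}

#' Retrain the final model on all annotated compounds
#'
#' @param x,y Full feature matrix and response (modelling scale).
#' @param params Hyperparameters, typically from [select_best_fold()].
#' @param seed Seed for the Random Forest fit.
#' @param log_scale Is `y` log10-transformed?
#' @return A `pk_model` bundle holding the fit, hyperparameters, seed,
#'   feature names and the training response range.
#' @export
retrain_final <- function(x, y, params, seed = 1, log_scale = TRUE) {
  fit <- fit_one_model(x, y, params, seed = seed)
  structure(list(fit = fit, params = params, seed = seed,
                 log_scale = log_scale, features = colnames(x),
                 y_range = range(y), n_train = length(y)),
            class = "pk_model")
}

#' Predict from a fitted model bundle
#'
#' @param object A `pk_model`.
#' @param newdata Feature matrix with the bundle's feature columns.
#' @param ... Unused.
#' @return Numeric predictions on the modelling scale.
#' @export
predict.pk_model <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$features)) {
    if (!all(object$features %in% colnames(newdata))) {
      stop("newdata lacks model feature columns", call. = FALSE)
    }
    newdata <- newdata[, object$features, drop = FALSE]
  }
  predict_one_model(object$fit, newdata)
}

#' @method tidy pk_model
#' @export
tidy.pk_model <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    model = if (identical(p$model, "mean")) "mean" else "random_forest",
    num_trees = p$num_trees %||% NA_real_,
    max_depth = p$max_depth %||% NA_real_,
    min_node = p$min_node %||% NA_real_,
    mtry_frac = p$mtry_frac %||% NA_real_,
    n_train = x$n_train, seed = x$seed, log_scale = x$log_scale
  )
}
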