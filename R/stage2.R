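# Stage 2: human-endpoint models over the ten feature combinations.
# Combination 7 (fingerprints + descriptors + predicted animal PK) is
# the released final model; combination 10 is the mean-predictor
# baseline run through the identical harness.

#' The ten stage-2 feature combinations
#'
#' @return Tibble with `combo_id`, `label`, `blocks` (list column over
#'   `morgan`, `descriptors`, `animal_pred`, `animal_real_or_pred`) and
#'   `is_baseline`.
#' @export
feature_combos <- function() {
  tibble::tibble(
    combo_id = 1:10,
    label = c("morgan", "descriptors", "animal_pred",
              "morgan+descriptors", "morgan+animal_pred",
              "descriptors+animal_pred",
              "morgan+descriptors+animal_pred",
              "animal_real_or_pred",
              "morgan+descriptors+animal_real_or_pred",
              "mean_baseline"),
    blocks = list(
      "morgan", "descriptors", "animal_pred",
      c("morgan", "descriptors"), c("morgan", "animal_pred"),
      c("descriptors", "animal_pred"),
      c("morgan", "descriptors", "animal_pred"),
      "animal_real_or_pred",
      c("morgan", "descriptors", "animal_real_or_pred"),
      character()),
    is_baseline = c(rep(FALSE, 9), TRUE)
  )
}

# Overlay measured animal values (same modelling scales as the
# predictions: log10 VDss/CL, raw fu) onto the predicted block,
# matching compounds by standardized SMILES.
overlay_real_animal <- function(pred_block, std_smiles, real_animal) {
  if (is.null(real_animal)) return(pred_block)
  stopifnot(inherits(real_animal, "pk_dataset"))
  idx <- match(std_smiles, real_animal$std_smiles)
  for (e in sub("_pred$", "", colnames(pred_block))) {
    col <- paste0(e, "_pred")
    real <- real_animal[[e]][idx]
    use <- !is.na(real)
    pred_block[use, col] <- real[use]
  }
  pred_block
}

#' Assemble the feature matrix for one combination
#'
#' Concatenates the requested blocks in fixed order (Morgan bits,
#' descriptors, animal PK). For `animal_real_or_pred`, measured animal
#' values overwrite the predicted ones cell-wise where available and
#' predictions fill the gaps.
#'
#' @param std_smiles Standardized SMILES of the compounds.
#' @param blocks Character subset of `morgan`, `descriptors`,
#'   `animal_pred`, `animal_real_or_pred`.
#' @param recipe Human-dataset `feature_recipe`.
#' @param animal_models `animal_model_set` (needed for animal blocks).
#' @param real_animal Curated animal `pk_dataset` for the
#'   real-where-available overlay.
#' @return Numeric feature matrix.
#' @export
assemble_features <- function(std_smiles, blocks, recipe,
                              animal_models = NULL, real_animal = NULL) {
  if (!length(blocks)) {
    stop("no feature blocks selected (non-baseline models need >= 1)",
         call. = FALSE)
  }
  parts <- list()
  if (any(c("morgan", "descriptors") %in% blocks)) {
    base <- apply_feature_recipe(std_smiles, recipe)
    if ("morgan" %in% blocks) parts$morgan <- base$morgan
    if ("descriptors" %in% blocks) parts$descriptors <- base$descriptors
  }
  if (any(c("animal_pred", "animal_real_or_pred") %in% blocks)) {
    stopifnot(!is.null(animal_models))
    ap <- predict_animal_features(std_smiles, animal_models)
    if ("animal_real_or_pred" %in% blocks) {
      ap <- overlay_real_animal(ap, std_smiles, real_animal)
    }
    parts$animal <- ap
  }
  do.call(cbind, unname(parts))
}

#' Train human pharmacokinetic models across feature combinations
#'
#' For every endpoint and requested combination: assemble the feature
#' matrix, standardize it (fit on the full modelling subset before
#' splitting), run repeated nested cross-validation, select the
#' lowest-GMFE fold's hyperparameters and refit on all annotated
#' compounds. Fold assignments are identical across combinations of the
#' same endpoint, so combination comparisons are paired. A
#' similarity-based fold-error model is fit for each endpoint on the
#' final combination's cross-validation results.
#'
#' @param human_data Curated human `pk_dataset`.
#' @param animal_models `animal_model_set` from
#'   [train_animal_models()].
#' @param config A [cv_config()].
#' @param combos Combination ids to train (default `c(7, 10)`:
#'   the released model and the baseline).
#' @param endpoints Human endpoints to model (default all five).
#' @param real_animal Curated animal dataset for combinations 8/9.
#' @param final_combo Combination released as the final model
#'   (default 7).
#' @param fit_fold_errors Fit per-endpoint fold-error models
#'   (default `TRUE` when `final_combo` is trained).
#' @return A `human_model_set`.
#' @export
train_human_models <- function(human_data, animal_models,
                               config = cv_config(),
                               combos = c(7, 10),
                               endpoints = HUMAN_ENDPOINTS,
                               real_animal = NULL, final_combo = 7,
                               fit_fold_errors = final_combo %in% combos) {
  stopifnot(inherits(human_data, "pk_dataset"),
            inherits(animal_models, "animal_model_set"))
  combo_tbl <- feature_combos()
  stopifnot(all(combos %in% combo_tbl$combo_id))
  smiles <- human_data$std_smiles
  recipe <- fit_feature_recipe(smiles)
  fingerprints <- morgan_fingerprints(smiles)

  # feature matrices per combo over all compounds, built once
  x_by_combo <- list()
  for (cid in setdiff(combos, 10)) {
    blocks <- combo_tbl$blocks[[cid]]
    x_by_combo[[as.character(cid)]] <- assemble_features(
      smiles, blocks, recipe, animal_models, real_animal)
  }

  models <- list(); cvs <- list(); scalers <- list(); fe_models <- list()
  for (e in intersect(endpoints, attr(human_data, "endpoints"))) {
    ann <- !is.na(human_data[[e]])
    y <- human_data[[e]][ann]
    log_scale <- e %in% attr(human_data, "log_transformed")
    models[[e]] <- list(); cvs[[e]] <- list(); scalers[[e]] <- list()
    for (cid in combos) {
      key <- as.character(cid)
      if (cid == 10) {
        x <- matrix(0, nrow = sum(ann), ncol = 1,
                    dimnames = list(NULL, "intercept_only"))
        cv <- suppressWarnings(nested_cv(x, y, config = config,
                                         log_scale = log_scale,
                                         model = "mean"))
        bundle <- retrain_final(x, y, list(model = "mean"),
                                seed = config$seed, log_scale = log_scale)
      } else {
        scaler <- fit_scaler(x_by_combo[[key]][ann, , drop = FALSE], drop_zero_variance = TRUE)
        x <- apply_scaler(x_by_combo[[key]][ann, , drop = FALSE], scaler)
        cv <- nested_cv(x, y, config = config, log_scale = log_scale)
        bundle <- retrain_final(x, y, select_best_fold(cv),
                                seed = config$seed, log_scale = log_scale)
        scalers[[e]][[key]] <- scaler
      }
      bundle$train_smiles <- smiles[ann]
      models[[e]][[key]] <- bundle
      cvs[[e]][[key]] <- cv
    }
    if (fit_fold_errors && as.character(final_combo) %in% names(cvs[[e]])) {
      pairs <- collect_similarity_fe_pairs(
        cvs[[e]][[as.character(final_combo)]],
        fingerprints[ann, , drop = FALSE])
      fe_models[[e]] <- fit_fold_error_model(
        pairs, train_fingerprints = fingerprints[ann, , drop = FALSE],
        seed = config$seed)
    }
  }
  structure(list(models = models, cv = cvs, scalers = scalers,
                 fe_models = fe_models, recipe = recipe,
                 animal_models = animal_models, combos = combos,
                 final_combo = final_combo, config = config,
                 endpoints = names(models),
                 units = endpoint_units(names(models)),
                 log_transformed = attr(human_data, "log_transformed")),
            class = "human_model_set")
}

#' @export
print.human_model_set <- function(x, ...) {
  cat(sprintf("<human_model_set: endpoints %s; combos %s; final combo %d>\n",
              paste(x$endpoints, collapse = "/"),
              paste(x$combos, collapse = ","), x$final_combo))
  invisible(x)
}

#' Cross-validation summary of a human model set
#'
#' @param x A `human_model_set`.
#' @param ... Unused.
#' @return Tibble with one row per (endpoint, combination).
#' @method tidy human_model_set
#' @export
tidy.human_model_set <- function(x, ...) {
  combo_tbl <- feature_combos()
  purrr::map_dfr(names(x$cv), function(e) {
    purrr::map_dfr(names(x$cv[[e]]), function(cid) {
      g <- glance(x$cv[[e]][[cid]])
      dplyr::bind_cols(
        tibble::tibble(endpoint = e, combo_id = as.integer(cid),
                       label = combo_tbl$label[[as.integer(cid)]]), g)
    })
  })
}

#' Predict human pharmacokinetic parameters for new compounds
#'
#' Standardizes the input SMILES, runs the final released models, and
#' returns natural-unit predictions with an estimated fold error, a
#' prediction range `[pred / FE, pred * FE]`, the mean 5-nearest-
#' neighbour Tanimoto similarity to the training data, and an
#' applicability-domain alert when that similarity falls below 0.25.
#' Invalid SMILES yield per-row error entries; the batch continues.
#'
#' @param smiles Raw SMILES (standardized internally).
#' @param model_set A `human_model_set`.
#' @return Long tibble: `input`, `std_smiles`, `endpoint`, `unit`,
#'   `prediction`, `fold_error`, `range_low`, `range_high`,
#'   `similarity_5nn`, `ad_alert`, `error`.
#' @export
predict_human <- function(smiles, model_set) {
  stopifnot(inherits(model_set, "human_model_set"))
  std <- suppressWarnings(standardize_smiles(smiles))
  out <- list()
  combo_tbl <- feature_combos()
  blocks <- combo_tbl$blocks[[model_set$final_combo]]
  valid <- std$ok
  if (any(valid)) {
    vs <- std$std_smiles[valid]
    x_all <- assemble_features(vs, blocks, model_set$recipe,
                               model_set$animal_models)
    fps <- morgan_fingerprints(vs)
  }
  for (e in model_set$endpoints) {
    key <- as.character(model_set$final_combo)
    bundle <- model_set$models[[e]][[key]]
    fe_model <- model_set$fe_models[[e]]
    res <- tibble::tibble(
      input = std$input, std_smiles = std$std_smiles, endpoint = e,
      unit = endpoint_units(e)[[1]],
      prediction = NA_real_, fold_error = NA_real_,
      range_low = NA_real_, range_high = NA_real_,
      similarity_5nn = NA_real_, ad_alert = NA,
      error = ifelse(std$ok, NA_character_, "unparsable SMILES"))
    if (any(valid)) {
      scaler <- model_set$scalers[[e]][[key]]
      x <- if (is.null(scaler)) x_all else apply_scaler(x_all, scaler)
      pred <- predict(bundle, x)
      nat <- if (bundle$log_scale) 10^pred else pmin(pmax(pred, 1e-4), 1)
      res$prediction[valid] <- nat
      if (!is.null(fe_model)) {
        fe <- estimate_fold_error(fps, fe_model)
        res$fold_error[valid] <- fe$fold_error
        res$similarity_5nn[valid] <- fe$similarity
        res$ad_alert[valid] <- fe$ad_alert
        res$range_low[valid] <- nat / fe$fold_error
        res$range_high[valid] <- if (bundle$log_scale)
          nat * fe$fold_error else pmin(nat * fe$fold_error, 1)
      }
    }
    out[[e]] <- res
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(match(.data$input, smiles))
}
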