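# Stage 1: nine animal models (rat/dog/monkey x VDss/CL/fu) trained on
# the curated animal dataset; their predictions become the
# cross-species feature block for the human models.

ANIMAL_FEATURE_COLS <- as.vector(outer(
  c("VDss", "CL", "fu"), ANIMAL_SPECIES,
  function(e, s) paste(e, s, "pred", sep = "_")))

#' Train the animal pharmacokinetic model set
#'
#' For each species, compounds annotated for at least one of that
#' species' endpoints define the species subset; a feature recipe
#' (selected Morgan bits + selected descriptors) is fit on it. Each of
#' the nine (species, endpoint) models is produced by nested
#' cross-validation, best-fold selection by lowest GMFE, and a final
#' refit on all annotated compounds. Feature scaling is fit on each
#' model's full modelling subset before splitting.
#'
#' @param animal_data Curated animal `pk_dataset` (log-scale VDss/CL,
#'   raw fu).
#' @param config A [cv_config()].
#' @param min_n Minimum annotated compounds per endpoint (default 25).
#' @return An `animal_model_set`: model bundles, CV results, per-species
#'   recipes and scalers.
#' @export
train_animal_models <- function(animal_data, config = cv_config(),
                                min_n = 25) {
  stopifnot(inherits(animal_data, "pk_dataset"))
  smiles <- animal_data$std_smiles
  recipes <- list()
  models <- list()
  cvs <- list()
  scalers <- list()
  for (s in ANIMAL_SPECIES) {
    eps <- paste(c("VDss", "CL", "fu"), s, sep = "_")
    sub_rows <- rowSums(!is.na(animal_data[, eps, drop = FALSE])) > 0
    recipes[[s]] <- fit_feature_recipe(smiles[sub_rows])
    blocks <- apply_feature_recipe(smiles, recipes[[s]])
    x_all <- cbind(blocks$morgan, blocks$descriptors)
    for (e in eps) {
      ann <- !is.na(animal_data[[e]])
      if (sum(ann) < min_n) {
        stop("endpoint ", e, " has only ", sum(ann),
             " annotated compounds (minimum ", min_n, ")", call. = FALSE)
      }
      y <- animal_data[[e]][ann]
      log_scale <- e %in% attr(animal_data, "log_transformed")
      scaler <- fit_scaler(x_all[ann, , drop = FALSE], drop_zero_variance = TRUE)
      x <- apply_scaler(x_all[ann, , drop = FALSE], scaler)
      cv <- nested_cv(x, y, config = config, log_scale = log_scale)
      params <- select_best_fold(cv)
      bundle <- retrain_final(x, y, params, seed = config$seed,
                              log_scale = log_scale)
      bundle$train_smiles <- smiles[ann]
      models[[e]] <- bundle
      cvs[[e]] <- cv
      scalers[[e]] <- scaler
    }
  }
  structure(list(models = models, cv = cvs, recipes = recipes,
                 scalers = scalers, config = config),
            class = "animal_model_set")
}

#' @export
print.animal_model_set <- function(x, ...) {
  cat("<animal_model_set: ", length(x$models), " models (",
      paste(names(x$models), collapse = ", "), ")>\n", sep = "")
  invisible(x)
}

#' Cross-validation summary of every animal model
#'
#' @param x An `animal_model_set`.
#' @param ... Unused.
#' @return Tibble, one row per (species, endpoint) model, with the
#'   mean and median fold metrics.
#' @method tidy animal_model_set
#' @export
tidy.animal_model_set <- function(x, ...) {
  purrr::map_dfr(names(x$cv), function(nm) {
    g <- glance(x$cv[[nm]])
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    dplyr::bind_cols(tibble::tibble(endpoint = parts[[1]],
                                    species = parts[[2]]), g)
  })
}

#' Predicted-animal-PK feature block
#'
#' Runs the nine final animal models on arbitrary compounds and returns
#' their predictions as a feature matrix: log-scale values for VDss and
#' CL passed through without back-transform, fu clipped to
#' `[1e-4, 1]`.
#'
#' @param std_smiles Standardized SMILES.
#' @param model_set An `animal_model_set`.
#' @return Numeric matrix `length(std_smiles)` x 9 with columns
#'   `VDss_rat_pred`, ..., `fu_monkey_pred`.
#' @export
predict_animal_features <- function(std_smiles, model_set) {
  stopifnot(inherits(model_set, "animal_model_set"))
  out <- matrix(NA_real_, nrow = length(std_smiles),
                ncol = length(ANIMAL_FEATURE_COLS),
                dimnames = list(std_smiles, ANIMAL_FEATURE_COLS))
  for (s in ANIMAL_SPECIES) {
    blocks <- apply_feature_recipe(std_smiles, model_set$recipes[[s]])
    x_all <- cbind(blocks$morgan, blocks$descriptors)
    for (e in paste(c("VDss", "CL", "fu"), s, sep = "_")) {
      x <- apply_scaler(x_all, model_set$scalers[[e]])
      pred <- predict(model_set$models[[e]], x)
      if (grepl("^fu_", e)) pred <- pmin(pmax(pred, 1e-4), 1)
      out[, paste0(e, "_pred")] <- pred
    }
  }
  out
}
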