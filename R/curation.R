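# Curation protocol: standardize -> merge duplicates -> molecular-weight
# filter -> decadic log transform. Every removal is counted in a
# curation report attached to the returned dataset.

HUMAN_ENDPOINTS <- c("VDss", "CL", "t_half", "fu", "MRT")
ANIMAL_SPECIES <- c("rat", "dog", "monkey")
ANIMAL_ENDPOINTS <- as.vector(outer(c("VDss", "CL", "fu"), ANIMAL_SPECIES,
                                    function(e, s) paste(e, s, sep = "_")))

endpoint_units <- function(endpoints) {
  base <- c(VDss = "L/kg", CL = "mL/min/kg", t_half = "h", fu = "", MRT = "h")
  vapply(endpoints, function(e) {
    base[[sub("_(rat|dog|monkey)$", "", e)]]
  }, character(1))
}

# fu (and fu_rat etc.) stays on its natural 0-1 scale; everything else
# is decadic-log transformed.
log_endpoints <- function(endpoints) {
  endpoints[!grepl("^fu(_|$)", endpoints)]
}

#' Construct a pharmacokinetic dataset
#'
#' A `pk_dataset` is a tibble of unique standardized compounds
#' (`std_smiles`, `mol_weight`) with sparse endpoint columns, carrying
#' the species label, unit map and the set of log-transformed endpoints
#' as attributes.
#'
#' @param data Data frame with columns `std_smiles`, `mol_weight` and
#'   endpoint columns.
#' @param species One of `"human"`, `"rat"`, `"dog"`, `"monkey"`,
#'   `"animal"`, `"external"`.
#' @param endpoints Character vector naming the endpoint columns.
#' @param log_transformed Endpoints currently stored as log10 values.
#' @return A `pk_dataset` tibble.
#' @export
pk_dataset <- function(data, species, endpoints,
                       log_transformed = character()) {
  stopifnot(all(c("std_smiles", "mol_weight") %in% names(data)),
            all(endpoints %in% names(data)))
  if (anyDuplicated(data$std_smiles)) {
    stop("std_smiles must be unique within a pk_dataset", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  structure(out,
            class = c("pk_dataset", class(out)),
            species = species,
            endpoints = endpoints,
            units = endpoint_units(endpoints),
            log_transformed = log_transformed)
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("<pk_dataset: %s, %d compounds, %d endpoints, sparsity %.1f%%>\n",
              attr(x, "species"), nrow(x), length(attr(x, "endpoints")),
              100 * dataset_sparsity(x)))
  NextMethod()
}

#' Fraction of missing endpoint cells in a dataset
#'
#' @param dataset A `pk_dataset`.
#' @return Proportion in `[0, 1]` of compound-by-endpoint cells that are
#'   unannotated.
#' @export
dataset_sparsity <- function(dataset) {
  eps <- attr(dataset, "endpoints")
  cells <- as.matrix(dataset[, eps, drop = FALSE])
  mean(is.na(cells))
}

#' Merge duplicate records by standardized SMILES
#'
#' Collapses repeated measurements of the same standardized structure to
#' one record per compound, taking the median of the available values
#' for each endpoint (the mean when exactly two records are present).
#' Endpoints missing in every duplicate stay missing.
#'
#' @param data Data frame with `std_smiles`, `mol_weight` and endpoint
#'   columns.
#' @param endpoints Endpoint column names.
#' @return Tibble with one row per unique `std_smiles`.
#' @export
merge_duplicates <- function(data, endpoints) {
  data |>
    dplyr::group_by(.data$std_smiles) |>
    dplyr::summarise(
      mol_weight = .data$mol_weight[[1]],
      dplyr::across(dplyr::all_of(endpoints),
                    ~ if (all(is.na(.x))) NA_real_ else
                      stats::median(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Molecular-weight outlier filter
#'
#' Removes compounds whose exact molecular weight exceeds
#' `mean + k * sd` of the dataset's weight distribution (upper bound
#' only; small molecules are never removed).
#'
#' @param data Data frame with a `mol_weight` column.
#' @param k Number of standard deviations above the mean (default 1.5).
#' @return The filtered data with attributes `mw_threshold` and
#'   `n_removed`.
#' @export
mw_filter <- function(data, k = 1.5) {
  if (nrow(data) < 2) {
    stop("mw_filter needs at least 2 records to estimate a standard deviation",
         call. = FALSE)
  }
  threshold <- mean(data$mol_weight) + k * stats::sd(data$mol_weight)
  keep <- data$mol_weight <= threshold
  out <- data[keep, , drop = FALSE]
  attr(out, "mw_threshold") <- threshold
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Decadic log transform of pharmacokinetic endpoints
#'
#' Replaces every endpoint except the fraction unbound (`fu`) by its
#' log10 value. `back_transform()` inverts it.
#'
#' @param dataset A `pk_dataset` on the natural scale.
#' @return The dataset with transformed columns and an updated
#'   `log_transformed` attribute.
#' @export
log_transform_endpoints <- function(dataset) {
  eps <- attr(dataset, "endpoints")
  targets <- setdiff(log_endpoints(eps), attr(dataset, "log_transformed"))
  for (e in targets) {
    vals <- dataset[[e]]
    bad <- !is.na(vals) & vals <= 0
    if (any(bad)) {
      stop("non-positive value for endpoint ", e, " in compound(s): ",
           paste(utils::head(dataset$std_smiles[bad], 3), collapse = ", "),
           call. = FALSE)
    }
    dataset[[e]] <- log10(vals)
  }
  attr(dataset, "log_transformed") <- union(attr(dataset, "log_transformed"),
                                            targets)
  dataset
}

#' Back-transform predictions to natural units
#'
#' @param values Numeric vector on the model scale.
#' @param endpoint Endpoint name.
#' @return `10^values` for log-modelled endpoints; `values` unchanged
#'   for `fu`.
#' @export
back_transform <- function(values, endpoint) {
  if (endpoint %in% log_endpoints(endpoint)) 10^values else values
}

#' Remove test compounds present in a training set
#'
#' External-set hygiene: drops every test record whose standardized
#' SMILES occurs in the training data.
#'
#' @param test,train `pk_dataset`s standardized with identical settings.
#' @return `test` restricted to compounds absent from `train`.
#' @export
remove_overlap <- function(test, train) {
  keep <- !(test$std_smiles %in% train$std_smiles)
  out <- test[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Curate a raw compound/PK table
#'
#' The full curation protocol: SMILES standardization with pH 7.4
#' protonation (failures logged and dropped), invalid endpoint values
#' set to missing (`fu` outside `(0, 1]`; non-positive values of
#' log-scale endpoints), duplicate merging by median, molecular-weight
#' filtering at `mean + mw_k * sd`, and decadic log transformation of
#' all endpoints except `fu`.
#'
#' @param data Data frame of raw records with a SMILES column and
#'   endpoint columns.
#' @param species Dataset label (`"human"`, `"animal"`, `"external"`).
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param endpoints Endpoint column names; defaults to the human or
#'   animal endpoint set depending on `species`.
#' @param mw_k Weight-filter width in standard deviations (default 1.5).
#' @param log_transform Apply the log transform (default `TRUE`).
#' @return A curated `pk_dataset`; `curation_report()` retrieves the
#'   per-step audit counts.
#' @export
curate_pk_data <- function(data, species, smiles_col = "smiles",
                           endpoints = NULL, mw_k = 1.5,
                           log_transform = TRUE) {
  if (is.null(endpoints)) {
    endpoints <- if (identical(species, "animal")) ANIMAL_ENDPOINTS else
      intersect(HUMAN_ENDPOINTS, names(data))
  }
  stopifnot(smiles_col %in% names(data), all(endpoints %in% names(data)))
  report <- list(n_input = nrow(data))

  std <- standardize_smiles(data[[smiles_col]])
  report$n_unparsable <- sum(!std$ok)
  report$unparsable <- data[[smiles_col]][!std$ok]
  work <- tibble::tibble(std_smiles = std$std_smiles,
                         mol_weight = std$mol_weight)
  work <- dplyr::bind_cols(work, data[endpoints])
  work <- work[std$ok, , drop = FALSE]

  # invalid endpoint values become missing, with an audit count
  n_invalid <- 0L
  for (e in endpoints) {
    v <- work[[e]]
    bad <- if (grepl("^fu(_|$)", e)) !is.na(v) & (v <= 0 | v > 1)
           else !is.na(v) & v <= 0
    n_invalid <- n_invalid + sum(bad)
    v[bad] <- NA_real_
    work[[e]] <- v
  }
  report$n_invalid_values <- n_invalid

  merged <- merge_duplicates(work, endpoints)
  report$n_duplicates_merged <- nrow(work) - nrow(merged)

  filtered <- mw_filter(merged, k = mw_k)
  report$mw_threshold <- attr(filtered, "mw_threshold")
  report$n_mw_removed <- attr(filtered, "n_removed")

  ds <- pk_dataset(filtered, species = species, endpoints = endpoints)
  if (log_transform) ds <- log_transform_endpoints(ds)
  report$n_final <- nrow(ds)
  report$sparsity <- dataset_sparsity(ds)
  attr(ds, "curation_report") <- report
  ds
}

#' @rdname curate_pk_data
#' @param dataset A curated `pk_dataset`.
#' @export
curation_report <- function(dataset) {
  attr(dataset, "curation_report")
}
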