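# Dataset characterization: similarity distributions, cross-species
# regressions, PCA on continuous descriptors, clearance stratification.

#' Intra-dataset nearest-neighbour similarity profile
#'
#' For every compound, the mean Tanimoto similarity of its 5 nearest
#' neighbours among the remaining compounds of the same dataset
#' (self-similarity excluded), plus the fraction of compounds falling
#' strictly below a diversity threshold.
#'
#' @param dataset A `pk_dataset`, or a fingerprint matrix.
#' @param threshold Diversity threshold (default 0.30).
#' @param k Neighbours (default 5).
#' @return List: `similarities` tibble (`std_smiles`, `mean_knn_sim`),
#'   `fraction_below`, `threshold`.
#' @export
similarity_profile <- function(dataset, threshold = 0.30, k = 5) {
  fps <- if (is.matrix(dataset)) dataset else
    morgan_fingerprints(dataset$std_smiles)
  if (nrow(fps) < k + 1) {
    stop("similarity profile needs at least ", k + 1, " compounds",
         call. = FALSE)
  }
  sims <- knn_mean_similarity(fps, fps, k = k, exclude_self = TRUE)
  tib <- tibble::tibble(std_smiles = rownames(fps) %||%
                          as.character(seq_len(nrow(fps))),
                        mean_knn_sim = sims)
  list(similarities = tib,
       fraction_below = mean(sims < threshold),
       threshold = threshold)
}

#' Observed animal-to-human endpoint regression
#'
#' Ordinary least squares of the human endpoint on the corresponding
#' animal endpoint over the compounds shared by both curated datasets
#' (matched by standardized SMILES; log scale except fu).
#'
#' @param human Curated human `pk_dataset`.
#' @param animal Curated animal `pk_dataset`.
#' @param endpoint One of `"VDss"`, `"CL"`, `"fu"`.
#' @param species One of `"rat"`, `"dog"`, `"monkey"`.
#' @return One-row tibble: `endpoint`, `species`, `slope`, `intercept`,
#'   `r2`, `n`.
#' @export
cross_species_regression <- function(human, animal, endpoint, species) {
  acol <- paste(endpoint, species, sep = "_")
  stopifnot(endpoint %in% names(human), acol %in% names(animal))
  idx <- match(human$std_smiles, animal$std_smiles)
  h <- human[[endpoint]]
  a <- animal[[acol]][idx]
  keep <- !is.na(h) & !is.na(a)
  if (sum(keep) < 3) {
    stop("fewer than 3 overlapping annotated compounds for ", acol,
         call. = FALSE)
  }
  fit <- stats::lm(h[keep] ~ a[keep])
  tibble::tibble(endpoint = endpoint, species = species,
                 slope = unname(stats::coef(fit)[[2]]),
                 intercept = unname(stats::coef(fit)[[1]]),
                 r2 = summary(fit)$r.squared,
                 n = sum(keep))
}

#' PCA projection of continuous descriptors
#'
#' Fits a principal component analysis on the continuous (non-binary:
#' more than two distinct values) descriptor columns of a reference
#' block and projects any further blocks with the same loadings.
#'
#' @param reference Numeric descriptor matrix used to fit the PCA.
#' @param ... Further descriptor matrices (same columns) to project.
#' @param n_components Components to keep (default 2).
#' @return List: `scores` tibble with a `dataset` column (`"reference"`
#'   then the names or indices of `...`), `loadings`,
#'   `continuous_descriptors`, `variance_explained`.
#' @export
pca_projection <- function(reference, ..., n_components = 2) {
  distinct <- apply(reference, 2, function(col)
    length(unique(col[!is.na(col)])))
  continuous <- colnames(reference)[distinct > 2]
  ref <- reference[, continuous, drop = FALSE]
  ref[is.na(ref)] <- 0
  pca <- stats::prcomp(ref, center = TRUE, scale. = TRUE)
  n_components <- min(n_components, ncol(pca$x))
  project <- function(m, label) {
    if (!all(continuous %in% colnames(m))) {
      stop("projected block lacks the reference's continuous descriptors",
           call. = FALSE)
    }
    m <- m[, continuous, drop = FALSE]
    m[is.na(m)] <- 0
    sc <- stats::predict(pca, m)[, seq_len(n_components), drop = FALSE]
    tibble::as_tibble(sc) |> dplyr::mutate(dataset = label, .before = 1)
  }
  others <- list(...)
  labels <- names(others) %||% as.character(seq_along(others))
  if (length(others) && is.null(names(others))) names(others) <- labels
  scores <- dplyr::bind_rows(
    project(reference, "reference"),
    purrr::imap_dfr(others, function(m, nm) project(m, nm)))
  list(scores = scores,
       loadings = pca$rotation[, seq_len(n_components), drop = FALSE],
       continuous_descriptors = continuous,
       variance_explained = (pca$sdev^2 / sum(pca$sdev^2)))
}

#' Clearance-stratified prediction accuracy
#'
#' Splits compounds into low (< 5), low-to-intermediate (< 12) and high
#' (> 20 mL/min/kg) clearance strata and reports the percentage
#' predicted within twofold in each, plus the low/high split at
#' 25 mL/min/kg.
#'
#' @param cl_true,cl_pred Observed and predicted clearance on the
#'   natural scale (mL/min/kg).
#' @return Tibble: `stratum`, `n`, `pct_within_2fold`.
#' @export
clearance_strata <- function(cl_true, cl_pred) {
  keep <- !is.na(cl_true) & !is.na(cl_pred)
  cl_true <- cl_true[keep]; cl_pred <- cl_pred[keep]
  fe <- fold_error(pmax(cl_pred, 1e-4), pmax(cl_true, 1e-4))
  strata <- list(
    "low (< 5 mL/min/kg)" = cl_true < 5,
    "low-intermediate (< 12 mL/min/kg)" = cl_true < 12,
    "high (> 20 mL/min/kg)" = cl_true > 20,
    "low CL (<= 25 mL/min/kg)" = cl_true <= 25,
    "high CL (> 25 mL/min/kg)" = cl_true > 25)
  purrr::map_dfr(names(strata), function(nm) {
    sel <- strata[[nm]]
    tibble::tibble(stratum = nm, n = sum(sel),
                   pct_within_2fold = if (sum(sel)) 100 * mean(fe[sel] <= 2)
                   else NA_real_)
  })
}
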