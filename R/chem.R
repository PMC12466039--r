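# RDKit-backed cheminformatics primitives. All heavy lifting is batched
# through one subprocess call per request and memoised per session, so
# repeated featurization of the same molecules is free.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("pkcascade.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("No python interpreter found; set options(pkcascade.python = ...)",
         call. = FALSE)
  }
  py
}

chem_tool_path <- function() {
  path <- system.file("python", "chem_tools.py", package = "pkcascade")
  if (!nzchar(path)) stop("chem_tools.py not found in package installation")
  path
}

run_chem_tool <- function(command, smiles) {
  infile <- tempfile("smiles-")
  writeLines(smiles, infile)
  on.exit(unlink(infile), add = TRUE)
  out <- suppressWarnings(
    system2(chem_python(), c(shQuote(chem_tool_path()), command),
            stdin = infile, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (exit ", status, ")", call. = FALSE)
  }
  out
}

# Batched, memoised dispatch: only cache misses hit the subprocess.
chem_query <- function(command, smiles) {
  keys <- paste0(command, "\r", smiles)
  miss <- !vapply(keys, exists, logical(1), envir = .chem_cache)
  if (any(miss)) {
    uniq <- unique(smiles[miss])
    lines <- run_chem_tool(command, uniq)
    if (command == "descriptors") {
      header <- lines[[1]]
      lines <- lines[-1]
      assign(paste0(".header.", command), header, envir = .chem_cache)
    }
    stopifnot(length(lines) == length(uniq))
    for (i in seq_along(uniq)) {
      assign(paste0(command, "\r", uniq[[i]]), lines[[i]], envir = .chem_cache)
    }
  }
  vapply(keys, get, character(1), envir = .chem_cache, USE.NAMES = FALSE)
}

#' Standardize SMILES with pH 7.4 protonation
#'
#' Applies the curation-grade standardization pipeline: sanitization,
#' normalization, largest-fragment selection (dropping counter-ions),
#' canonical-tautomer selection, then a deterministic rule-based
#' protonation at pH 7.4 (carboxylic, sulfonic and phosphonic acids and
#' tetrazoles deprotonated; aliphatic amines, amidines and guanidines
#' protonated). The result is a canonical SMILES; re-standardizing the
#' output returns it unchanged.
#'
#' @param smiles Character vector of input SMILES.
#' @return A tibble with one row per input: `input`, `std_smiles`,
#'   `mol_weight` (exact molecular weight, Da) and `ok`. Unparsable
#'   inputs get `ok = FALSE` with `NA` results and a warning listing
#'   them; they are never silently dropped.
#' @examples
#' \dontrun{
#' standardize_smiles(c("CCO.Cl", "CC(=O)O"))
#' }
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0, all(nzchar(smiles)))
  lines <- chem_query("standardize", smiles)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) p[[1]] == "ok", logical(1))
  res <- tibble::tibble(
    input = smiles,
    std_smiles = ifelse(ok, vapply(parts, `[`, character(1), 2), NA_character_),
    mol_weight = ifelse(ok, suppressWarnings(
      as.numeric(vapply(parts, `[`, character(1), 3))), NA_real_),
    ok = ok
  )
  if (any(!ok)) {
    warning("standardization failed for ", sum(!ok), " SMILES: ",
            paste(utils::head(smiles[!ok], 5), collapse = ", "),
            if (sum(!ok) > 5) ", ..." else "", call. = FALSE)
  }
  res
}

#' Morgan fingerprints (radius 2, 2048 bits)
#'
#' Circular substructure fingerprints hashed to a fixed 2048-bit vector,
#' the structural representation used throughout the pipeline and for
#' Tanimoto similarity.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @return Integer matrix of 0/1 with `length(smiles)` rows and 2048
#'   columns, rownames set to the input SMILES.
#' @export
morgan_fingerprints <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  lines <- chem_query("fingerprint", smiles)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) p[[1]] != "ok", logical(1))
  if (any(bad)) {
    stop("fingerprint failed for SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "), call. = FALSE)
  }
  fp <- matrix(0L, nrow = length(smiles), ncol = 2048,
               dimnames = list(smiles, paste0("fp_", seq_len(2048))))
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) >= 2 && nzchar(parts[[i]][[2]])) {
      idx <- as.integer(strsplit(parts[[i]][[2]], " ", fixed = TRUE)[[1]])
      fp[i, idx] <- 1L
    }
  }
  fp
}

#' Physicochemical 2D descriptor block
#'
#' Computes the full RDKit 2D descriptor set (210 descriptors covering
#' constitutional, topological, electrotopological and estimated
#' property descriptors). Values that cannot be computed for a molecule
#' are returned as `NA`.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @return Numeric matrix, one row per molecule, descriptor names as
#'   column names, rownames set to the input SMILES.
#' @export
physchem_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  lines <- chem_query("descriptors", smiles)
  header <- get(".header.descriptors", envir = .chem_cache)
  names <- strsplit(header, "\t", fixed = TRUE)[[1]][-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) p[[1]] != "ok", logical(1))
  if (any(bad)) {
    stop("descriptor computation failed for SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "), call. = FALSE)
  }
  vals <- vapply(parts, function(p) {
    suppressWarnings(as.numeric(p[-1]))
  }, numeric(length(names)))
  m <- t(vals)
  dimnames(m) <- list(smiles, names)
  m
}

#' Pairwise Tanimoto similarity between fingerprint sets
#'
#' @param fp_a,fp_b Binary fingerprint matrices (rows = molecules) with
#'   identical column counts.
#' @return Numeric matrix `nrow(fp_a)` x `nrow(fp_b)` of Tanimoto
#'   (Jaccard) similarities in `[0, 1]`. Two all-zero fingerprints have
#'   similarity 0 by convention.
#' @export
tanimoto_similarity <- function(fp_a, fp_b) {
  stopifnot(ncol(fp_a) == ncol(fp_b))
  a <- matrix(as.numeric(fp_a), nrow = nrow(fp_a))
  b <- matrix(as.numeric(fp_b), nrow = nrow(fp_b))
  inter <- a %*% t(b)
  na <- rowSums(a)
  nb <- rowSums(b)
  union <- outer(na, nb, "+") - inter
  sim <- ifelse(union == 0, 0, inter / union)
  dimnames(sim) <- list(rownames(fp_a), rownames(fp_b))
  sim
}
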