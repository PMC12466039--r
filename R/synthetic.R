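# Seeded synthetic-data generator. Produces raw compound/PK tables
# (with duplicate and salt-form records to exercise the curation
# protocol) whose endpoints follow a known generative model: a
# structural signal linear in continuous descriptors, a shared
# per-compound latent linking species, and Gaussian noise on the log
# scale. fu is mapped to (0, 1) through a decadic logistic link.

SIGNAL_DESCRIPTORS <- c("MolLogP", "TPSA", "MolWt", "NumRotatableBonds",
                        "FractionCSP3", "NumHAcceptors", "RingCount")

#' Bundled drug-like SMILES pool
#'
#' @return Character vector of the packaged SMILES (raw, pre-curation
#'   forms).
#' @export
smiles_pool <- function() {
  path <- system.file("extdata", "smiles_pool.smi", package = "pkcascade")
  readLines(path)
}

# Deterministic combinatorial expansion used when more structures are
# requested than the bundled pool provides: left fragment + substituted
# core, enumerated in fixed order.
expand_scaffold_smiles <- function() {
  lefts <- c("C", "CC", "CCC", "CC(C)", "CCO", "COC", "CC(=O)N", "CCN(CC)",
             "OC(=O)", "CNC(=O)", "CS(=O)(=O)N", "FC(F)(F)", "OCC", "N#C",
             "CCCN", "OCCO", "CC(O)", "CN(C)C(=O)")
  cores <- c("c1ccc(%s)cc1", "c1ccc(%s)cn1", "c1ccc(%s)nc1", "c1cc(%s)ccn1",
             "c1ccc2cc(%s)ccc2c1", "C1CCN(%s)CC1", "C1CCC(%s)CC1",
             "c1csc(%s)c1", "c1ccc2[nH]c(%s)cc2c1", "c1ccc(-c2ccc(%s)cc2)cc1",
             "C1CN(%s)CCN1C", "c1ccc2occ(%s)c2c1", "c1cnc2cc(%s)ccc2c1",
             "C1COC(%s)C1")
  subs <- c("C", "CC", "O", "OC", "N", "NC", "N(C)C", "Cl", "F", "Br",
            "C(F)(F)F", "C(=O)O", "C(=O)N", "C(=O)OC", "S(N)(=O)=O", "C#N",
            "CO", "CN", "CCN", "OCC", "C(C)C", "OC(F)F", "NC(C)=O", "CCl",
            "S(C)(=O)=O", "[N+](=O)[O-]", "C(=O)C", "OCC(O)CO", "CCCC", "NCC",
            "CCO", "OCCN", "C(F)F", "CC(C)C")
  combos <- expand.grid(sub = subs, core = cores, left = lefts,
                        stringsAsFactors = FALSE)
  paste0(combos$left, sprintf(combos$core, combos$sub))
}

#' Specification for a synthetic pharmacokinetic study
#'
#' Defaults emulate the curated study conditions of the modelling
#' datasets: 1,283 human compounds, 371 animal compounds, 300 shared,
#' per-endpoint missingness matching the published annotation counts,
#' and effect sizes placing structure-only models in the R^2 0.4-0.6
#' regime.
#'
#' @param n_human,n_animal Unique compounds in the human and animal
#'   tables.
#' @param n_overlap Compounds present in both.
#' @param signal_fraction Fraction of log-scale endpoint variance
#'   carried by the structural (descriptor-linear) signal.
#' @param cross_species_weight Fraction of variance carried by a shared
#'   per-compound latent that links species beyond structure (0 removes
#'   the cross-species channel; the remainder is independent noise).
#' @param sparsity_human,sparsity_animal Named per-endpoint missing
#'   fractions.
#' @param n_duplicates Extra duplicated records (jittered endpoint
#'   values) injected to exercise median merging.
#' @param n_salts Extra salt-form records (`.Cl` counter-ion appended).
#' @param seed Seed; identical spec + seed reproduces the dataset
#'   exactly.
#' @return A `synthetic_pk_spec` list.
#' @export
synthetic_pk_spec <- function(n_human = 1283, n_animal = 371,
                              n_overlap = 300,
                              signal_fraction = 0.55,
                              cross_species_weight = 0.15,
                              sparsity_human = c(VDss = 0.027, CL = 0.002,
                                                 t_half = 0.014, fu = 0.315,
                                                 MRT = 0.031),
                              sparsity_animal = c(rat = 0.127, dog = 0.288,
                                                  monkey = 0.5),
                              n_duplicates = 12, n_salts = 8, seed = 1) {
  stopifnot(n_overlap <= min(n_human, n_animal),
            signal_fraction + cross_species_weight <= 1,
            signal_fraction >= 0, cross_species_weight >= 0)
  structure(list(n_human = n_human, n_animal = n_animal,
                 n_overlap = n_overlap,
                 signal_fraction = signal_fraction,
                 cross_species_weight = cross_species_weight,
                 sparsity_human = sparsity_human,
                 sparsity_animal = sparsity_animal,
                 n_duplicates = n_duplicates, n_salts = n_salts,
                 seed = seed),
            class = "synthetic_pk_spec")
}

# location/scale of each endpoint family on the log10 scale (fu is the
# location of the logistic-link latent)
ENDPOINT_LOCATION <- c(VDss = 0.0, CL = 0.9, t_half = 0.5, MRT = 0.6,
                       fu = -0.5)
ENDPOINT_SCALE <- c(VDss = 0.6, CL = 0.6, t_half = 0.5, MRT = 0.5, fu = 1.0)

#' Generate a synthetic human + animal pharmacokinetic study
#'
#' Draws unique compounds from the bundled pool (expanding combinatorial
#' scaffolds deterministically when more are needed), builds endpoint
#' values from the generative model of [synthetic_pk_spec()], applies
#' per-endpoint missingness, and injects duplicate and salt-form raw
#' records. Values are returned in natural units (L/kg, mL/min/kg, h,
#' dimensionless fu).
#'
#' @param spec A [synthetic_pk_spec()].
#' @return List with raw tibbles `human` (`smiles` + human endpoints)
#'   and `animal` (`smiles` + `VDss_rat`, ..., `fu_monkey`), and
#'   `truth`: the generative parameters (descriptor coefficients,
#'   latents, per-compound structural signals, chosen compounds).
#' @export
generate_pk_data <- function(spec = synthetic_pk_spec()) {
  stopifnot(inherits(spec, "synthetic_pk_spec"))
  n_unique <- spec$n_human + spec$n_animal - spec$n_overlap

  pool <- smiles_pool()
  if (n_unique > length(pool) + length(expand_scaffold_smiles())) {
    stop("requested ", n_unique, " unique compounds but at most ",
         length(pool) + length(expand_scaffold_smiles()),
         " are available from the pool and scaffold expansion",
         call. = FALSE)
  }
  std <- standardize_smiles(pool)
  std <- std[std$ok & !duplicated(std$std_smiles), ]
  if (nrow(std) < n_unique) {
    extra <- setdiff(expand_scaffold_smiles(), pool)
    need <- n_unique - nrow(std)
    taken <- 0L
    chunk <- 1L
    while (taken < length(extra) && nrow(std) < n_unique) {
      idx <- seq(taken + 1L, min(taken + max(4L * need, 200L), length(extra)))
      taken <- max(idx)
      more <- suppressWarnings(standardize_smiles(extra[idx]))
      more <- more[more$ok & !is.na(more$std_smiles), ]
      more <- more[!(more$std_smiles %in% std$std_smiles) &
                     !duplicated(more$std_smiles), ]
      std <- rbind(std, more)
      chunk <- chunk + 1L
    }
    if (nrow(std) < n_unique) {
      stop("requested ", n_unique, " unique compounds but only ",
           nrow(std), " available from the pool and scaffold expansion",
           call. = FALSE)
    }
  }
  std <- std[seq_len(n_unique), ]

  desc <- physchem_descriptors(std$std_smiles)[, SIGNAL_DESCRIPTORS,
                                               drop = FALSE]
  desc[is.na(desc)] <- 0
  z <- scale(desc)
  z[is.nan(z)] <- 0

  set.seed(spec$seed)
  # per-endpoint-family descriptor coefficient vectors
  fams <- names(ENDPOINT_LOCATION)
  coefs <- lapply(fams, function(f)
    stats::rnorm(length(SIGNAL_DESCRIPTORS)))
  names(coefs) <- fams
  structural <- vapply(fams, function(f) {
    s <- as.vector(z %*% coefs[[f]])
    as.vector(scale(s))
  }, numeric(n_unique))
  latent <- stats::rnorm(n_unique)

  f_s <- spec$signal_fraction
  f_l <- spec$cross_species_weight
  f_n <- 1 - f_s - f_l
  make_log_values <- function(fam, species_tag) {
    eps <- stats::rnorm(n_unique)
    zval <- sqrt(f_s) * structural[, fam] + sqrt(f_l) * latent +
      sqrt(f_n) * eps
    ENDPOINT_LOCATION[[fam]] + ENDPOINT_SCALE[[fam]] * zval
  }

  human_idx <- seq_len(spec$n_human)
  animal_idx <- c(seq_len(spec$n_overlap),
                  seq(spec$n_human + 1, length.out = spec$n_animal -
                        spec$n_overlap))

  human <- tibble::tibble(smiles = std$input[human_idx])
  for (e in c("VDss", "CL", "t_half", "fu", "MRT")) {
    lv <- make_log_values(e, "human")[human_idx]
    vals <- if (e == "fu") 1 / (1 + 10^(-lv)) else 10^lv
    miss <- stats::runif(length(vals)) < spec$sparsity_human[[e]]
    vals[miss] <- NA_real_
    human[[e]] <- vals
  }

  animal <- tibble::tibble(smiles = std$input[animal_idx])
  for (s in ANIMAL_SPECIES) {
    for (e in c("VDss", "CL", "fu")) {
      lv <- make_log_values(e, s)[animal_idx]
      vals <- if (e == "fu") 1 / (1 + 10^(-lv)) else 10^lv
      miss <- stats::runif(length(vals)) < spec$sparsity_animal[[s]]
      vals[miss] <- NA_real_
      animal[[paste(e, s, sep = "_")]] <- vals
    }
  }

  inject_raw_records <- function(tab, n_dup, n_salt) {
    eps_cols <- setdiff(names(tab), "smiles")
    if (n_dup > 0 && nrow(tab) > 0) {
      rows <- tab[rep_len(seq_len(nrow(tab)), n_dup), ]
      for (e in eps_cols) {
        rows[[e]] <- rows[[e]] * stats::runif(n_dup, 0.8, 1.25)
      }
      if ("fu" %in% eps_cols) rows$fu <- pmin(rows$fu, 0.999)
      for (e in grep("^fu_", eps_cols, value = TRUE)) {
        rows[[e]] <- pmin(rows[[e]], 0.999)
      }
      tab <- rbind(tab, rows)
    }
    if (n_salt > 0 && nrow(tab) > 0) {
      rows <- tab[rep_len(seq_len(min(n_salt, nrow(tab))), n_salt), ]
      rows$smiles <- paste0(rows$smiles, ".Cl")
      tab <- rbind(tab, rows)
    }
    tab
  }
  human <- inject_raw_records(human, spec$n_duplicates, spec$n_salts)
  animal <- inject_raw_records(animal, max(1L, spec$n_duplicates %/% 2),
                               max(1L, spec$n_salts %/% 2))

  list(human = human, animal = animal,
       truth = list(spec = spec, std_smiles = std$std_smiles,
                    coefs = coefs, structural = structural,
                    latent = latent, human_idx = human_idx,
                    animal_idx = animal_idx,
                    signal_descriptors = SIGNAL_DESCRIPTORS))
}

#' Generate and curate a synthetic study in one step
#'
#' Convenience wrapper running [generate_pk_data()] then
#' [curate_pk_data()] on both tables.
#'
#' @inheritParams generate_pk_data
#' @return List with curated `pk_dataset`s `human` and `animal`, plus
#'   `truth`.
#' @export
generate_curated_pk_data <- function(spec = synthetic_pk_spec()) {
  raw <- generate_pk_data(spec)
  list(
    human = suppressWarnings(curate_pk_data(raw$human, species = "human")),
    animal = suppressWarnings(curate_pk_data(raw$animal, species = "animal")),
    truth = raw$truth
  )
}
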