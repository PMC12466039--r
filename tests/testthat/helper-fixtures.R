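# Shared fixtures, computed lazily and memoised for the whole run.
# Problem sizes are kept small; the generator's statistical structure
# (cross-species signal, sparsity, duplicates, salts) is what matters.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_spec <- function() {
  synthetic_pk_spec(
    n_human = 140, n_animal = 110, n_overlap = 45,
    sparsity_animal = c(rat = 0.10, dog = 0.20, monkey = 0.30),
    seed = 101)
}

fx_data <- function() memo("data", generate_curated_pk_data(fx_spec()))

fx_cfg <- function() {
  cv_config(n_repeats = 2, n_outer = 3, n_inner = 3,
            grid = small_rf_grid(), seed = 202)
}

fx_animal_models <- function() {
  memo("animal_models", train_animal_models(fx_data()$animal, fx_cfg()))
}

fx_human_models <- function() {
  memo("human_models", train_human_models(
    fx_data()$human, fx_animal_models(), config = fx_cfg(),
    combos = c(1, 7, 10), endpoints = c("VDss", "fu"),
    real_animal = fx_data()$animal))
}

# quick deterministic toy fingerprints: n molecules over `bits` bits
toy_fingerprints <- function(n, bits = 64, density = 0.25, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * bits, 1, density), nrow = n,
              dimnames = list(paste0("mol", seq_len(n)),
                              paste0("b", seq_len(bits))))
  storage.mode(m) <- "integer"
  m
}

# brute-force Tanimoto for oracle checks
tanimoto_brute <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 0 else inter / uni
}
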