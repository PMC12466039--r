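# Small linear-signal dataset for harness checks (no chemistry needed).
linear_case <- function(n = 60, p = 8, noise = 0.3, seed = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(1, -0.8, 0.5, rep(0, p - 3))
  list(x = x, y = as.vector(x %*% beta) * 0.3 + rnorm(n, sd = noise))
}

quick_cfg <- function(seed = 42, repeats = 2) {
  cv_config(n_repeats = repeats, n_outer = 3, n_inner = 2,
            grid = tidyr::expand_grid(num_trees = 100, max_depth = 0,
                                      min_node = c(3, 5), mtry_frac = NA),
            seed = seed)
}

test_that("every compound is held out exactly once per repeat", {
  d <- linear_case()
  cv <- nested_cv(d$x, d$y, quick_cfg())
  counts <- table(cv$predictions$row, cv$predictions$repeat_)
  expect_true(all(counts == 1))
  expect_identical(nrow(cv$folds),
                   as.integer(cv$config$n_repeats * cv$config$n_outer))
  # train/test disjoint in every fold
  for (i in seq_len(nrow(cv$folds))) {
    te <- cv$predictions$row[cv$predictions$repeat_ == cv$folds$repeat_[[i]] &
                               cv$predictions$fold == cv$folds$fold[[i]]]
    expect_length(intersect(te, cv$folds$train_rows[[i]]), 0)
  }
})

test_that("identical data, config and seed reproduce the run exactly", {
  d <- linear_case()
  cv1 <- nested_cv(d$x, d$y, quick_cfg())
  cv2 <- nested_cv(d$x, d$y, quick_cfg())
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(tidy(cv1)$gmfe, tidy(cv2)$gmfe)
  cv3 <- nested_cv(d$x, d$y, quick_cfg(seed = 43))
  expect_false(identical(cv1$predictions$y_pred, cv3$predictions$y_pred))
})

test_that("a real signal is recovered and pure noise is not", {
  d <- linear_case(n = 80, noise = 0.15)
  cv <- nested_cv(d$x, d$y, quick_cfg())
  expect_gt(glance(cv)$median_r2, 0.3)

  set.seed(99)
  noise_y <- rnorm(60)
  cvn <- nested_cv(d$x[1:60, ], noise_y, quick_cfg())
  expect_lt(glance(cvn)$median_r2, 0.15)
})

test_that("best-fold selection takes the GMFE argmin with simplicity ties", {
  d <- linear_case()
  cv <- nested_cv(d$x, d$y, quick_cfg())
  best <- select_best_fold(cv)
  i_min <- which.min(cv$folds$gmfe)
  expect_identical(best, cv$folds$params[[i_min]])

  # tie-break: equal GMFE -> fewer trees, then shallower depth
  fake <- cv
  fake$folds <- fake$folds[1:3, ]
  fake$folds$gmfe <- c(2, 2, 2)
  fake$folds$params <- list(
    list(num_trees = 500, max_depth = 0, min_node = 1, mtry_frac = NA),
    list(num_trees = 100, max_depth = 8, min_node = 1, mtry_frac = NA),
    list(num_trees = 100, max_depth = 0, min_node = 1, mtry_frac = NA))
  expect_identical(select_best_fold(fake)$num_trees, 100)
  expect_identical(select_best_fold(fake)$max_depth, 8)
})

test_that("final bundle round-trips serialization and validates schema", {
  d <- linear_case()
  bundle <- retrain_final(d$x, d$y,
                          list(num_trees = 100, max_depth = 0,
                               min_node = 3, mtry_frac = NA), seed = 7)
  p1 <- predict(bundle, d$x)
  path <- tempfile(fileext = ".rds")
  saveRDS(bundle, path)
  p2 <- predict(readRDS(path), d$x)
  expect_identical(p1, p2)
  # column order is normalized by name; missing columns error
  shuffled <- d$x[, rev(colnames(d$x))]
  expect_equal(predict(bundle, shuffled), p1, tolerance = 1e-12)
  expect_error(predict(bundle, d$x[, 1:3]), "feature columns")
  # in-sample fit is at least as good as held-out performance
  cv <- nested_cv(d$x, d$y, quick_cfg())
  in_sample <- gmfe(10^p1, 10^d$y)
  expect_lte(in_sample, median(tidy(cv)$gmfe))
})

test_that("mean baseline predicts the training mean and scores R2 <= 0", {
  d <- linear_case(n = 50)
  cv <- nested_cv(d$x, d$y, quick_cfg(), model = "mean")
  expect_lte(glance(cv)$median_r2, 0)
  bundle <- retrain_final(d$x, d$y, list(model = "mean"))
  expect_equal(predict(bundle, d$x), rep(mean(d$y), 50), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or flagged", {
  d <- linear_case(n = 20)
  cfg <- quick_cfg()
  expect_error(nested_cv(d$x[1:2, ], d$y[1:2], cfg), "fewer samples")
  expect_warning(nested_cv(d$x, rep(1, 20), cfg), "constant response")
})
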