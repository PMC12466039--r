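test_that("knn mean similarity matches the brute-force top-k mean", {
  train <- toy_fingerprints(6, bits = 32, seed = 7)
  query <- toy_fingerprints(3, bits = 32, seed = 8)
  got <- knn_mean_similarity(query, train, k = 5)
  for (i in 1:3) {
    sims <- sapply(1:6, function(j) tanimoto_brute(query[i, ], train[j, ]))
    expect_equal(got[[i]], mean(sort(sims, decreasing = TRUE)[1:5]),
                 tolerance = 1e-12)
  }
  # identical to >= 5 training compounds -> 1
  same <- train[rep(1, 6), ]
  expect_equal(unname(knn_mean_similarity(train[1, , drop = FALSE], same,
                                          k = 5)), 1)
  # disjoint bits -> 0
  zq <- matrix(c(rep(1L, 16), rep(0L, 16)), 1)
  zt <- matrix(c(rep(0L, 16), rep(1L, 16)), 4, 32, byrow = TRUE)
  expect_equal(unname(knn_mean_similarity(zq, zt, k = 2)), 0)
  expect_error(knn_mean_similarity(zq, zt[0, , drop = FALSE]), "empty")
  # excluding self drops one perfect match
  expect_lt(knn_mean_similarity(train[1, , drop = FALSE], train, k = 5,
                                exclude_self = TRUE)[[1]], 1)
})

test_that("similarity/fold-error pairs bin correctly on a controlled cv", {
  d <- list(x = toy_fingerprints(30, bits = 64, seed = 21))
  storage.mode(d$x) <- "double"
  set.seed(22)
  y <- rnorm(30)
  cfg <- cv_config(n_repeats = 1, n_outer = 3, n_inner = 2,
                   grid = tidyr::expand_grid(num_trees = 50, max_depth = 0,
                                             min_node = 5, mtry_frac = NA),
                   seed = 5)
  cv <- nested_cv(d$x, y, cfg)
  fps <- toy_fingerprints(30, bits = 64, seed = 21)
  pairs <- collect_similarity_fe_pairs(cv, fps, sd_filter = Inf)
  raw <- attr(pairs, "compound_pairs")
  expect_identical(nrow(raw), 30L)
  expect_true(all(raw$fe >= 1))
  expect_true(all(pairs$similarity >= 0 & pairs$similarity <= 1))
  # bin means recompute from the raw pairs
  manual <- raw |>
    dplyr::mutate(bin = round(similarity, 2)) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(m = mean(fe)) |>
    dplyr::arrange(bin)
  expect_equal(pairs$mean_fe[order(pairs$similarity)], manual$m,
               tolerance = 1e-12)
  # perfect predictions give all-1 bins
  cv_perf <- cv
  cv_perf$predictions$y_pred <- cv_perf$predictions$y_true
  bins <- collect_similarity_fe_pairs(cv_perf, fps, sd_filter = Inf)
  expect_true(all(bins$mean_fe == 1))
  # the low-similarity filter drops compounds below mean - 1.5 sd
  filt <- collect_similarity_fe_pairs(cv, fps, sd_filter = 1.5)
  cutoff <- mean(raw$similarity) - 1.5 * sd(raw$similarity)
  expect_true(all(attr(filt, "compound_pairs")$similarity >= cutoff))
})

test_that("kernel ridge recovers a smooth curve and shrinks pure noise", {
  set.seed(31)
  x <- round(runif(60, 0.05, 0.95), 2)
  y_smooth <- 3 - 2 * x + rnorm(60, sd = 0.02)
  pairs <- tibble::tibble(similarity = x, mean_fe = y_smooth)
  fit <- fit_fold_error_model(pairs, seed = 1)
  expect_gt(fit$cv_r2, 0.9)
  curve <- fold_error_curve(fit, similarity = sort(unique(x)))
  expect_equal(curve$fold_error, 3 - 2 * sort(unique(x)), tolerance = 0.15)

  y_noise <- rnorm(60, mean = 2.5, sd = 0.3)
  fitn <- fit_fold_error_model(
    tibble::tibble(similarity = x, mean_fe = y_noise), seed = 1)
  preds <- fold_error_curve(fitn, similarity = seq(0.2, 0.8, 0.1))
  expect_true(all(abs(preds$fold_error - mean(y_noise)) < 0.5))

  # determinism of the grid search
  fit2 <- fit_fold_error_model(pairs, seed = 1)
  expect_identical(fit$grid_best, fit2$grid_best)
  expect_error(fit_fold_error_model(
    tibble::tibble(similarity = rep(0.5, 25), mean_fe = 2)), "degenerate")
})

test_that("fold-error estimates are clipped at 1 and alert below 0.25", {
  set.seed(41)
  train <- toy_fingerprints(20, bits = 2048, density = 0.02, seed = 42)
  # give the first compound five identical neighbours so its mean 5-NN
  # similarity is exactly 1
  train[2:6, ] <- train[rep(1, 5), ]
  x <- round(runif(40, 0.05, 0.95), 2)
  pairs <- tibble::tibble(similarity = x, mean_fe = 4 - 3.4 * x)
  fem <- fit_fold_error_model(pairs, train_fingerprints = train, seed = 2)

  self <- estimate_fold_error(train[1, , drop = FALSE], fem)
  expect_equal(self$similarity[[1]], 1)
  expect_false(self$ad_alert[[1]])
  expect_true(all(self$fold_error >= 1))
  # and the reported similarity matches the brute-force mean 5-NN value
  lone <- toy_fingerprints(1, bits = 2048, density = 0.02, seed = 77)
  est_lone <- estimate_fold_error(lone, fem)
  sims <- sort(apply(train, 1, tanimoto_brute, b = lone[1, ]),
               decreasing = TRUE)
  expect_equal(est_lone$similarity[[1]], mean(sims[1:5]), tolerance = 1e-12)

  # empty fingerprint has similarity 0 -> alert
  far <- matrix(0L, 1, 2048)
  est <- estimate_fold_error(far, fem)
  expect_true(est$ad_alert)

  # boundary convention is strict less-than
  fem_fake <- fem
  expect_false(0.25 < fem$ad_threshold)
})
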