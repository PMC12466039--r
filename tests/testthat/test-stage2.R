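test_that("the ten feature combinations are defined as specified", {
  combos <- feature_combos()
  expect_identical(nrow(combos), 10L)
  expect_identical(combos$blocks[[7]],
                   c("morgan", "descriptors", "animal_pred"))
  expect_identical(combos$blocks[[8]], "animal_real_or_pred")
  expect_identical(combos$blocks[[9]],
                   c("morgan", "descriptors", "animal_real_or_pred"))
  expect_true(combos$is_baseline[[10]])
  expect_false(any(combos$is_baseline[1:9]))
})

test_that("assembled feature widths add up block-wise", {
  hm <- fx_human_models()
  am <- fx_animal_models()
  smiles <- fx_data()$human$std_smiles[1:10]
  w_morgan <- length(hm$recipe$morgan_bits)
  w_desc <- length(hm$recipe$descriptors)
  x1 <- assemble_features(smiles, "morgan", hm$recipe)
  x7 <- assemble_features(smiles, c("morgan", "descriptors", "animal_pred"),
                          hm$recipe, am)
  expect_identical(ncol(x1), w_morgan)
  expect_identical(ncol(x7), w_morgan + w_desc + 9L)
  expect_error(assemble_features(smiles, character(), hm$recipe),
               "no feature blocks")
})

test_that("real animal values overwrite predictions cell-wise", {
  am <- fx_animal_models()
  animal <- fx_data()$animal
  # one compound in the animal dataset, one certainly absent
  in_smiles <- animal$std_smiles[which(!is.na(animal$VDss_rat))[1]]
  out_smiles <- "CCO"
  x <- assemble_features(c(in_smiles, out_smiles), "animal_real_or_pred",
                         am$recipe, am, real_animal = animal)
  pred_only <- predict_animal_features(c(in_smiles, out_smiles), am)
  # absent compound: row equals its predicted 9-vector
  expect_equal(unname(x[2, ]), unname(pred_only[2, ]), tolerance = 1e-12)
  # present compound: measured cells replaced
  expect_identical(x[1, "VDss_rat_pred"],
                   animal$VDss_rat[animal$std_smiles == in_smiles])
  # cells missing in the animal table keep the prediction
  missing_eps <- names(which(is.na(
    unlist(animal[animal$std_smiles == in_smiles,
                  sub("_pred$", "", colnames(pred_only))]))))
  for (e in missing_eps) {
    expect_identical(x[1, paste0(e, "_pred")], pred_only[1, paste0(e, "_pred")])
  }
})

test_that("fold assignments are identical across combinations (paired)", {
  hm <- fx_human_models()
  for (e in names(hm$cv)) {
    ref <- hm$cv[[e]][[1]]$predictions[, c("repeat_", "fold", "row")]
    for (cid in names(hm$cv[[e]])[-1]) {
      expect_identical(
        hm$cv[[e]][[cid]]$predictions[, c("repeat_", "fold", "row")], ref)
    }
  }
})

test_that("richer feature spaces beat fingerprints alone on synthetic data", {
  hm <- fx_human_models()
  summ <- tidy(hm)
  for (e in unique(summ$endpoint)) {
    r2_1 <- summ$median_r2[summ$endpoint == e & summ$combo_id == 1]
    r2_7 <- summ$median_r2[summ$endpoint == e & summ$combo_id == 7]
    r2_base <- summ$median_r2[summ$endpoint == e & summ$combo_id == 10]
    expect_gt(r2_7, r2_base)
    expect_lte(r2_base, 0.05)
    # descriptor-linear signal: the full feature set should win
    expect_gt(r2_7, r2_1 - 0.05)
  }
})

test_that("predictions are returned in natural units with AD annotation", {
  hm <- fx_human_models()
  smiles <- c(fx_data()$human$std_smiles[1:3], "definitely)(bad")
  suppressWarnings(preds <- predict_human(smiles, hm))
  expect_s3_class(preds, "tbl_df")
  expect_identical(nrow(preds), 4L * length(hm$endpoints))
  ok <- preds[is.na(preds$error), ]
  expect_true(all(ok$prediction > 0))
  expect_true(all(ok$prediction[ok$endpoint == "fu"] <= 1))
  expect_true(all(ok$range_low <= ok$prediction + 1e-9))
  expect_true(all(ok$range_high >= ok$prediction - 1e-9))
  expect_true(all(ok$fold_error >= 1))
  expect_identical(ok$ad_alert, ok$similarity_5nn < 0.25)
  # failed row is reported, not dropped
  bad <- preds[preds$input == "definitely)(bad", ]
  expect_true(all(bad$error == "unparsable SMILES"))
  expect_true(all(is.na(bad$prediction)))
  # training compounds score high similarity, no alert
  expect_true(all(!ok$ad_alert[ok$similarity_5nn > 0.5]))
})

test_that("prediction is deterministic across calls", {
  hm <- fx_human_models()
  smiles <- fx_data()$human$std_smiles[5:8]
  p1 <- predict_human(smiles, hm)
  p2 <- predict_human(smiles, hm)
  expect_identical(p1, p2)
})
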