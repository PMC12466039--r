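toy_records <- function(cl = c(2, 4, NA), fu = c(NA, 0.4, NA),
                        smiles = rep("CCO", 3)) {
  tibble::tibble(std_smiles = smiles, mol_weight = 46.04,
                 CL = cl, fu = fu)
}

test_that("duplicate merging takes the endpoint-wise median", {
  merged <- merge_duplicates(toy_records(cl = c(2, 4, NA)), c("CL", "fu"))
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$CL, 3)            # median of two = mean
  expect_identical(merged$fu, 0.4)          # single present value wins
  merged3 <- merge_duplicates(toy_records(cl = c(1, 10, 100)), c("CL", "fu"))
  expect_identical(merged3$CL, 10)
  # endpoints missing everywhere stay missing
  none <- merge_duplicates(toy_records(cl = c(NA, NA, NA)), c("CL", "fu"))
  expect_true(is.na(none$CL))
  # output count equals distinct std_smiles
  mixed <- merge_duplicates(
    toy_records(smiles = c("CCO", "CCO", "CCN")), c("CL", "fu"))
  expect_identical(nrow(mixed), 2L)
})

test_that("molecular-weight filter removes only the heavy upper tail", {
  d <- tibble::tibble(std_smiles = paste0("m", 1:20),
                      mol_weight = c(rep(300, 18), 900, 1500))
  out <- mw_filter(d, k = 1.5)
  thr <- mean(d$mol_weight) + 1.5 * sd(d$mol_weight)
  expect_identical(attr(out, "mw_threshold"), thr)
  expect_setequal(setdiff(d$std_smiles, out$std_smiles),
                  d$std_smiles[d$mol_weight > thr])
  # identical weights: sd 0, nothing removed
  same <- tibble::tibble(std_smiles = paste0("m", 1:10), mol_weight = 250)
  expect_identical(nrow(mw_filter(same)), 10L)
  # huge k removes nothing
  expect_identical(nrow(mw_filter(d, k = 1e6)), 20L)
  expect_error(mw_filter(d[1, ]), "at least 2")
})

test_that("log transform hits all endpoints except fu and round-trips", {
  d <- pk_dataset(
    tibble::tibble(std_smiles = c("a", "b", "c"), mol_weight = 100,
                   VDss = c(1, 10, 0.5), CL = c(100, 10, 1),
                   fu = c(0.5, 0.1, 1)),
    species = "human", endpoints = c("VDss", "CL", "fu"))
  lt <- log_transform_endpoints(d)
  expect_identical(lt$CL, c(2, 1, 0))
  expect_identical(lt$VDss[[1]], 0)
  expect_identical(lt$fu, d$fu)
  expect_setequal(attr(lt, "log_transformed"), c("VDss", "CL"))
  expect_equal(back_transform(lt$CL, "CL"), d$CL, tolerance = 1e-12)
  expect_identical(back_transform(lt$fu, "fu"), d$fu)

  bad <- d
  bad$CL[[2]] <- -1
  expect_error(log_transform_endpoints(bad), "non-positive.*CL")
})

test_that("overlap removal keeps exactly the unseen compounds", {
  train <- pk_dataset(tibble::tibble(std_smiles = c("a", "b", "c"),
                                     mol_weight = 1, CL = 1),
                      "human", "CL")
  test_sub <- pk_dataset(tibble::tibble(std_smiles = c("a", "b"),
                                        mol_weight = 1, CL = 1),
                         "external", "CL")
  expect_identical(nrow(remove_overlap(test_sub, train)), 0L)
  test_dis <- pk_dataset(tibble::tibble(std_smiles = c("x", "y"),
                                        mol_weight = 1, CL = 1),
                         "external", "CL")
  expect_identical(remove_overlap(test_dis, train)$std_smiles, c("x", "y"))
})

test_that("full curation standardizes, merges salts, filters and reports", {
  raw <- tibble::tibble(
    smiles = c("CCO", "OCC", "CCO.Cl", "CC(=O)O", "CCN", "c1ccccc1O",
               "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CN1CCC[C@H]1c1cccnc1",
               "bad_smiles", "NCCc1ccc(O)c(O)c1"),
    VDss = c(1, 3, 2, 0.5, 1, 2, 0.2, 3, 1, 1.5),
    CL = c(10, 20, 30, 5, -2, 8, 7, 12, 1, 9),
    fu = c(0.5, 0.7, 0.9, 0.2, 0.3, 1.2, 0.1, 0, 0.5, 0.6))
  expect_warning(ds <- curate_pk_data(raw, species = "human"),
                 "standardization failed")
  rep <- curation_report(ds)
  expect_identical(rep$n_unparsable, 1L)
  # CCO, OCC and CCO.Cl collapse to one ethanol record
  expect_false(anyDuplicated(ds$std_smiles) > 0)
  eth <- ds[ds$std_smiles == "CCO", ]
  expect_identical(nrow(eth), 1L)
  expect_identical(10^eth$VDss, 2)       # median of 1, 3, 2
  # invalid values became missing: CL -2, fu 1.2, fu 0
  expect_gte(rep$n_invalid_values, 3)
  # sparsity matches its definition
  cells <- as.matrix(ds[, attr(ds, "endpoints")])
  expect_equal(dataset_sparsity(ds), mean(is.na(cells)), tolerance = 1e-12)
  expect_equal(rep$sparsity, dataset_sparsity(ds), tolerance = 1e-12)
  expect_true(all(ds$fu > 0 & ds$fu <= 1, na.rm = TRUE))
})
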