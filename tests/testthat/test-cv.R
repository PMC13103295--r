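test_that("evaluate_predictions reproduces hand-computed r and RMSE", {
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$rmse, 0)
  expect_lt(perfect$p_param, 1e-6)
  off <- evaluate_predictions(c(11, 12, 13), c(1, 2, 3))
  expect_equal(off$r, 1)
  expect_equal(off$rmse, 10)
  rev <- evaluate_predictions(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev$r, -1)
  expect_equal(rev$rmse, sqrt(8 / 3))
  # constant predictions: undefined correlation maps to the r = 0 convention
  flat <- evaluate_predictions(c(2, 2, 2, 2), c(1, 2, 3, 4))
  expect_equal(flat$r, 0)
  expect_equal(flat$p_param, 1)
  expect_error(evaluate_predictions(c(1, 2), c(1, 2)), "at least 3")
  expect_error(evaluate_predictions(1:4, rep(1, 4)), "constant")
})

test_that("noiseless recoverable signal gives LOOCV r = 1", {
  sim <- make_sim(seed = 61, n_subjects = 30, n_nodes = 8,
                  n_pos_edges = 0, n_neg_edges = 0, effect_r = 0)
  ds <- sim$dataset
  ds$behavior <- 4 * ds$edge_matrix[, 5] + 50   # exact linear in one edge
  cv <- run_cv(ds, threshold_p = 0.01, covariate_mode = "none")
  expect_gt(cv$metrics$positive$r, 1 - 1e-6)
  expect_lt(cv$metrics$positive$rmse, 1e-6)
})

test_that("LOOCV matches the naive fold-by-fold oracle exactly", {
  sim <- make_sim(seed = 62, n_subjects = 30, n_nodes = 15,
                  n_pos_edges = 10, n_neg_edges = 10, effect_r = 0.4)
  ds <- sim$dataset
  cv <- run_cv(ds, threshold_p = 0.01, covariate_mode = "none",
               keep_fold_masks = TRUE)
  ref <- oracle_loocv(ds$edge_matrix, ds$behavior, threshold = 0.01)
  for (f in seq_along(cv$folds)) {
    expect_identical(cv$fold_masks[[f]]$positive, ref$masks[[f]]$positive)
    expect_identical(cv$fold_masks[[f]]$negative, ref$masks[[f]]$negative)
  }
  expect_lt(max(abs(cv$predictions - ref$predictions)), 1e-10)
})

test_that("covariate-adjusted LOOCV matches the naive partial-correlation oracle", {
  sim <- make_sim(seed = 63, n_subjects = 30, n_nodes = 10,
                  n_pos_edges = 6, n_neg_edges = 6, effect_r = 0.5)
  ds <- sim$dataset
  cv <- run_cv(ds, threshold_p = 0.05, covariate_mode = "partial",
               keep_fold_masks = TRUE)
  ref <- oracle_loocv(ds$edge_matrix, ds$behavior, X = ds$covariates,
                      threshold = 0.05)
  for (f in seq_along(cv$folds)) {
    expect_identical(cv$fold_masks[[f]]$positive, ref$masks[[f]]$positive)
    expect_identical(cv$fold_masks[[f]]$negative, ref$masks[[f]]$negative)
  }
  expect_lt(max(abs(cv$predictions - ref$predictions)), 1e-10)
})

test_that("k-fold with k = n reproduces LOOCV predictions", {
  sim <- make_sim(seed = 64, n_subjects = 25, n_nodes = 10)
  loo <- run_cv(sim$dataset, covariate_mode = "none")
  kn <- run_cv(sim$dataset, scheme = "kfold",
               k = length(sim$dataset$behavior), covariate_mode = "none",
               seed = 99)
  expect_equal(kn$predictions, loo$predictions, tolerance = 1e-12)
})

test_that("no information leaks: fold masks equal full reselection on training subjects", {
  sim <- make_sim(seed = 65, n_subjects = 40, n_nodes = 10)
  ds <- sim$dataset
  cv <- run_cv(ds, threshold_p = 0.05, covariate_mode = "partial",
               keep_fold_masks = TRUE)
  for (f in c(1, 17, 40)) {
    tr <- setdiff(seq_along(ds$behavior), cv$folds[[f]])
    m <- select_edges(subset_dataset(ds, tr), 0.05, "partial")
    expect_identical(which(m$positive), cv$fold_masks[[f]]$positive)
    expect_identical(which(m$negative), cv$fold_masks[[f]]$negative)
  }
})

test_that("run_cv is deterministic and empty-mask folds fall back to the training mean", {
  sim <- make_sim(seed = 66, n_subjects = 40, n_nodes = 10, effect_r = 0)
  cv1 <- run_cv(sim$dataset, covariate_mode = "none", threshold_p = 1e-4)
  cv2 <- run_cv(sim$dataset, covariate_mode = "none", threshold_p = 1e-4)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_gt(cv1$empty_mask_folds, 0)
  # every subject predicted exactly once, predictions finite
  expect_false(anyNA(cv1$predictions))
  # a fold with empty masks predicts that fold's training mean
  f <- which(rowSums(cv1$mask_sizes) == 0)[1]
  if (!is.na(f)) {
    te <- cv1$folds[[f]]
    expect_equal(unname(cv1$predictions[te, "combined"]),
                 mean(sim$dataset$behavior[-te]), tolerance = 1e-12)
  }
})

test_that("permutation p-values follow the add-one counting rule", {
  sim <- make_sim(seed = 67, n_subjects = 40, n_nodes = 8,
                  n_pos_edges = 6, n_neg_edges = 6, effect_r = 0.6)
  p <- permutation_test(sim$dataset, covariate_mode = "none",
                        n_perm = 100, seed = 5)
  for (mod in c("positive", "negative", "combined")) {
    expect_equal(p$p_perm[[mod]],
                 (1 + sum(p$null_r[, mod] >= p$observed_r[[mod]])) / 101)
    expect_gt(p$p_perm[[mod]], 0)
    expect_lte(p$p_perm[[mod]], 1)
  }
  # strong planted signal beats every permutation
  expect_equal(p$p_perm[["positive"]], 1 / 101)
  expect_equal(nrow(p$null_r), 100)
  # reproducible given the seed
  p2 <- permutation_test(sim$dataset, covariate_mode = "none",
                         n_perm = 100, seed = 5)
  expect_identical(p$null_r, p2$null_r)
  expect_error(permutation_test(sim$dataset, n_perm = 50), "at least 100")
})
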