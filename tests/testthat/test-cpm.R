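test_that("edge_behavior_stats matches cor.test and the lm-residual partial oracle", {
  sim <- make_sim(seed = 51, n_subjects = 40, n_nodes = 8)
  E <- sim$dataset$edge_matrix
  y <- sim$dataset$behavior
  X <- sim$dataset$covariates
  st <- edge_behavior_stats(E, y)
  stp <- edge_behavior_stats(E, y, X)
  for (j in seq_len(ncol(E))) {
    ref <- oracle_edge_assoc(E[, j], y)
    expect_equal(st$r[j], ref$r, tolerance = 1e-12)
    expect_equal(st$p[j], ref$p, tolerance = 1e-12)
    refp <- oracle_edge_assoc(E[, j], y, X)
    expect_equal(stp$r[j], refp$r, tolerance = 1e-10)
    expect_equal(stp$p[j], refp$p, tolerance = 1e-10)
  }
  expect_equal(unique(st$df), 38)
  expect_equal(unique(stp$df), 35)
})

test_that("selection routes tails by sign, stays disjoint, flags perfect correlation", {
  sim <- make_sim(seed = 52, n_subjects = 60, n_nodes = 10)
  ds <- sim$dataset
  # an edge identically equal to behavior is always selected, positively
  ds$edge_matrix[, 7] <- ds$behavior
  masks <- suppressWarnings(select_edges(ds, threshold_p = 1e-6,
                                         covariate_mode = "none"))
  expect_true(masks$positive[7])
  expect_false(any(masks$positive & masks$negative))
  # zero-variance edge is excluded with a warning, never selected
  ds$edge_matrix[, 3] <- 1.7
  expect_warning(m2 <- select_edges(ds, 0.05, "none"), "zero-variance")
  expect_false(m2$positive[3] || m2$negative[3])
})

test_that("selection is invariant to subject order and affine behavior rescaling", {
  sim <- make_sim(seed = 53, n_subjects = 80, n_nodes = 12)
  ds <- sim$dataset
  m1 <- select_edges(ds, 0.05, "none")
  perm <- sample(seq_along(ds$behavior))
  m2 <- select_edges(subset_dataset(ds, perm), 0.05, "none")
  expect_identical(m1$positive, m2$positive)
  expect_identical(m1$negative, m2$negative)
  ds3 <- ds
  ds3$behavior <- 3.2 * ds$behavior + 17
  m3 <- select_edges(ds3, 0.05, "none")
  expect_identical(m1$positive, m3$positive)
  expect_identical(m1$negative, m3$negative)
})

test_that("covariate adjustment rejects confound-only edges that marginal selection accepts", {
  sim <- make_sim(seed = 54, n_subjects = 2000, n_nodes = 12,
                  n_pos_edges = 3, n_neg_edges = 3, effect_r = 0.3,
                  confound_strength = 0.6, n_confound_edges = 5)
  ds <- sim$dataset
  conf <- which(sim$truth$confound_mask)
  m_none <- select_edges(ds, 0.01, "none")
  m_part <- select_edges(ds, 0.01, "partial")
  sel_none <- m_none$positive | m_none$negative
  sel_part <- m_part$positive | m_part$negative
  expect_true(all(sel_none[conf]))
  expect_false(any(sel_part[conf]))
  pos <- which(sim$truth$true_positive_mask)
  expect_true(all(sel_part[pos]))
})

test_that("network_strength implements sum/mean with the empty-sum convention", {
  E <- rbind(c(0.2, 0.3, 9), c(1, 2, 9))
  mask <- c(TRUE, TRUE, FALSE)
  expect_equal(network_strength(E, mask, "sum"), c(0.5, 3))
  expect_equal(network_strength(E, mask, "mean"), c(0.25, 1.5))
  empty <- rep(FALSE, 3)
  expect_equal(network_strength(E, empty, "sum"), c(0, 0))
  expect_error(network_strength(E, empty, "mean"), "empty")
  expect_error(network_strength(E, c(TRUE, TRUE), "sum"), "mask length")
})

test_that("fit_cpm recovers exact linear structure and handles degenerate tails", {
  sim <- make_sim(seed = 55, n_subjects = 50, n_nodes = 10,
                  n_pos_edges = 4, n_neg_edges = 0, effect_r = 0)
  ds <- sim$dataset
  pos <- sim$truth$true_positive_mask
  s <- network_strength(ds$edge_matrix, pos, "sum")
  ds$behavior <- 2 * s + 5
  masks <- edge_mask_pair(pos, rep(FALSE, length(pos)))
  model <- suppressWarnings(fit_cpm(ds, masks))
  expect_equal(unname(model$coefficients$positive), c(5, 2),
               tolerance = 1e-8)
  # negative tail is empty: intercept-only, flagged; combined reduces to
  # the positive-only fit
  expect_true(model$degenerate[["negative"]])
  expect_equal(unname(model$coefficients$combined),
               c(model$coefficients$positive, 0), tolerance = 1e-12)
  expect_equal(predict(model, ds, which = "positive"), ds$behavior,
               tolerance = 1e-8)
  # prediction is equivariant under subject permutation
  perm <- c(5, 1, 50, 17, 3)
  expect_equal(predict(model, ds$edge_matrix[perm, ], which = "combined"),
               predict(model, ds, which = "combined")[perm])
})

test_that("a null strength-behavior relation yields a slope within 3 SE of zero", {
  sim <- make_sim(seed = 56, n_subjects = 10000, n_nodes = 10,
                  n_pos_edges = 5, n_neg_edges = 5, effect_r = 0)
  ds <- sim$dataset
  masks <- edge_mask_pair(sim$truth$true_positive_mask,
                          sim$truth$true_negative_mask)
  model <- fit_cpm(ds, masks)
  s <- network_strength(ds$edge_matrix, masks$positive)
  se <- summary(lm(ds$behavior ~ s))$coefficients[2, 2]
  expect_lt(abs(model$coefficients$positive[2]), 3 * se)
})

test_that("collinear tails fall back to the positive-only combined model", {
  sim <- make_sim(seed = 57, n_subjects = 40, n_nodes = 10,
                  n_pos_edges = 2, n_neg_edges = 0, effect_r = 0.5)
  ds <- sim$dataset
  # make the "negative" strength an exact affine copy of the positive one
  pos <- which(sim$truth$true_positive_mask)
  nul <- setdiff(seq_len(ncol(ds$edge_matrix)), pos)[1:2]
  ds$edge_matrix[, nul] <- ds$edge_matrix[, pos]
  masks <- edge_mask_pair(seq_along(sim$truth$true_positive_mask) %in% pos,
                          seq_along(sim$truth$true_positive_mask) %in% nul)
  expect_warning(model <- fit_cpm(ds, masks), "collinear")
  expect_equal(unname(model$coefficients$combined[3]), 0)
  expect_equal(unname(model$coefficients$combined[1:2]),
               unname(model$coefficients$positive))
})

test_that("masks and models survive JSON round trips byte-stably", {
  sim <- make_sim(seed = 58, n_subjects = 60, n_nodes = 12)
  masks <- select_edges(sim$dataset, 0.05, "none")
  model <- fit_cpm(sim$dataset, masks)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "m1.json"); p2 <- file.path(d, "m2.json")
  write_masks(masks, p1); write_masks(masks, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_masks(p1)
  expect_identical(back$positive, masks$positive)
  expect_identical(back$negative, masks$negative)
  expect_equal(back$threshold_p, masks$threshold_p)

  q1 <- file.path(d, "mod1.json"); q2 <- file.path(d, "mod2.json")
  write_model(model, q1); write_model(model, q2)
  expect_identical(readBin(q1, "raw", file.size(q1)),
                   readBin(q2, "raw", file.size(q2)))
  mback <- read_model(q1)
  expect_equal(predict(mback, sim$dataset),
               predict(model, sim$dataset), tolerance = 1e-12)
})

test_that("aggregate choice (sum vs mean) leaves refit predictions unchanged", {
  sim <- make_sim(seed = 59, n_subjects = 80, n_nodes = 12)
  masks <- select_edges(sim$dataset, 0.01, "none")
  m_sum <- fit_cpm(sim$dataset, masks, aggregate = "sum")
  m_mean <- fit_cpm(sim$dataset, masks, aggregate = "mean")
  expect_equal(predict(m_sum, sim$dataset), predict(m_mean, sim$dataset),
               tolerance = 1e-8)
})
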