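test_that("generator is fully reproducible and behavior stays in bounds", {
  a <- make_sim(seed = 123)
  b <- make_sim(seed = 123)
  expect_identical(a$dataset$edge_matrix, b$dataset$edge_matrix)
  expect_identical(a$dataset$behavior, b$dataset$behavior)
  expect_identical(a$truth, b$truth)
  c <- make_sim(seed = 124)
  expect_false(identical(a$dataset$edge_matrix, c$dataset$edge_matrix))
  expect_true(all(a$dataset$behavior >= 20 & a$dataset$behavior <= 100))
})

test_that("behavior moments match the truncated-normal target", {
  sim <- make_sim(seed = 11, n_subjects = 10000, n_nodes = 8,
                  n_pos_edges = 0, n_neg_edges = 0, effect_r = 0)
  b <- sim$dataset$behavior
  # analytic moments of Normal(60.34, 16.31) truncated to [20, 100]
  mu <- 60.34; s <- 16.31
  z1 <- (20 - mu) / s; z2 <- (100 - mu) / s
  Z <- pnorm(z2) - pnorm(z1)
  tmean <- mu + s * (dnorm(z1) - dnorm(z2)) / Z
  tvar <- s^2 * (1 + (z1 * dnorm(z1) - z2 * dnorm(z2)) / Z -
                   ((dnorm(z1) - dnorm(z2)) / Z)^2)
  expect_lt(abs(mean(b) - tmean) / tmean, 0.02)
  expect_lt(abs(sd(b) - sqrt(tvar)) / sqrt(tvar), 0.02)
})

test_that("planted-edge correlation converges to effect_r; null edges stay null", {
  sim <- make_sim(seed = 21, n_subjects = 5000, n_nodes = 12,
                  n_pos_edges = 5, n_neg_edges = 5, effect_r = 0.4)
  E <- sim$dataset$edge_matrix
  y <- sim$dataset$behavior
  r <- as.numeric(cor(E, y))
  pos <- which(sim$truth$true_positive_mask)
  neg <- which(sim$truth$true_negative_mask)
  expect_true(all(abs(r[pos] - 0.4) < 0.05))
  expect_true(all(abs(r[neg] + 0.4) < 0.05))
  nul <- setdiff(seq_along(r), c(pos, neg))
  expect_true(all(abs(r[nul]) < 3 / sqrt(5000) * 1.5))

  # effect_r = 0: planted and null edges indistinguishable (the 0.1 bound
  # is > 4 sampling SDs at this n)
  sim0 <- make_sim(seed = 22, n_subjects = 2000, n_nodes = 12, effect_r = 0)
  r0 <- as.numeric(cor(sim0$dataset$edge_matrix, sim0$dataset$behavior))
  expect_true(all(abs(r0) < 0.1))

  # near-deterministic coupling
  sim99 <- make_sim(seed = 23, n_subjects = 500, n_nodes = 10,
                    n_pos_edges = 3, n_neg_edges = 0, effect_r = 0.99)
  r99 <- as.numeric(cor(sim99$dataset$edge_matrix, sim99$dataset$behavior))
  expect_true(all(r99[sim99$truth$true_positive_mask] > 0.9))
})

test_that("confound-only edges correlate marginally but not partially", {
  sim <- make_sim(seed = 31, n_subjects = 5000, n_nodes = 12,
                  n_pos_edges = 3, n_neg_edges = 3, effect_r = 0.3,
                  confound_strength = 0.6, n_confound_edges = 5)
  ds <- sim$dataset
  conf <- which(sim$truth$confound_mask)
  marg <- edge_behavior_stats(ds$edge_matrix, ds$behavior)
  part <- edge_behavior_stats(ds$edge_matrix, ds$behavior, ds$covariates)
  expect_true(all(abs(marg$r[conf]) > 0.1))        # spurious marginal signal
  expect_true(all(abs(part$r[conf]) < 0.05))       # vanishes under partial
  # genuinely planted edges survive adjustment
  pos <- which(sim$truth$true_positive_mask)
  expect_true(all(part$r[pos] > 0.15))
})

test_that("generate_atlas distributes nodes over the ten networks", {
  eq <- setNames(rep(0.1, 10), canonical_networks())
  a10 <- generate_atlas(10, eq)
  expect_equal(as.vector(table(factor(a10$network,
                                      canonical_networks()))), rep(1, 10))
  conc <- setNames(c(rep(0, 8), 1, 0), canonical_networks())
  expect_true(all(generate_atlas(25, conc)$network == "SC"))
  a268 <- generate_atlas(268)
  expect_equal(nrow(a268), 268)
  counts <- table(factor(a268$network, canonical_networks()))
  expect_equal(sum(counts), 268)
  expect_true(all(counts >= 1))
  # seeded permutation is reproducible
  expect_identical(generate_atlas(30, seed = 4), generate_atlas(30, seed = 4))
})

test_that("split_dataset partitions subjects per the floor-then-remainder rule", {
  sim <- make_sim(seed = 41, n_subjects = 656, n_nodes = 8,
                  n_pos_edges = 0, n_neg_edges = 0, effect_r = 0)
  parts <- split_dataset(sim$dataset, c(0.89, 0.11), seed = 1)
  expect_equal(length(parts$discovery$behavior), 584)
  expect_equal(length(parts$external$behavior), 72)
  expect_setequal(c(parts$discovery$subject_ids, parts$external$subject_ids),
                  sim$dataset$subject_ids)
  expect_length(intersect(parts$discovery$subject_ids,
                          parts$external$subject_ids), 0)
  again <- split_dataset(sim$dataset, c(0.89, 0.11), seed = 1)
  expect_identical(again$discovery$subject_ids, parts$discovery$subject_ids)
})
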