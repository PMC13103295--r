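#' Configuration for the synthetic connectome generator
#'
#' Bundles and validates the parameters that define a simulated study: cohort
#' size, atlas size, how many edges are truly coupled to behavior in each
#' tail, the strength of that coupling, the behavioral score distribution
#' (an IAT-like severity scale bounded to [20, 100], defaulting to the
#' discovery-cohort moments mean 60.34 / SD 16.31), edge noise on the
#' Fisher-z scale, and optional covariate confounding.
#'
#' With \code{confound_strength > 0} a latent confound score (a linear
#' combination of age, sex and mean framewise displacement) is coupled both
#' to the behavior score and to a disjoint set of "confound-only" edges,
#' creating spurious marginal edge-behavior correlations that vanish under
#' partial correlation given the covariates.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of atlas nodes (default 60; 268 supported).
#' @param n_pos_edges,n_neg_edges Planted edges per tail.
#' @param effect_r Target population correlation between each planted edge
#'   and behavior, in (0, 1); use 0 for a pure-null dataset.
#' @param behavior_mean,behavior_sd,behavior_bounds Behavior distribution:
#'   Normal(mean, sd) truncated to bounds by rejection sampling.
#' @param edge_baseline_sd Edge noise SD in Fisher-z units.
#' @param confound_strength Covariate-confounding coupling (0 = none).
#' @param n_confound_edges Confound-only edges (disjoint from planted sets).
#' @param seed Mandatory RNG seed; the generator is fully reproducible.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_subjects, n_nodes = 60, n_pos_edges = 20,
                             n_neg_edges = 20, effect_r = 0.4,
                             behavior_mean = 60.34, behavior_sd = 16.31,
                             behavior_bounds = c(20, 100),
                             edge_baseline_sd = 0.3,
                             confound_strength = 0, n_confound_edges = 20,
                             seed) {
  if (missing(seed)) .stopf("a seed is mandatory for reproducibility")
  if (effect_r < 0 || effect_r >= 1)
    .stopf("effect_r must be in [0, 1), got %g", effect_r)
  n_e <- .n_edges(n_nodes)
  n_special <- n_pos_edges + n_neg_edges +
    if (confound_strength > 0) n_confound_edges else 0
  if (n_special > n_e)
    .stopf("%d planted/confound edges exceed the %d available edges",
           n_special, n_e)
  if (n_subjects < 10) .stopf("need at least 10 subjects")
  if (edge_baseline_sd <= 0) .stopf("edge_baseline_sd must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 n_pos_edges = as.integer(n_pos_edges),
                 n_neg_edges = as.integer(n_neg_edges),
                 effect_r = effect_r, behavior_mean = behavior_mean,
                 behavior_sd = behavior_sd,
                 behavior_bounds = behavior_bounds,
                 edge_baseline_sd = edge_baseline_sd,
                 confound_strength = confound_strength,
                 n_confound_edges = as.integer(n_confound_edges),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# truncated-normal sampling by rejection; bounds are wide (> 2 SD) so the
# acceptance rate is high and vectorized resampling converges in a few rounds
.rtruncnorm <- function(n, mean, sd, bounds) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < bounds[1] | x > bounds[2])
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < bounds[1] | x[bad] > bounds[2]]
  }
  x
}

#' Generate a synthetic atlas
#'
#' Assigns each node to one of the ten canonical networks. Target counts are
#' proportions times \code{n_nodes}, rounded down, with leftover nodes
#' assigned by largest fractional remainder; every network with a positive
#' proportion receives at least one node. Labels are laid out in canonical
#' network order, optionally permuted across nodes.
#'
#' @param n_nodes Number of nodes.
#' @param proportions Named numeric over the ten canonical networks, summing
#'   to 1; defaults to whole-brain-atlas-like proportions.
#' @param seed If non-NULL, permute the node-to-network assignment
#'   reproducibly; NULL keeps contiguous blocks.
#' @return Atlas data frame with columns \code{node_id}, \code{network}.
#' @export
generate_atlas <- function(n_nodes, proportions = NULL, seed = NULL) {
  nets <- canonical_networks()
  if (is.null(proportions)) proportions <- .default_network_proportions()
  proportions <- proportions[nets]
  if (anyNA(proportions))
    .stopf("proportions must be named over: %s", paste(nets, collapse = ", "))
  if (abs(sum(proportions) - 1) > 1e-9)
    .stopf("proportions must sum to 1 (got %g)", sum(proportions))
  target <- proportions * n_nodes
  counts <- floor(target)
  frac <- target - counts
  # settle the remainder by largest fractional part (deterministic order)
  rem <- n_nodes - sum(counts)
  for (i in order(-frac, seq_along(frac))) {
    if (rem == 0) break
    counts[i] <- counts[i] + 1
    rem <- rem - 1
  }
  # guarantee one node per positive-proportion network where feasible,
  # borrowing from the largest allocations
  need <- which(proportions > 0 & counts == 0)
  for (i in need[order(-proportions[need])]) {
    donor <- which.max(counts)
    if (counts[donor] > 1) {
      counts[donor] <- counts[donor] - 1
      counts[i] <- 1L
    }
  }
  labels <- rep(nets, times = counts)
  if (!is.null(seed)) labels <- .with_seed(seed, sample(labels))
  data.frame(node_id = seq_len(n_nodes), network = labels)
}

#' Generate a synthetic connectome dataset with known ground truth
#'
#' Edges are generated directly on the Fisher-z scale: every edge has a
#' subject-independent baseline mean plus independent Gaussian noise; planted
#' positive edges additionally receive \code{beta * standardized(behavior)}
#' and planted negative edges \code{-beta}, with
#' \code{beta = sd * effect_r / sqrt(1 - effect_r^2)} so each planted edge's
#' population correlation with behavior equals \code{effect_r}. Covariates
#' (age, sex, motion summaries) are always generated; when
#' \code{confound_strength > 0} a latent confound couples them to behavior
#' and to a disjoint confound-only edge set.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return List with \code{dataset} (a \code{\link{connectome_dataset}}) and
#'   \code{truth} (positive/negative/confound masks and the generating
#'   coefficient).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_subjects
    n_e <- .n_edges(cfg$n_nodes)
    behavior <- .rtruncnorm(n, cfg$behavior_mean, cfg$behavior_sd,
                            cfg$behavior_bounds)
    age <- stats::rnorm(n, 22.3, 2.0)
    sex <- stats::rbinom(n, 1, 0.69)
    mean_fd <- pmin(abs(stats::rnorm(n, 0.08, 0.04)), 0.199)
    max_tr <- pmin(abs(stats::rnorm(n, 0.6, 0.5)), 2.49)
    max_ro <- pmin(abs(stats::rnorm(n, 0.5, 0.45)), 2.49)

    if (cfg$confound_strength > 0) {
      conf <- (scale(age)[, 1] + scale(sex)[, 1] + scale(mean_fd)[, 1]) /
        sqrt(3)
      behavior <- behavior + cfg$confound_strength * cfg$behavior_sd * conf
      behavior <- pmin(pmax(behavior, cfg$behavior_bounds[1]),
                       cfg$behavior_bounds[2])
    } else conf <- NULL

    slots <- sample.int(n_e, cfg$n_pos_edges + cfg$n_neg_edges +
                          if (cfg$confound_strength > 0)
                            cfg$n_confound_edges else 0L)
    pos_idx <- slots[seq_len(cfg$n_pos_edges)]
    neg_idx <- slots[cfg$n_pos_edges + seq_len(cfg$n_neg_edges)]
    conf_idx <- if (cfg$confound_strength > 0)
      slots[cfg$n_pos_edges + cfg$n_neg_edges +
              seq_len(cfg$n_confound_edges)] else integer(0)

    sigma <- cfg$edge_baseline_sd
    baseline <- stats::rnorm(n_e, 0.25, 0.10)
    emat <- matrix(stats::rnorm(n * n_e, 0, sigma), n, n_e)
    emat <- sweep(emat, 2, baseline, "+")
    beta <- sigma * cfg$effect_r / sqrt(1 - cfg$effect_r^2)
    b_std <- as.numeric(scale(behavior))
    if (cfg$n_pos_edges > 0 && beta != 0)
      emat[, pos_idx] <- emat[, pos_idx] + beta * b_std
    if (cfg$n_neg_edges > 0 && beta != 0)
      emat[, neg_idx] <- emat[, neg_idx] - beta * b_std
    if (length(conf_idx) > 0)
      emat[, conf_idx] <- emat[, conf_idx] +
        cfg$confound_strength * sigma * conf

    ids <- sprintf("sub%04d", seq_len(n))
    subjects <- data.frame(subject_id = ids, behavior = behavior, age = age,
                           sex = sex, max_translation_mm = max_tr,
                           max_rotation_deg = max_ro, mean_fd_mm = mean_fd)
    atlas <- generate_atlas(cfg$n_nodes)
    dataset <- connectome_dataset(
      emat, behavior, cfg$n_nodes,
      covariates = cbind(age = age, sex = sex, mean_fd_mm = mean_fd),
      atlas = atlas, subject_ids = ids, subjects = subjects)
    truth <- list(
      true_positive_mask = seq_len(n_e) %in% pos_idx,
      true_negative_mask = seq_len(n_e) %in% neg_idx,
      confound_mask = seq_len(n_e) %in% conf_idx,
      beta = beta, config = cfg)
    list(dataset = dataset, truth = truth)
  })
}

#' Split a dataset into discovery and external partitions
#'
#' Subjects are permuted reproducibly and divided according to
#' \code{fractions}: each part receives \code{floor(fraction * n)} subjects
#' and the remainder is assigned one subject at a time to the parts in order.
#' Partitions are disjoint and jointly exhaustive.
#'
#' @param dataset A \code{connectome_dataset}.
#' @param fractions Numeric vector summing to 1 (default discovery/external
#'   89/11, echoing a 586 + 70 design).
#' @param seed RNG seed for the permutation.
#' @return List of \code{connectome_dataset}, one per fraction (named
#'   \code{discovery}, \code{external} when there are two).
#' @export
split_dataset <- function(dataset, fractions = c(0.89, 0.11), seed) {
  if (abs(sum(fractions) - 1) > 1e-9)
    .stopf("fractions must sum to 1")
  n <- length(dataset$behavior)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  perm <- .with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  parts <- lapply(seq_along(sizes), function(g)
    subset_dataset(dataset, sort(perm[starts[g]:ends[g]])))
  names(parts) <- if (length(parts) == 2) c("discovery", "external")
  else sprintf("part%d", seq_along(parts))
  parts
}

#' Simulate node time series with latent network structure
#'
#' A light time-series-backed mode used for connectivity round-trip checks:
#' each node loads on a small number of shared latent signals plus
#' independent noise, producing realistic correlated time courses. Not a
#' hemodynamic model.
#'
#' @param n_timepoints,n_nodes Dimensions.
#' @param n_factors Number of shared latent signals.
#' @param noise_sd Node-specific noise SD.
#' @param seed RNG seed.
#' @return Numeric matrix, timepoints x nodes.
#' @export
simulate_timeseries <- function(n_timepoints = 200, n_nodes = 20,
                                n_factors = 3, noise_sd = 1, seed) {
  .with_seed(seed, {
    f <- matrix(stats::rnorm(n_timepoints * n_factors), n_timepoints)
    load <- matrix(stats::rnorm(n_factors * n_nodes, 0, 0.8), n_factors)
    f %*% load + matrix(stats::rnorm(n_timepoints * n_nodes, 0, noise_sd),
                        n_timepoints)
  })
}
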