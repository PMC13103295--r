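#' Score predictions against observed behavior
#'
#' The package's standard performance metrics: Pearson correlation between
#' predicted and observed scores with its parametric two-sided p-value, and
#' the root mean square error. If the predictions are constant (possible
#' when every fold's masks were empty) the correlation is undefined; the
#' convention r = 0, p = 1 is used so null-calibration runs stay well
#' defined.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 3);
#'   observed must have nonzero variance.
#' @return Named list: \code{r}, \code{p_param}, \code{rmse}.
#' @export
evaluate_predictions <- function(predicted, observed) {
  n <- length(observed)
  if (length(predicted) != n) .stopf("length mismatch")
  if (n < 3) .stopf("need at least 3 pairs")
  if (stats::sd(observed) == 0) .stopf("observed scores are constant")
  rmse <- sqrt(mean((predicted - observed)^2))
  if (stats::sd(predicted) == 0) {
    return(list(r = 0, p_param = 1, rmse = rmse))
  }
  r <- stats::cor(predicted, observed)
  df <- n - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p_param = 2 * stats::pt(-abs(tt), df), rmse = rmse)
}

# fold assignment: loocv = singleton folds in subject order; kfold = a
# seeded permutation cut into k nearly equal blocks
.make_folds <- function(n, scheme, k = NULL, seed = 1L) {
  if (scheme == "loocv") return(as.list(seq_len(n)))
  if (is.null(k) || k < 2 || k > n)
    .stopf("kfold needs 2 <= k <= n_subjects")
  perm <- .with_seed(seed, sample.int(n))
  # balanced contiguous blocks over the permuted order
  sizes <- rep(floor(n / k), k)
  sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1
  split(perm, rep(seq_len(k), times = sizes))
}

# The CV engine. Per fold: select edges on the training subjects only, fit
# the three strength models on the training subjects, predict the held-out
# subjects. Two selection backends:
#   * covariate_mode == "none": exact sufficient-statistic downdating of the
#     full-sample sums (after global centering for numerical stability), so
#     each fold costs O(n_edges) instead of O(n_subjects * n_edges); the
#     p < threshold rule is applied as |r| > r_crit with
#     r_crit = t_c / sqrt(df + t_c^2), t_c = qt(1 - p/2, df) — the same
#     decision boundary.
#   * covariate_mode == "partial": honest per-fold QR residualization.
.cv_engine <- function(E, y, X, folds, threshold_p, covariate_mode,
                       aggregate, keep_fold_masks = FALSE) {
  n <- nrow(E)
  pred <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("positive", "negative", "combined")))
  n_folds <- length(folds)
  mask_sizes <- matrix(0L, n_folds, 2,
                       dimnames = list(NULL, c("positive", "negative")))
  fold_masks <- if (keep_fold_masks) vector("list", n_folds) else NULL
  empty_events <- 0L
  fast <- identical(covariate_mode, "none")
  if (fast) {
    # global centering shrinks the magnitudes entering the downdated sums
    mu_e <- colMeans(E)
    mu_y <- mean(y)
    Ec <- sweep(E, 2, mu_e)
    yc <- y - mu_y
    Sx <- colSums(Ec); Sxx <- colSums(Ec * Ec); Sxy <- colSums(Ec * yc)
    Sy <- sum(yc); Syy <- sum(yc * yc)
    r_crit_cache <- rep(NA_real_, n)  # per training-set size
  }
  for (f in seq_len(n_folds)) {
    te <- folds[[f]]
    m <- n - length(te)
    if (fast) {
      if (length(te) == 1L) {
        ef <- Ec[te, ]; yf <- yc[te]
        sx <- Sx - ef; sxx <- Sxx - ef * ef; sxy <- Sxy - ef * yf
        sy <- Sy - yf; syy <- Syy - yf * yf
      } else {
        Ef <- Ec[te, , drop = FALSE]; yf <- yc[te]
        sx <- Sx - colSums(Ef); sxx <- Sxx - colSums(Ef * Ef)
        sxy <- Sxy - colSums(Ef * yf)
        sy <- Sy - sum(yf); syy <- Syy - sum(yf * yf)
      }
      vx <- pmax(sxx - sx * sx / m, 0)
      vy <- max(syy - sy * sy / m, 0)
      cxy <- sxy - sx * sy / m
      den <- sqrt(vx * vy)
      r <- cxy / den
      r[den == 0] <- 0
      if (is.na(r_crit_cache[m])) {
        df <- m - 2L
        t_c <- stats::qt(1 - threshold_p / 2, df)
        r_crit_cache[m] <- t_c / sqrt(df + t_c * t_c)
      }
      r_crit <- r_crit_cache[m]
      pos <- which(r > r_crit)
      neg <- which(r < -r_crit)
    } else {
      tr <- setdiff(seq_len(n), te)
      st <- edge_behavior_stats(E[tr, , drop = FALSE], y[tr],
                                X[tr, , drop = FALSE])
      ok <- !is.na(st$p) & st$p < threshold_p
      pos <- which(ok & st$r > 0)
      neg <- which(ok & st$r < 0)
    }
    s_pos <- .strength(E, pos, aggregate)
    s_neg <- .strength(E, neg, aggregate)
    tr <- if (fast) seq_len(n)[-te] else tr
    fit <- .fit_strengths(s_pos[tr], s_neg[tr], y[tr])
    if (length(pos) == 0 || length(neg) == 0) empty_events <- empty_events + 1L
    pred[te, ] <- .predict_strengths(fit, s_pos[te], s_neg[te])
    mask_sizes[f, ] <- c(length(pos), length(neg))
    if (keep_fold_masks) fold_masks[[f]] <- list(positive = pos, negative = neg)
  }
  list(predictions = pred, mask_sizes = mask_sizes, fold_masks = fold_masks,
       empty_mask_folds = empty_events)
}

#' Cross-validated CPM performance estimation
#'
#' Runs the full CPM protocol inside cross-validation: in every fold the
#' edge selection AND the model fitting use the training subjects only, and
#' the held-out subjects are predicted with that fold's model. Predictions
#' are aggregated over folds (each subject predicted exactly once) and
#' scored with \code{\link{evaluate_predictions}} for the positive-only,
#' negative-only and combined models.
#'
#' A fold whose positive (or negative) mask is empty predicts the
#' training-set behavior mean for that model rather than aborting; such
#' folds are counted in \code{empty_mask_folds}.
#'
#' @param dataset A \code{\link{connectome_dataset}}.
#' @param threshold_p Edge-selection threshold (default 0.01).
#' @param scheme \code{"loocv"} (default) or \code{"kfold"}.
#' @param k Number of folds when \code{scheme = "kfold"};
#'   \code{k = n_subjects} reproduces LOOCV.
#' @param covariate_mode \code{"partial"} (covariate-adjusted selection,
#'   default) or \code{"none"}.
#' @param aggregate Strength aggregation, \code{"sum"} or \code{"mean"}.
#' @param seed Seed for k-fold assignment (LOOCV needs none).
#' @param keep_fold_masks Keep per-fold selected-edge indices (for audit;
#'   off by default to save memory in permutation loops).
#' @return A \code{cpm_cv} object: per-subject predictions for the three
#'   models, metrics (r, parametric p, RMSE) per model, per-fold mask sizes,
#'   and the empty-mask fold count.
#' @export
run_cv <- function(dataset, threshold_p = 0.01,
                   scheme = c("loocv", "kfold"), k = NULL,
                   covariate_mode = c("partial", "none"),
                   aggregate = c("sum", "mean"), seed = 1L,
                   keep_fold_masks = FALSE) {
  scheme <- match.arg(scheme)
  covariate_mode <- match.arg(covariate_mode)
  aggregate <- match.arg(aggregate)
  n <- length(dataset$behavior)
  X <- dataset$covariates
  if (covariate_mode == "partial" && is.null(X))
    .stopf("covariate_mode = 'partial' but the dataset has no covariates")
  folds <- .make_folds(n, scheme, k, seed)
  eng <- .cv_engine(dataset$edge_matrix, dataset$behavior, X, folds,
                    threshold_p, covariate_mode, aggregate, keep_fold_masks)
  metrics <- lapply(c(positive = "positive", negative = "negative",
                      combined = "combined"), function(mod)
                        evaluate_predictions(eng$predictions[, mod],
                                             dataset$behavior))
  structure(list(scheme = scheme, k = k, threshold_p = threshold_p,
                 covariate_mode = covariate_mode, aggregate = aggregate,
                 subject_ids = dataset$subject_ids,
                 observed = dataset$behavior,
                 predictions = eng$predictions,
                 metrics = metrics,
                 mask_sizes = eng$mask_sizes,
                 empty_mask_folds = eng$empty_mask_folds,
                 folds = folds,
                 fold_masks = eng$fold_masks,
                 seed = seed),
            class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf("cpm_cv: %s over %d subjects (threshold p < %g, %s selection)\n",
              if (x$scheme == "loocv") "LOOCV"
              else sprintf("%d-fold CV", x$k),
              length(x$observed), x$threshold_p, x$covariate_mode))
  for (mod in names(x$metrics)) {
    m <- x$metrics[[mod]]
    cat(sprintf("  %-9s r = %6.3f  p = %.3g  RMSE = %.3f\n",
                mod, m$r, m$p_param, m$rmse))
  }
  if (x$empty_mask_folds > 0)
    cat(sprintf("  (%d fold(s) had an empty mask; mean-prediction fallback)\n",
                x$empty_mask_folds))
  invisible(x)
}

#' Write a cross-validation result to a directory
#'
#' Emits \code{cvresult.tsv} (subject_id, observed, pred_pos, pred_neg,
#' pred_combined) and \code{metrics.json} with the per-model metrics and the
#' run configuration.
#'
#' @param cv A \code{cpm_cv}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cv_result <- function(cv, dir) {
  stopifnot(inherits(cv, "cpm_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(subject_id = cv$subject_ids, observed = cv$observed,
               pred_pos = cv$predictions[, "positive"],
               pred_neg = cv$predictions[, "negative"],
               pred_combined = cv$predictions[, "combined"]),
    file.path(dir, "cvresult.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .write_manifest(file.path(dir, "metrics.json"),
                  list(metrics = cv$metrics, scheme = cv$scheme,
                       threshold_p = cv$threshold_p,
                       covariate_mode = cv$covariate_mode,
                       aggregate = cv$aggregate,
                       empty_mask_folds = cv$empty_mask_folds,
                       n_subjects = length(cv$observed)))
  invisible(dir)
}
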