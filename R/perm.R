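#' Permutation-test significance of cross-validated prediction
#'
#' Builds a null distribution of the predicted-vs-observed correlation by
#' permuting the behavioral scores and rerunning the ENTIRE cross-validation
#' procedure — edge selection inside every fold included — for each
#' permutation. Covariates stay attached to the imaging data (only the
#' behavior labels move). The one-sided p-value uses the add-one formula
#' \code{p = (1 + #\{null r >= observed r\}) / (1 + n_perm)}, which can
#' never return 0; one-sided because the alternative of interest is a
#' positive predictive correlation.
#'
#' @inheritParams run_cv
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Seed for the permutation stream (and k-fold assignment).
#' @return A \code{cpm_perm}: observed r per model, the n_perm x 3 null
#'   correlation matrix, and one-sided p-values per model.
#' @export
permutation_test <- function(dataset, threshold_p = 0.01,
                             scheme = c("loocv", "kfold"), k = NULL,
                             covariate_mode = c("partial", "none"),
                             aggregate = c("sum", "mean"),
                             n_perm = 1000, seed = 1L) {
  scheme <- match.arg(scheme)
  covariate_mode <- match.arg(covariate_mode)
  aggregate <- match.arg(aggregate)
  if (n_perm < 100) .stopf("n_perm must be at least 100")
  n <- length(dataset$behavior)
  X <- dataset$covariates
  if (covariate_mode == "partial" && is.null(X))
    .stopf("covariate_mode = 'partial' but the dataset has no covariates")
  folds <- .make_folds(n, scheme, k, seed)
  E <- dataset$edge_matrix
  y <- dataset$behavior
  score <- function(yy) {
    eng <- .cv_engine(E, yy, X, folds, threshold_p, covariate_mode,
                      aggregate, keep_fold_masks = FALSE)
    vapply(c("positive", "negative", "combined"), function(mod)
      evaluate_predictions(eng$predictions[, mod], yy)$r, numeric(1))
  }
  observed <- score(y)
  null_r <- .with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) score(y[sample.int(n)]),
             numeric(3)))
  })
  colnames(null_r) <- c("positive", "negative", "combined")
  p_perm <- vapply(colnames(null_r), function(mod)
    (1 + sum(null_r[, mod] >= observed[[mod]])) / (1 + n_perm), numeric(1))
  structure(list(observed_r = observed, null_r = null_r, p_perm = p_perm,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 threshold_p = threshold_p, scheme = scheme,
                 covariate_mode = covariate_mode),
            class = "cpm_perm")
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat(sprintf("cpm_perm: %d permutations of the full %s pipeline\n",
              x$n_perm, toupper(x$scheme)))
  for (mod in names(x$p_perm))
    cat(sprintf("  %-9s observed r = %6.3f  p_perm = %.4g\n",
                mod, x$observed_r[[mod]], x$p_perm[[mod]]))
  invisible(x)
}

#' Write a permutation result to a directory
#'
#' Emits \code{nullr.tsv} (one row per permutation, one column per model)
#' and \code{metrics.json} with observed r and permutation p per model.
#'
#' @param perm A \code{cpm_perm}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_perm_result <- function(perm, dir) {
  stopifnot(inherits(perm, "cpm_perm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(perm$null_r),
                     file.path(dir, "nullr.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(file.path(dir, "permutation_metrics.json"),
                  list(observed_r = as.list(perm$observed_r),
                       p_perm = as.list(perm$p_perm),
                       n_perm = perm$n_perm, seed = perm$seed,
                       threshold_p = perm$threshold_p,
                       scheme = perm$scheme,
                       covariate_mode = perm$covariate_mode))
  invisible(dir)
}
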