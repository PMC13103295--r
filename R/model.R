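#' Network-strength summary feature
#'
#' Collapses each subject's selected edges into a single scalar: the sum
#' (default) or mean of the masked Fisher-z edge values. This is the
#' regression predictor of the CPM model.
#'
#' @param edge_matrix Subjects x edges matrix.
#' @param mask Logical edge vector (or integer indices).
#' @param aggregate \code{"sum"} or \code{"mean"}. An empty mask yields 0
#'   under \code{"sum"} (the empty-sum convention) and is an error under
#'   \code{"mean"}.
#' @return Numeric vector, one strength per subject.
#' @export
network_strength <- function(edge_matrix, mask, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  E <- as.matrix(edge_matrix)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (is.logical(mask) && length(mask) != ncol(E))
    .stopf("mask length %d != %d edges", length(mask), ncol(E))
  if (length(idx) == 0) {
    if (aggregate == "mean") .stopf("mean of an empty mask is undefined")
    return(rep(0, nrow(E)))
  }
  s <- rowSums(E[, idx, drop = FALSE])
  if (aggregate == "mean") s <- s / length(idx)
  s
}

# strengths for the CV engine: empty masks silently yield zeros (the fold
# falls back to a degenerate intercept-only model rather than aborting)
.strength <- function(E, idx, aggregate) {
  if (length(idx) == 0) return(rep(0, nrow(E)))
  s <- rowSums(E[, idx, drop = FALSE])
  if (aggregate == "mean") s / length(idx) else s
}

# OLS with intercept via QR; x2 optional second predictor
.ols <- function(y, x1, x2 = NULL) {
  X <- if (is.null(x2)) cbind(1, x1) else cbind(1, x1, x2)
  as.numeric(qr.solve(X, y))
}

# Fit the three CPM strength models on a training set, handling degenerate
# (constant) strengths and collinear tails. Returns plain coefficient
# vectors: pos/neg = (intercept, slope); comb = (intercept, slope_pos,
# slope_neg). Degenerate predictors get slope 0 and an intercept equal to
# the training-set behavior mean.
.fit_strengths <- function(s_pos, s_neg, y) {
  vp <- stats::var(s_pos) > 0
  vn <- stats::var(s_neg) > 0
  mu <- mean(y)
  coef_pos <- if (vp) .ols(y, s_pos) else c(mu, 0)
  coef_neg <- if (vn) .ols(y, s_neg) else c(mu, 0)
  collinear <- FALSE
  if (vp && vn) {
    if (abs(stats::cor(s_pos, s_neg)) > 1 - 1e-10) {
      collinear <- TRUE
      coef_comb <- c(coef_pos, 0)
    } else {
      coef_comb <- .ols(y, s_pos, s_neg)
    }
  } else if (vp) {
    coef_comb <- c(coef_pos, 0)
  } else if (vn) {
    coef_comb <- c(coef_neg[1], 0, coef_neg[2])
  } else {
    coef_comb <- c(mu, 0, 0)
  }
  list(positive = coef_pos, negative = coef_neg, combined = coef_comb,
       degenerate_positive = !vp, degenerate_negative = !vn,
       collinear = collinear)
}

.predict_strengths <- function(fit, s_pos, s_neg) {
  cbind(positive = fit$positive[1] + fit$positive[2] * s_pos,
        negative = fit$negative[1] + fit$negative[2] * s_neg,
        combined = fit$combined[1] + fit$combined[2] * s_pos +
          fit$combined[3] * s_neg)
}

#' Fit the CPM linear severity models
#'
#' Computes per-subject positive- and negative-network strengths under the
#' supplied masks and fits three ordinary-least-squares models of behavior:
#' on the positive strength alone, on the negative strength alone, and on
#' both jointly (the combined model, with the two strengths as independent
#' variables). An empty (or constant-strength) tail yields a degenerate
#' intercept-only model for that tail, flagged in the result; collinear
#' strengths (|cor| > 1 - 1e-10) make the combined model fall back to the
#' positive-only fit with a warning.
#'
#' @param dataset A \code{\link{connectome_dataset}} (the training set).
#' @param masks An \code{\link{edge_mask_pair}}.
#' @param aggregate Strength aggregation, \code{"sum"} (default) or
#'   \code{"mean"}.
#' @return A \code{cpm_model}: masks, aggregate, coefficient vectors for the
#'   three models, degeneracy flags, and training metadata.
#' @export
fit_cpm <- function(dataset, masks, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(masks, "edge_mask_pair"))
  if (length(masks$positive) != ncol(dataset$edge_matrix))
    .stopf("mask refers to %d edges, dataset has %d (ordering %s)",
           length(masks$positive), ncol(dataset$edge_matrix),
           masks$edge_ordering)
  n <- length(dataset$behavior)
  if (n < 10) .stopf("need at least 10 subjects to fit, got %d", n)
  s_pos <- .strength(dataset$edge_matrix, which(masks$positive), aggregate)
  s_neg <- .strength(dataset$edge_matrix, which(masks$negative), aggregate)
  fit <- .fit_strengths(s_pos, s_neg, dataset$behavior)
  if (fit$collinear)
    .warnf("positive and negative strengths are collinear; combined model falls back to positive-only")
  if (fit$degenerate_positive)
    .warnf("positive mask empty/constant; positive model is intercept-only")
  if (fit$degenerate_negative)
    .warnf("negative mask empty/constant; negative model is intercept-only")
  structure(list(masks = masks, aggregate = aggregate,
                 coefficients = fit[c("positive", "negative", "combined")],
                 degenerate = c(positive = fit$degenerate_positive,
                                negative = fit$degenerate_negative),
                 collinear = fit$collinear,
                 n_train = n, n_nodes = dataset$n_nodes,
                 edge_ordering = .edge_ordering_version()),
            class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("cpm_model (n_train = %d, %d nodes, aggregate = %s)\n",
              x$n_train, x$n_nodes, x$aggregate))
  cat(sprintf("  positive: %d edges, behavior = %.3f + %.4f * strength\n",
              sum(x$masks$positive), x$coefficients$positive[1],
              x$coefficients$positive[2]))
  cat(sprintf("  negative: %d edges, behavior = %.3f + %.4f * strength\n",
              sum(x$masks$negative), x$coefficients$negative[1],
              x$coefficients$negative[2]))
  cat(sprintf("  combined: behavior = %.3f + %.4f * s_pos + %.4f * s_neg\n",
              x$coefficients$combined[1], x$coefficients$combined[2],
              x$coefficients$combined[3]))
  invisible(x)
}

#' Predict behavior from a fitted CPM model
#'
#' Computes network strengths on new connectivity data with the model's own
#' masks and aggregate, then applies the stored coefficients. Purely
#' deterministic; no refitting.
#'
#' @param object A \code{cpm_model}.
#' @param newdata A \code{connectome_dataset} or a subjects x edges matrix
#'   in the same edge ordering as the model.
#' @param which \code{"combined"} (default), \code{"positive"} or
#'   \code{"negative"}.
#' @param ... Unused.
#' @return Numeric vector of predicted behavior scores.
#' @export
predict.cpm_model <- function(object, newdata,
                              which = c("combined", "positive", "negative"),
                              ...) {
  which <- match.arg(which)
  E <- if (inherits(newdata, "connectome_dataset")) newdata$edge_matrix
  else as.matrix(newdata)
  if (ncol(E) != length(object$masks$positive))
    .stopf("newdata has %d edges but the model expects %d (edge ordering %s)",
           ncol(E), length(object$masks$positive), object$edge_ordering)
  s_pos <- .strength(E, which(object$masks$positive), object$aggregate)
  s_neg <- .strength(E, which(object$masks$negative), object$aggregate)
  co <- object$coefficients
  switch(which,
         positive = co$positive[1] + co$positive[2] * s_pos,
         negative = co$negative[1] + co$negative[2] * s_neg,
         combined = co$combined[1] + co$combined[2] * s_pos +
           co$combined[3] * s_neg)
}

#' Write / read a fitted CPM model as JSON
#'
#' Stores masks (as edge indices), aggregate, coefficients and training
#' metadata; serialization is deterministic (writing twice gives identical
#' bytes) and a restored model predicts to within machine precision.
#'
#' @param model A \code{cpm_model}.
#' @param path JSON file path.
#' @return \code{path} (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cpm_model"))
  jsonlite::write_json(list(
    positive_edges = which(model$masks$positive),
    negative_edges = which(model$masks$negative),
    n_edges = length(model$masks$positive),
    n_nodes = model$n_nodes,
    threshold_p = model$masks$threshold_p,
    covariate_mode = model$masks$covariate_mode,
    aggregate = model$aggregate,
    coefficients = model$coefficients,
    degenerate = as.list(model$degenerate),
    collinear = model$collinear,
    n_train = model$n_train,
    edge_ordering = model$edge_ordering),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$edge_ordering, .edge_ordering_version()))
    .stopf("model file uses edge ordering %s; this package uses %s",
           j$edge_ordering, .edge_ordering_version())
  pos <- neg <- rep(FALSE, j$n_edges)
  pos[as.integer(unlist(j$positive_edges))] <- TRUE
  neg[as.integer(unlist(j$negative_edges))] <- TRUE
  masks <- edge_mask_pair(pos, neg, threshold_p = j$threshold_p,
                          covariate_mode = j$covariate_mode,
                          n_nodes = j$n_nodes)
  structure(list(masks = masks, aggregate = j$aggregate,
                 coefficients = lapply(j$coefficients, as.numeric),
                 degenerate = c(positive = isTRUE(j$degenerate$positive),
                                negative = isTRUE(j$degenerate$negative)),
                 collinear = isTRUE(j$collinear),
                 n_train = as.integer(j$n_train),
                 n_nodes = as.integer(j$n_nodes),
                 edge_ordering = j$edge_ordering),
            class = "cpm_model")
}
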