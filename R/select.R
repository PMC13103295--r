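#' Edge-wise association between connectivity and behavior
#'
#' For every edge, computes the Pearson correlation (or, with covariates, the
#' partial correlation given the covariates) between edge strength and the
#' behavioral score, together with the two-sided p-value from the t
#' transform \code{t = r * sqrt(df / (1 - r^2))} with \code{df = n - 2}
#' (Pearson) or \code{df = n - 2 - k} (partial, k covariates).
#'
#' Partial correlation is computed by residualizing both edge strengths and
#' behavior against the covariates (with intercept) via QR and correlating
#' the residuals — the standard covariate-adjusted variant of CPM edge
#' selection.
#'
#' @param edge_matrix Subjects x edges matrix.
#' @param behavior Numeric vector.
#' @param covariates Subjects x k covariate matrix, or NULL for plain
#'   Pearson correlation.
#' @return Data frame with one row per edge: \code{r}, \code{p}, \code{df}.
#'   Zero-variance edges get \code{r = NA, p = NA}.
#' @export
edge_behavior_stats <- function(edge_matrix, behavior, covariates = NULL) {
  E <- as.matrix(edge_matrix)
  y <- as.numeric(behavior)
  n <- nrow(E)
  if (length(y) != n) .stopf("behavior length mismatch")
  if (is.null(covariates)) {
    k <- 0L
  } else {
    X <- cbind(1, as.matrix(covariates))
    k <- ncol(X) - 1L
    if (n <= k + 3) .stopf("need n > k + 3 subjects for partial correlation")
    qr_x <- qr(X)
    E <- qr.resid(qr_x, E)
    y <- qr.resid(qr_x, y)
  }
  yc <- y - mean(y)
  Ec <- sweep(E, 2, colMeans(E))
  ss_e <- colSums(Ec^2)
  ss_y <- sum(yc^2)
  r <- as.numeric(crossprod(Ec, yc)) / sqrt(ss_e * ss_y)
  r[ss_e == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2L - k
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(r = r, p = p, df = df)
}

#' Select behavior-correlated edges into positive and negative masks
#'
#' The CPM feature-selection step: edges whose association with behavior is
#' significant at \code{threshold_p} are retained, routed by the sign of the
#' correlation into the "positive network" (r > 0) and "negative network"
#' (r < 0). The two masks are disjoint by construction. With
#' \code{covariate_mode = "partial"} (the default) the association is the
#' partial correlation given the dataset's covariates (age, sex, head
#' motion); \code{"none"} uses the plain Pearson correlation.
#'
#' @param dataset A \code{\link{connectome_dataset}}.
#' @param threshold_p Selection threshold on the two-sided p-value
#'   (default 0.01).
#' @param covariate_mode \code{"partial"} or \code{"none"}.
#' @return An \code{edge_mask_pair}: logical vectors \code{positive} and
#'   \code{negative}, plus the threshold, mode and edge-ordering version.
#' @export
select_edges <- function(dataset, threshold_p = 0.01,
                         covariate_mode = c("partial", "none")) {
  covariate_mode <- match.arg(covariate_mode)
  if (threshold_p <= 0 || threshold_p >= 1)
    .stopf("threshold_p must be in (0, 1)")
  covs <- if (covariate_mode == "partial") dataset$covariates else NULL
  if (covariate_mode == "partial" && is.null(covs))
    .stopf("covariate_mode = 'partial' but the dataset has no covariates")
  st <- edge_behavior_stats(dataset$edge_matrix, dataset$behavior, covs)
  dropped <- which(is.na(st$r))
  if (length(dropped) > 0)
    .warnf("%d zero-variance edge(s) excluded from selection",
           length(dropped))
  sel <- !is.na(st$p) & st$p < threshold_p
  edge_mask_pair(positive = sel & st$r > 0,
                 negative = sel & st$r < 0,
                 threshold_p = threshold_p,
                 covariate_mode = covariate_mode,
                 n_nodes = dataset$n_nodes)
}

#' Construct an edge mask pair
#'
#' @param positive,negative Disjoint logical edge vectors of equal length.
#' @param threshold_p Selection threshold the masks were derived at.
#' @param covariate_mode Selection mode used.
#' @param n_nodes Node count the edge ordering refers to.
#' @return An object of class \code{edge_mask_pair}.
#' @export
edge_mask_pair <- function(positive, negative, threshold_p = NA_real_,
                           covariate_mode = NA_character_, n_nodes = NULL) {
  positive <- as.logical(positive)
  negative <- as.logical(negative)
  if (length(positive) != length(negative))
    .stopf("mask lengths differ")
  if (any(positive & negative))
    .stopf("positive and negative masks must be disjoint")
  if (is.null(n_nodes)) n_nodes <- .nodes_from_edges(length(positive))
  if (.n_edges(n_nodes) != length(positive))
    .stopf("mask length %d does not match %d nodes", length(positive),
           n_nodes)
  structure(list(positive = positive, negative = negative,
                 threshold_p = threshold_p, covariate_mode = covariate_mode,
                 n_nodes = as.integer(n_nodes),
                 edge_ordering = .edge_ordering_version()),
            class = "edge_mask_pair")
}

#' @export
print.edge_mask_pair <- function(x, ...) {
  cat(sprintf(
    "edge_mask_pair (%d nodes, %d edges): %d positive, %d negative (p < %s, %s)\n",
    x$n_nodes, length(x$positive), sum(x$positive), sum(x$negative),
    format(x$threshold_p), x$covariate_mode))
  invisible(x)
}

#' Write / read an edge mask pair as JSON
#'
#' Masks are stored as 1-based edge indices per tail together with the
#' threshold and edge-ordering version, so they can be transferred between
#' discovery and external datasets. Serialization is deterministic
#' (byte-stable round trips).
#'
#' @param masks An \code{edge_mask_pair}.
#' @param path Output JSON file.
#' @return \code{path} (write) or the mask pair (read).
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "edge_mask_pair"))
  jsonlite::write_json(list(
    positive = which(masks$positive), negative = which(masks$negative),
    n_edges = length(masks$positive), n_nodes = masks$n_nodes,
    threshold_p = masks$threshold_p, covariate_mode = masks$covariate_mode,
    edge_ordering = masks$edge_ordering),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$edge_ordering, .edge_ordering_version()))
    .stopf("mask file uses edge ordering %s; this package uses %s",
           j$edge_ordering, .edge_ordering_version())
  pos <- neg <- rep(FALSE, j$n_edges)
  pos[as.integer(unlist(j$positive))] <- TRUE
  neg[as.integer(unlist(j$negative))] <- TRUE
  edge_mask_pair(pos, neg, threshold_p = j$threshold_p,
                 covariate_mode = j$covariate_mode, n_nodes = j$n_nodes)
}
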