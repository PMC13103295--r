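#' Node-wise functional connectivity from time series
#'
#' Computes the Pearson correlation between the time courses of every pair of
#' nodes, yielding a symmetric connectivity matrix. The diagonal is set to 0
#' by convention (self-connections are never analysis features).
#'
#' @param ts Numeric matrix, timepoints x nodes.
#' @return Symmetric \code{n_nodes x n_nodes} matrix of Pearson r with zero
#'   diagonal and attribute \code{scale = "pearson_r"}.
#' @examples
#' ts <- cbind(a = sin(1:20), b = cos(1:20))
#' compute_fc(ts)
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) .stopf("need at least 3 timepoints, got %d", nrow(ts))
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0))
    .stopf("zero-variance time course at node(s): %s",
           paste(which(sds == 0), collapse = ", "))
  r <- stats::cor(ts)
  diag(r) <- 0
  attr(r, "scale") <- "pearson_r"
  r
}

#' Fisher r-to-z transform of connectivity values
#'
#' Applies the variance-stabilizing transform \code{z = atanh(r)} elementwise.
#' Correlations at or beyond \code{+/-1} (possible only for degenerate input)
#' are clipped to \code{+/-(1 - 1e-7)} with a warning so the transform stays
#' finite.
#'
#' @param fc Matrix (or vector) of Pearson correlations in \code{[-1, 1]}.
#' @return Object of the same shape on the Fisher-z scale, attribute
#'   \code{scale = "fisher_z"}; a zero diagonal maps to zero.
#' @export
fisher_z <- function(fc) {
  lim <- 1 - 1e-7
  n_clip <- sum(abs(fc) > lim)
  if (n_clip > 0) {
    .warnf("clipped %d correlation(s) with |r| > %g before atanh", n_clip, lim)
    fc <- pmin(pmax(fc, -lim), lim)
  }
  z <- atanh(fc)
  attr(z, "scale") <- "fisher_z"
  z
}
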