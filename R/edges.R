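#' Edge index table for an n-node connectome
#'
#' Enumerates the strict upper triangle of an \code{n x n} symmetric
#' connectivity matrix in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This is the canonical edge
#' ordering used by every vectorized representation in the package; masks and
#' models are only portable between datasets that share it.
#'
#' @param n_nodes Number of atlas nodes.
#' @return A data.frame with columns \code{node_i}, \code{node_j}
#'   (1-based, \code{node_i < node_j}), one row per edge, in canonical order.
#' @export
edge_index_table <- function(n_nodes) {
  if (n_nodes < 2) .stopf("need at least 2 nodes, got %d", n_nodes)
  w <- which(lower.tri(matrix(FALSE, n_nodes, n_nodes)), arr.ind = TRUE)
  # column-major lower triangle enumerates the same pairs as row-major upper
  data.frame(node_i = as.integer(w[, "col"]), node_j = as.integer(w[, "row"]))
}

# linear edge index of pair (i, j), i < j, under the canonical ordering
.edge_linear_index <- function(i, j, n_nodes) {
  if (any(i >= j)) .stopf("edge pairs must satisfy node_i < node_j")
  as.integer((i - 1) * (2 * n_nodes - i) / 2 + (j - i))
}

.n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

# infer node count from an edge-vector length; errors if not triangular
.nodes_from_edges <- function(n_edges) {
  n <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(n - round(n)) > 1e-9)
    .stopf("edge vector length %d is not n(n-1)/2 for any integer n", n_edges)
  as.integer(round(n))
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in the canonical row-major edge order
#' (see \code{\link{edge_index_table}}). The diagonal is ignored:
#' self-connections are never features.
#'
#' @param m Symmetric numeric matrix.
#' @param tol Symmetry tolerance; asymmetry beyond it is an error.
#' @return Numeric vector of length \code{n(n-1)/2}.
#' @seealso \code{\link{devectorize_edges}}
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    .stopf("expected a square matrix")
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    .stopf("matrix is asymmetric (max |m - t(m)| = %g > tol %g)", asym, tol)
  m[lower.tri(m)]
}

#' Reconstruct a symmetric matrix from an edge vector
#'
#' Inverse of \code{\link{vectorize_edges}}; the diagonal is set to zero.
#'
#' @param v Edge vector in canonical order.
#' @return Symmetric matrix with zero diagonal.
#' @export
devectorize_edges <- function(v) {
  n <- .nodes_from_edges(length(v))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}
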