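#' Summarize a selected-edge mask over canonical networks
#'
#' Maps each selected edge onto the canonical-network pair of its two
#' endpoint nodes and accumulates: a symmetric 10 x 10 count matrix (the
#' diagonal holds within-network counts, each within-network edge counted
#' once), a per-network total (the number of selected edges with at least
#' one endpoint in the network — incidence counting, so a between-network
#' edge contributes to both of its networks), and a per-node degree (number
#' of selected edges incident to the node).
#'
#' @param mask Logical edge vector in canonical ordering, or an
#'   \code{\link{edge_mask_pair}} combined with \code{tail}.
#' @param atlas Atlas data frame (\code{node_id}, \code{network}) covering
#'   every node.
#' @param tail When \code{mask} is an \code{edge_mask_pair}: which tail to
#'   summarize, \code{"positive"} or \code{"negative"}.
#' @return A \code{network_edge_summary}: \code{count_matrix},
#'   \code{per_network_total}, \code{per_node_degree}, \code{n_edges},
#'   \code{tail}.
#' @export
summarize_mask <- function(mask, atlas, tail = c("positive", "negative")) {
  if (inherits(mask, "edge_mask_pair")) {
    tail <- match.arg(tail)
    mask <- mask[[tail]]
  } else {
    tail <- if (identical(tail, c("positive", "negative"))) NA_character_
    else match.arg(tail)
  }
  n_nodes <- .nodes_from_edges(length(mask))
  .validate_atlas(atlas, n_nodes)
  nets <- canonical_networks()
  net_of <- atlas$network[match(seq_len(n_nodes), atlas$node_id)]
  if (anyNA(net_of)) .stopf("atlas does not label every node")
  code <- match(net_of, nets)
  ei <- edge_index_table(n_nodes)
  idx <- which(mask)
  i <- ei$node_i[idx]; j <- ei$node_j[idx]
  ni <- code[i]; nj <- code[j]
  lo <- pmin(ni, nj); hi <- pmax(ni, nj)
  tab <- table(factor(lo, levels = seq_along(nets)),
               factor(hi, levels = seq_along(nets)))
  cm <- matrix(as.integer(tab), length(nets), length(nets))
  cm <- cm + t(cm)
  diag(cm) <- diag(matrix(as.integer(tab), length(nets)))
  dimnames(cm) <- list(nets, nets)
  totals <- vapply(seq_along(nets), function(g)
    sum(ni == g | nj == g), integer(1))
  names(totals) <- nets
  degree <- tabulate(c(i, j), nbins = n_nodes)
  structure(list(count_matrix = cm, per_network_total = totals,
                 per_node_degree = degree, n_edges = length(idx),
                 tail = tail, n_nodes = n_nodes),
            class = "network_edge_summary")
}

#' @export
print.network_edge_summary <- function(x, ...) {
  cat(sprintf("network_edge_summary (%s tail): %d edges over %d nodes\n",
              x$tail, x$n_edges, x$n_nodes))
  print(x$count_matrix)
  invisible(x)
}

#' Rank canonical networks by selected-edge count
#'
#' Orders the networks by their edge totals, descending; ties are broken by
#' the canonical label order (\code{\link{canonical_networks}}). The default
#' \code{"incidence"} counting credits a between-network edge to both of its
#' networks (so totals across networks can exceed the mask size — the
#' convention under which one network can hold most of a tail's
#' connections); \code{"within"} counts only within-network edges.
#'
#' @param summary A \code{\link{summarize_mask}} result.
#' @param count \code{"incidence"} (default) or \code{"within"}.
#' @return Data frame (\code{network}, \code{total}), ranked.
#' @export
rank_networks <- function(summary, count = c("incidence", "within")) {
  count <- match.arg(count)
  stopifnot(inherits(summary, "network_edge_summary"))
  totals <- if (count == "incidence") summary$per_network_total
  else diag(summary$count_matrix)
  nets <- canonical_networks()
  ord <- order(-totals, match(names(totals), nets))
  data.frame(network = names(totals)[ord], total = as.integer(totals[ord]),
             row.names = NULL)
}

#' Nodes above a degree threshold
#'
#' Hub-style display filtering: nodes whose selected-edge degree strictly
#' exceeds \code{min_degree} (default 30, the usual display threshold for
#' plotted connections).
#'
#' @param summary A \code{\link{summarize_mask}} result.
#' @param min_degree Strict lower bound on degree (>= 0).
#' @return Integer vector of node IDs.
#' @export
degree_threshold_view <- function(summary, min_degree = 30) {
  stopifnot(inherits(summary, "network_edge_summary"))
  if (min_degree < 0) .stopf("min_degree must be >= 0")
  which(summary$per_node_degree > min_degree)
}

#' Write a network summary to a directory
#'
#' Emits \code{summary_<tail>.tsv} (the 10 x 10 count matrix),
#' \code{network_totals_<tail>.tsv} and \code{node_degree_<tail>.tsv}.
#'
#' @param summary A \code{network_edge_summary}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "network_edge_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tail <- if (is.na(summary$tail)) "mask" else summary$tail
  utils::write.table(summary$count_matrix,
                     file.path(dir, sprintf("summary_%s.tsv", tail)),
                     sep = "\t", quote = FALSE)
  utils::write.table(
    data.frame(network = names(summary$per_network_total),
               total = as.integer(summary$per_network_total)),
    file.path(dir, sprintf("network_totals_%s.tsv", tail)),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node_id = seq_len(summary$n_nodes),
               degree = summary$per_node_degree),
    file.path(dir, sprintf("node_degree_%s.tsv", tail)),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Plot a network-pair edge-count matrix
#'
#' Simple static heat map of the 10 x 10 within/between edge-count matrix.
#'
#' @param x A \code{network_edge_summary}.
#' @param ... Passed to \code{image}.
#' @export
plot.network_edge_summary <- function(x, ...) {
  nets <- rownames(x$count_matrix)
  k <- length(nets)
  graphics::image(seq_len(k), seq_len(k), t(x$count_matrix[k:1, ]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("edges per network pair (%s tail)", x$tail),
                  ...)
  graphics::axis(1, at = seq_len(k), labels = nets, las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(nets), las = 2,
                 cex.axis = 0.8)
  invisible(x)
}
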