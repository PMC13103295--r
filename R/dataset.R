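#' Assemble a connectome dataset
#'
#' The unit of analysis: a subjects x edges matrix of Fisher-z functional
#' connectivity, the behavioral severity score to be predicted, and the
#' nuisance covariates (age, sex, mean framewise displacement) used for
#' covariate-adjusted edge selection.
#'
#' @param edge_matrix Numeric matrix, subjects x edges, edges in the
#'   canonical row-major upper-triangle order (\code{\link{edge_index_table}}).
#' @param behavior Numeric vector of severity scores, one per subject.
#' @param n_nodes Number of atlas nodes; \code{ncol(edge_matrix)} must equal
#'   \code{n_nodes(n_nodes-1)/2}.
#' @param covariates Numeric matrix (subjects x k) of nuisance covariates, or
#'   NULL.
#' @param atlas Optional atlas data frame (\code{node_id}, \code{network}).
#' @param subject_ids Optional character IDs; defaults to \code{sub0001}...
#' @param subjects Optional full subject table (kept for file round trips).
#' @return An object of class \code{connectome_dataset}.
#' @export
connectome_dataset <- function(edge_matrix, behavior, n_nodes,
                               covariates = NULL, atlas = NULL,
                               subject_ids = NULL, subjects = NULL) {
  edge_matrix <- as.matrix(edge_matrix)
  n <- nrow(edge_matrix)
  if (ncol(edge_matrix) != .n_edges(n_nodes))
    .stopf("edge matrix has %d columns; expected %d for %d nodes",
           ncol(edge_matrix), .n_edges(n_nodes), n_nodes)
  if (length(behavior) != n)
    .stopf("behavior length %d != %d subjects", length(behavior), n)
  if (anyNA(edge_matrix) || anyNA(behavior) || !all(is.finite(behavior)))
    .stopf("edge matrix and behavior must be finite with no missing values")
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%04d", seq_len(n))
  if (anyDuplicated(subject_ids))
    .stopf("subject_ids must be unique")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      .stopf("covariates have %d rows; expected %d", nrow(covariates), n)
  }
  if (!is.null(atlas)) .validate_atlas(atlas, n_nodes)
  structure(list(subject_ids = as.character(subject_ids),
                 edge_matrix = edge_matrix,
                 behavior = as.numeric(behavior),
                 covariates = covariates,
                 n_nodes = as.integer(n_nodes),
                 atlas = atlas,
                 subjects = subjects,
                 edge_ordering = .edge_ordering_version()),
            class = "connectome_dataset")
}

.validate_atlas <- function(atlas, n_nodes = NULL) {
  if (!all(c("node_id", "network") %in% names(atlas)))
    .stopf("atlas needs columns node_id and network")
  bad <- setdiff(unique(atlas$network), canonical_networks())
  if (length(bad) > 0)
    .stopf("unknown network label(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(atlas$node_id))
    .stopf("duplicate node_id in atlas")
  if (!is.null(n_nodes) && !setequal(atlas$node_id, seq_len(n_nodes)))
    .stopf("atlas must label nodes 1..%d exactly once", n_nodes)
  invisible(atlas)
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat(sprintf("connectome_dataset: %d subjects, %d nodes (%d edges)\n",
              length(x$behavior), x$n_nodes, ncol(x$edge_matrix)))
  cat(sprintf("  behavior: mean %.2f, sd %.2f\n",
              mean(x$behavior), stats::sd(x$behavior)))
  cat(sprintf("  covariates: %s\n",
              if (is.null(x$covariates)) "none"
              else paste(colnames(x$covariates), collapse = ", ")))
  cat(sprintf("  atlas: %s; edge ordering %s\n",
              if (is.null(x$atlas)) "none" else "10-network canonical",
              x$edge_ordering))
  invisible(x)
}

#' Subset a connectome dataset by subject
#'
#' @param dataset A \code{connectome_dataset}.
#' @param idx Integer or logical subject index.
#' @return A \code{connectome_dataset} containing the selected subjects;
#'   atlas and edge ordering are shared.
#' @export
subset_dataset <- function(dataset, idx) {
  connectome_dataset(dataset$edge_matrix[idx, , drop = FALSE],
                     dataset$behavior[idx],
                     dataset$n_nodes,
                     covariates = if (is.null(dataset$covariates)) NULL
                     else dataset$covariates[idx, , drop = FALSE],
                     atlas = dataset$atlas,
                     subject_ids = dataset$subject_ids[idx],
                     subjects = if (is.null(dataset$subjects)) NULL
                     else dataset$subjects[idx, , drop = FALSE])
}

#' Write a dataset to a directory of delimited text files
#'
#' Emits \code{subjects.tsv}, \code{atlas.tsv}, connectivity in either long
#' format (\code{edges.tsv}: subject_id, node_i, node_j, z with
#' \code{node_i < node_j}) or one square matrix file per subject, and a
#' \code{manifest.json} sidecar recording node count, edge ordering version
#' and scale.
#'
#' @param dataset A \code{connectome_dataset}.
#' @param dir Output directory (created if absent).
#' @param format \code{"edges"} (long table, default) or \code{"matrix"}.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("edges", "matrix")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- dataset$subjects
  if (is.null(subj)) {
    subj <- data.frame(subject_id = dataset$subject_ids,
                       behavior = dataset$behavior)
    if (!is.null(dataset$covariates))
      subj <- cbind(subj, as.data.frame(dataset$covariates))
  }
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$atlas))
    utils::write.table(dataset$atlas, file.path(dir, "atlas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (format == "edges") {
    ei <- edge_index_table(dataset$n_nodes)
    n_e <- nrow(ei)
    long <- data.frame(
      subject_id = rep(dataset$subject_ids, each = n_e),
      node_i = rep(ei$node_i, times = length(dataset$subject_ids)),
      node_j = rep(ei$node_j, times = length(dataset$subject_ids)),
      z = as.vector(t(dataset$edge_matrix)))
    utils::write.table(long, file.path(dir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    for (s in seq_along(dataset$subject_ids)) {
      m <- devectorize_edges(dataset$edge_matrix[s, ])
      utils::write.table(m, file.path(dir, sprintf("fc_%s.txt",
                                                   dataset$subject_ids[s])),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  .write_manifest(file.path(dir, "manifest.json"),
                  list(n_nodes = dataset$n_nodes,
                       n_subjects = length(dataset$subject_ids),
                       scale = "fisher_z", format = format))
  invisible(dir)
}

#' Read a dataset written by \code{write_dataset}
#'
#' Subject IDs in the connectivity data and subject table must match exactly
#' (mismatches are reported by ID); node counts must be consistent across
#' subjects.
#'
#' @param dir Directory containing \code{subjects.tsv}, \code{manifest.json},
#'   and either \code{edges.tsv} or per-subject \code{fc_<id>.txt} files;
#'   \code{atlas.tsv} is read if present.
#' @return A \code{connectome_dataset}.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) .stopf("no manifest.json in %s", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(man$edge_ordering, .edge_ordering_version()))
    .stopf("edge ordering %s does not match this package's %s",
           man$edge_ordering, .edge_ordering_version())
  subj_path <- file.path(dir, "subjects.tsv")
  if (!file.exists(subj_path)) .stopf("missing subject table: %s", subj_path)
  subj <- utils::read.delim(subj_path, stringsAsFactors = FALSE)
  subj$subject_id <- as.character(subj$subject_id)
  n_nodes <- as.integer(man$n_nodes)
  atlas <- NULL
  atlas_path <- file.path(dir, "atlas.tsv")
  if (file.exists(atlas_path)) {
    atlas <- utils::read.delim(atlas_path, stringsAsFactors = FALSE)
    .validate_atlas(atlas, n_nodes)
  }
  if (identical(man$format, "edges")) {
    long <- utils::read.delim(file.path(dir, "edges.tsv"),
                              stringsAsFactors = FALSE)
    long$subject_id <- as.character(long$subject_id)
    ids <- unique(long$subject_id)
    .check_id_match(ids, subj$subject_id)
    if (any(long$node_i >= long$node_j))
      .stopf("edges.tsv requires node_i < node_j")
    if (max(long$node_j) > n_nodes)
      .stopf("edge references node %d but manifest declares %d nodes",
             max(long$node_j), n_nodes)
    n_e <- .n_edges(n_nodes)
    per <- table(long$subject_id)
    if (length(unique(per)) != 1 || per[[1]] != n_e)
      .stopf("inconsistent edge counts per subject (expected %d)", n_e)
    emat <- matrix(NA_real_, length(ids), n_e)
    col <- .edge_linear_index(long$node_i, long$node_j, n_nodes)
    row <- match(long$subject_id, ids)
    emat[cbind(row, col)] <- long$z
  } else {
    ids <- subj$subject_id
    files <- file.path(dir, sprintf("fc_%s.txt", ids))
    missing <- !file.exists(files)
    if (any(missing))
      .stopf("no connectivity matrix for subject(s): %s",
             paste(ids[missing], collapse = ", "))
    emat <- t(vapply(files, function(f) {
      m <- as.matrix(utils::read.table(f))
      dimnames(m) <- NULL
      if (nrow(m) != n_nodes)
        .stopf("%s has %d nodes; manifest declares %d", f, nrow(m), n_nodes)
      vectorize_edges(m)
    }, numeric(.n_edges(n_nodes))))
  }
  .check_id_match(ids, subj$subject_id)
  subj <- subj[match(ids, subj$subject_id), , drop = FALSE]
  cov_cols <- intersect(c("age", "sex", "mean_fd_mm"), names(subj))
  covariates <- if (length(cov_cols) > 0)
    as.matrix(subj[, cov_cols, drop = FALSE]) else NULL
  connectome_dataset(emat, subj$behavior, n_nodes, covariates = covariates,
                     atlas = atlas, subject_ids = ids, subjects = subj)
}

.check_id_match <- function(fc_ids, table_ids) {
  only_fc <- setdiff(fc_ids, table_ids)
  only_tab <- setdiff(table_ids, fc_ids)
  if (length(only_fc) > 0 || length(only_tab) > 0)
    .stopf("subject ID mismatch; in connectivity only: [%s]; in table only: [%s]",
           paste(only_fc, collapse = ", "), paste(only_tab, collapse = ", "))
  invisible(TRUE)
}
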