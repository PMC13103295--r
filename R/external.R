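#' Fixed-model external validation
#'
#' Applies a discovery-trained CPM model — masks and coefficients unchanged,
#' no reselection, no refitting — to an independent dataset and correlates
#' the predicted with the observed behavior scores for the positive,
#' negative and combined models. A node-count or edge-ordering mismatch is
#' an error; edges are never silently reindexed.
#'
#' @param model A \code{\link{fit_cpm}} model trained on the discovery set.
#' @param external A \code{\link{connectome_dataset}} with the same node
#'   count and edge ordering.
#' @return An \code{external_validation} object: per-subject predictions,
#'   per-model metrics (r, parametric p, RMSE), and the fingerprint of the
#'   applied model for provenance.
#' @export
validate_external <- function(model, external) {
  stopifnot(inherits(model, "cpm_model"),
            inherits(external, "connectome_dataset"))
  if (model$n_nodes != external$n_nodes)
    .stopf("model was trained on %d nodes, external data has %d",
           model$n_nodes, external$n_nodes)
  if (!identical(model$edge_ordering, external$edge_ordering))
    .stopf("edge ordering mismatch: model %s vs data %s",
           model$edge_ordering, external$edge_ordering)
  fp <- .fingerprint(model)
  preds <- cbind(
    positive = predict(model, external, which = "positive"),
    negative = predict(model, external, which = "negative"),
    combined = predict(model, external, which = "combined"))
  metrics <- lapply(c(positive = "positive", negative = "negative",
                      combined = "combined"), function(mod)
                        evaluate_predictions(preds[, mod],
                                             external$behavior))
  structure(list(subject_ids = external$subject_ids,
                 observed = external$behavior,
                 predictions = preds, metrics = metrics,
                 model_fingerprint = fp,
                 n_train = model$n_train,
                 threshold_p = model$masks$threshold_p),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf(
    "external_validation: %d subjects, model trained on %d (fingerprint %s)\n",
    length(x$observed), x$n_train, x$model_fingerprint))
  for (mod in names(x$metrics)) {
    m <- x$metrics[[mod]]
    cat(sprintf("  %-9s r = %6.3f  p = %.3g  RMSE = %.3f\n",
                mod, m$r, m$p_param, m$rmse))
  }
  invisible(x)
}

#' Write an external-validation result to a directory
#'
#' Emits \code{externalresult.tsv} and \code{external_metrics.json}.
#'
#' @param result An \code{external_validation}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_external_result <- function(result, dir) {
  stopifnot(inherits(result, "external_validation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(subject_id = result$subject_ids, observed = result$observed,
               pred_pos = result$predictions[, "positive"],
               pred_neg = result$predictions[, "negative"],
               pred_combined = result$predictions[, "combined"]),
    file.path(dir, "externalresult.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .write_manifest(file.path(dir, "external_metrics.json"),
                  list(metrics = result$metrics,
                       model_fingerprint = result$model_fingerprint,
                       n_external = length(result$observed),
                       n_train = result$n_train))
  invisible(dir)
}
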