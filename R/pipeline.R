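#' Run the full CPM pipeline
#'
#' Wires the stages end to end: simulate (or load) a dataset, motion QC,
#' cross-validated prediction, optional permutation test, optional
#' fixed-model external validation, and canonical-network summaries of the
#' full-sample masks. Every stage writes its declared files into
#' \code{out_dir} together with JSON manifests carrying the configuration,
#' seed and package version; reruns with an identical config and seed are
#' byte-identical.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   \code{data_dir} (read an existing dataset instead of simulating),
#'   generator fields (\code{n_subjects}, \code{n_nodes}, \code{n_pos_edges},
#'   \code{n_neg_edges}, \code{effect_r}, \code{confound_strength}),
#'   \code{threshold_p} (default 0.01), \code{covariate_mode} (default
#'   "partial"), \code{aggregate} (default "sum"), \code{scheme} (default
#'   "loocv"), \code{k}, \code{n_perm} (default 1000), \code{min_degree}
#'   (default 30), \code{external_fraction} (default 0.11), \code{seed}
#'   (required).
#' @param out_dir Output run directory (created).
#' @param stages Character subset of
#'   \code{c("simulate", "qc", "crossval", "permtest", "external",
#'   "summarize")}.
#' @return Invisibly, a list with the per-stage result objects and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "qc", "crossval",
                                    "summarize")) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(threshold_p = 0.01, covariate_mode = "partial",
                   aggregate = "sum", scheme = "loocv", k = NULL,
                   n_perm = 1000, min_degree = 30,
                   external_fraction = 0.11,
                   n_subjects = 200, n_nodes = 60, n_pos_edges = 20,
                   n_neg_edges = 20, effect_r = 0.4, confound_strength = 0)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) .stopf("config must provide a seed")
  known <- c("simulate", "qc", "crossval", "permtest", "external",
             "summarize")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) .stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_manifest(file.path(out_dir, "manifest.json"),
                  list(config = cfg[order(names(cfg))],
                       stages = stages,
                       config_fingerprint = .fingerprint(cfg)))
  result <- list(out_dir = out_dir)

  if (!is.null(cfg$data_dir)) {
    dataset <- read_dataset(cfg$data_dir)
    truth <- NULL
  } else if ("simulate" %in% stages) {
    gen <- generator_config(n_subjects = cfg$n_subjects,
                            n_nodes = cfg$n_nodes,
                            n_pos_edges = cfg$n_pos_edges,
                            n_neg_edges = cfg$n_neg_edges,
                            effect_r = cfg$effect_r,
                            confound_strength = cfg$confound_strength,
                            seed = cfg$seed)
    sim <- generate_dataset(gen)
    dataset <- sim$dataset
    truth <- sim$truth
    write_dataset(dataset, file.path(out_dir, "data"))
    jsonlite::write_json(list(positive = which(truth$true_positive_mask),
                              negative = which(truth$true_negative_mask),
                              confound = which(truth$confound_mask),
                              beta = truth$beta),
                         file.path(out_dir, "data", "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    .stopf("no data_dir configured and 'simulate' not among stages")
  }
  result$dataset <- dataset

  if ("qc" %in% stages && !is.null(dataset$subjects) &&
      all(c("max_translation_mm", "max_rotation_deg", "mean_fd_mm") %in%
          names(dataset$subjects))) {
    qc <- qc_filter(dataset$subjects)
    if (nrow(qc$excluded) > 0) {
      keep <- dataset$subject_ids %in% qc$kept$subject_id
      dataset <- subset_dataset(dataset, keep)
      utils::write.table(qc$excluded, file.path(out_dir, "qc_excluded.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    result$qc <- qc
  }

  external <- NULL
  if ("external" %in% stages) {
    parts <- split_dataset(dataset,
                           c(1 - cfg$external_fraction,
                             cfg$external_fraction), seed = cfg$seed)
    dataset <- parts$discovery
    external <- parts$external
  }

  if ("crossval" %in% stages) {
    cv <- run_cv(dataset, threshold_p = cfg$threshold_p,
                 scheme = cfg$scheme, k = cfg$k,
                 covariate_mode = cfg$covariate_mode,
                 aggregate = cfg$aggregate, seed = cfg$seed)
    write_cv_result(cv, out_dir)
    result$cv <- cv
  }

  if ("permtest" %in% stages) {
    perm <- permutation_test(dataset, threshold_p = cfg$threshold_p,
                             scheme = cfg$scheme, k = cfg$k,
                             covariate_mode = cfg$covariate_mode,
                             aggregate = cfg$aggregate,
                             n_perm = cfg$n_perm, seed = cfg$seed)
    write_perm_result(perm, out_dir)
    result$perm <- perm
  }

  masks <- select_edges(dataset, threshold_p = cfg$threshold_p,
                        covariate_mode = cfg$covariate_mode)
  write_masks(masks, file.path(out_dir, "masks.json"))
  model <- fit_cpm(dataset, masks, aggregate = cfg$aggregate)
  write_model(model, file.path(out_dir, "model.json"))
  result$masks <- masks
  result$model <- model

  if ("external" %in% stages) {
    ext <- validate_external(model, external)
    write_external_result(ext, out_dir)
    result$external <- ext
  }

  if ("summarize" %in% stages) {
    if (is.null(dataset$atlas))
      .stopf("summarize stage requires an atlas (none in dataset)")
    for (tail in c("positive", "negative")) {
      sm <- summarize_mask(masks, dataset$atlas, tail = tail)
      write_summary(sm, out_dir)
      result[[paste0("summary_", tail)]] <- sm
      hubs <- degree_threshold_view(sm, cfg$min_degree)
      utils::write.table(
        data.frame(node_id = hubs,
                   degree = sm$per_node_degree[hubs]),
        file.path(out_dir, sprintf("hubs_%s.tsv", tail)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(result)
}
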