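#' Head-motion quality-control filter
#'
#' Excludes subjects whose head movement exceeds any of three thresholds:
#' maximum translation > 2.5 mm, maximum rotation > 2.5 degrees, or mean
#' framewise displacement > 0.2 mm. All comparisons are strict, so a subject
#' sitting exactly at a threshold is kept; the three rules are OR-combined.
#'
#' @param subjects Data frame with columns \code{subject_id},
#'   \code{max_translation_mm}, \code{max_rotation_deg}, \code{mean_fd_mm}.
#' @param max_translation,max_rotation,max_mean_fd Exclusion thresholds.
#' @return List with \code{kept} (data frame of retained subjects) and
#'   \code{excluded} (data frame with an extra \code{reason} column naming
#'   every rule each excluded subject triggered).
#' @export
qc_filter <- function(subjects, max_translation = 2.5, max_rotation = 2.5,
                      max_mean_fd = 0.2) {
  need <- c("subject_id", "max_translation_mm", "max_rotation_deg",
            "mean_fd_mm")
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0)
    .stopf("subject table lacks column(s): %s", paste(miss, collapse = ", "))
  for (col in need[-1]) {
    bad <- is.na(subjects[[col]])
    if (any(bad))
      .stopf("missing %s for subject(s): %s", col,
             paste(subjects$subject_id[bad], collapse = ", "))
    if (any(subjects[[col]] < 0))
      .stopf("negative %s for subject(s): %s", col,
             paste(subjects$subject_id[subjects[[col]] < 0], collapse = ", "))
  }
  hit_tr <- subjects$max_translation_mm > max_translation
  hit_ro <- subjects$max_rotation_deg > max_rotation
  hit_fd <- subjects$mean_fd_mm > max_mean_fd
  out <- hit_tr | hit_ro | hit_fd
  reason <- vapply(seq_len(nrow(subjects)), function(i) {
    paste(c("max_translation", "max_rotation",
            "mean_fd")[c(hit_tr[i], hit_ro[i], hit_fd[i])], collapse = ";")
  }, character(1))
  excluded <- subjects[out, , drop = FALSE]
  excluded$reason <- reason[out]
  list(kept = subjects[!out, , drop = FALSE], excluded = excluded)
}
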