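# internal helpers shared across modules

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards, so library functions never clobber a user's random stream.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# cheap stable fingerprint of an R object (provenance / mutation checks);
# rolling polynomial hash over the serialized bytes, reported as hex
.fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3L))
  # drop the serialization header (R version stamps) so the fingerprint only
  # reflects content
  bytes <- bytes[-seq_len(min(14L, length(bytes)))]
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.edge_ordering_version <- function() "ut-rowmajor-v1"

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# manifest written next to every numeric output; no timestamps so that reruns
# with identical config + seed are byte-identical
.write_manifest <- function(path, fields) {
  fields$package <- "cpmtools"
  fields$package_version <- as.character(utils::packageVersion("cpmtools"))
  fields$edge_ordering <- .edge_ordering_version()
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
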