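#' Canonical large-scale brain networks
#'
#' The ten canonical networks used to summarize selected edges, in their
#' fixed reference order: medial frontal (MF), frontoparietal (FP), default
#' mode (DMN), motor/sensory (Mot), visual a (VI), visual b (VII), visual
#' association (Vas), salience (SAL), subcortical (SC) and
#' cerebellum/brainstem (CBL). This order also serves as the deterministic
#' tie-break when ranking networks by edge count.
#'
#' @return Character vector of the ten network codes.
#' @export
canonical_networks <- function() {
  c("MF", "FP", "DMN", "Mot", "VI", "VII", "Vas", "SAL", "SC", "CBL")
}

# rough relative parcel counts of a whole-brain functional atlas; used as the
# default network proportions of the synthetic atlas generator
.default_network_proportions <- function() {
  p <- c(MF = 0.08, FP = 0.12, DMN = 0.10, Mot = 0.12, VI = 0.07,
         VII = 0.07, Vas = 0.10, SAL = 0.09, SC = 0.10, CBL = 0.15)
  p
}
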