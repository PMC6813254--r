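# Synthetic seed marker profiles. The original pI and terminase HMM profiles
# were built from reference genome sets that are not redistributable, so the
# package ships synthetic stand-in consensus motifs (Walker-box-flavoured
# ATPase-like strings) from which PSSMs are built. Real analyses supply their
# own profiles or parsed hmmsearch output; every function that consumes a
# model is agnostic to its origin.

.pi_consensus <- "GPSGSGKTTYLRELAHRLPEVVYTDEFG"
.terminase_consensus <- "WQGRGSGKSEWIDAVLRQMTKFNPLAGE"

#' Synthetic seed model for the pI-like morphogenesis ATPase
#'
#' A PSSM built from a fixed synthetic 28-residue ATPase-motif consensus.
#' This is a stand-in for a real pI profile: it exercises the marker engine,
#' the detection pipeline and the synthetic benchmark, and is what
#' [generate_fixture()] plants (with mutations) into synthetic pI genes.
#'
#' @return A `marker_model` (origin `"seed"`).
#' @export
inovirus_seed_model <- function() {
  build_pssm(.pi_consensus, model_id = "pI_seed_synthetic", origin = "seed")
}

#' Synthetic seed models for Caudovirales terminase detection
#'
#' Synthetic stand-ins for the terminase large-subunit profiles used to flag
#' Caudovirales co-infection; [generate_fixture()] plants the matching motif
#' into its Caudovirales-like confounder cassettes.
#'
#' @return A list of `marker_model`s.
#' @export
terminase_seed_models <- function() {
  list(build_pssm(.terminase_consensus, model_id = "terminase_seed_synthetic",
                  origin = "seed"))
}
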