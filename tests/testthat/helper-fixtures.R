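## Small hand-built genomes and scaled simulation profiles used across
## test files.

## one 30 bp plus-strand gene on a 40 bp circular molecule
toy_genome <- function() {
  Mitogenome("TOY1", organism = "toy", circular = TRUE,
             sequence = paste0("ATGAAATTTGGGCCCAAATTTGGGCCCTAA",
                               "ACGTACGTAC"),
             features = data.frame(name = "ND2", kind = "PCG",
                                   strand = "+", start = 1, end = 30,
                                   anticodon = NA))
}

## reduced gene lengths (same incomplete-stop classes, same junction
## plans) used where many replicate simulations are aligned; the
## composition/architecture guarantees are unchanged
scaled_params <- function(seed = 1L) {
  simulationParams(
    seed = seed,
    pcg_lengths = c(ND2 = 342, COI = 513, COII = 232, ATP8 = 160,
                    ATP6 = 228, COIII = 264, ND3 = 120, ND5 = 575,
                    ND4 = 448, ND4L = 146, ND6 = 177, CYTB = 379,
                    ND1 = 316),
    rrn_lengths = c(rrnL = 660, rrnS = 600),
    cr_length = 400)
}

panel_genomes <- function(panel) lapply(panel, `[[`, "genome")
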