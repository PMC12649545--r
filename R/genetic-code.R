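#' The invertebrate mitochondrial genetic code
#'
#' Builds the genetic-code object used throughout the package: the
#' codon-to-amino-acid table (NCBI translation table 5 by default, where
#' AUA = Met, UGA = Trp, AGA/AGG = Ser and the only stops are UAA/UAG),
#' the start- and stop-codon sets, the amino-acid synonymous families
#' (Leu has 6 codons, Ser 8 under table 5), and the synonymous
#' sub-families: the partition of sense codons into groups sharing both
#' the encoded amino acid and the first two codon bases. Table 5 yields
#' 13 two-fold and 9 four-fold sub-families covering all 62 sense
#' codons; this partition is what keeps Wright's ENC class algebra valid
#' for a non-standard code.
#'
#' @param tableId integer NCBI translation table id; default 5
#'   (invertebrate mitochondrial).
#' @return A list of class \code{GeneticCode} with elements
#'   \code{table_id}, \code{codons} (the 64 DNA codons in fixed
#'   TTT..GGG order), \code{aa} (named character, codon to one-letter
#'   amino acid, \code{"*"} for stop), \code{start_codons},
#'   \code{stop_codons}, \code{sense_codons}, \code{aa_family} (named
#'   factor: codon to amino-acid family), and \code{subfamily} (named
#'   character: sense codon to sub-family label \code{"<XY>:<aa>"}).
#' @examples
#' gc5 <- mitoGeneticCode()
#' gc5$aa[c("ATA", "TGA", "AGA")]   # M, W, S under table 5
#' table(table(gc5$subfamily))      # 13 two-fold, 9 four-fold
#' @export
mitoGeneticCode <- function(tableId = 5L) {
  aa <- Biostrings::getGeneticCode(as.character(tableId))
  codons <- names(aa)
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  ## sub-family: same amino acid AND same first two bases
  sub <- paste0(substr(sense, 1, 2), ":", aa[sense])
  names(sub) <- sense
  structure(
    list(
      table_id = as.integer(tableId),
      codons = codons,
      aa = aa,
      start_codons = c("ATT", "ATC", "ATA", "ATG", "GTG", "TTG", "CAA", "TCG"),
      stop_codons = stops,
      sense_codons = sense,
      aa_family = aa[sense],
      subfamily = sub
    ),
    class = "GeneticCode"
  )
}

#' Synonymous sub-families of a genetic code
#'
#' @param code a \code{GeneticCode} from \code{\link{mitoGeneticCode}}.
#' @return A list mapping each sub-family label to its member codons.
#' @export
codonSubfamilies <- function(code) {
  split(names(code$subfamily), code$subfamily)
}

#' Amino-acid synonymous families of a genetic code
#'
#' Full synonymous families keyed by amino acid (so Leu and Ser pool
#' their split codon boxes: 6 and 8 codons under table 5). This is the
#' synonymy used for RSCU; ENC uses \code{\link{codonSubfamilies}}.
#'
#' @param code a \code{GeneticCode}.
#' @return A list mapping one-letter amino acids to member codons.
#' @export
codonFamilies <- function(code) {
  split(names(code$aa_family), code$aa_family)
}

#' @export
print.GeneticCode <- function(x, ...) {
  sizes <- lengths(codonSubfamilies(x))
  cat("GeneticCode: NCBI translation table", x$table_id, "\n",
      length(x$sense_codons), "sense codons; stops:",
      paste(x$stop_codons, collapse = ", "), "\n",
      sum(sizes == 2), "two-fold and", sum(sizes == 4),
      "four-fold synonymous sub-families\n")
  invisible(x)
}
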