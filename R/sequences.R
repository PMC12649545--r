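#' Reading-strand sequence of a feature
#'
#' Extracts the sense (reading-strand) sequence of one feature:
#' deposited-strand bases over the feature's span, read across the
#' circular origin when the feature wraps it, and reverse-complemented
#' when the feature lies on the minus strand.
#'
#' @param genome a \code{Mitogenome}.
#' @param feature a feature-table row index, a canonical gene name, or a
#'   one-row data.frame from \code{features(genome)}.
#' @return A character string over A/C/G/T/N.
#' @examples
#' g <- Mitogenome("toy", sequence = "ACGTACGT",
#'   features = data.frame(name = "x", kind = "other", strand = "-",
#'                         start = 2, end = 4, anticodon = NA))
#' featureSequence(g, 1)  # "ACG", reverse complement of CGT
#' @export
featureSequence <- function(genome, feature) {
  ft <- .resolveFeature(genome, feature)
  L <- genomeLength(genome)
  if (ft$end > L && !isCircular(genome))
    stop("feature '", ft$name, "' wraps the origin of a non-circular record")
  s <- .spanSequence(genome, ft$start, ft$end)
  if (ft$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.resolveFeature <- function(genome, feature) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    return(feature)
  }
  ft <- features(genome)
  if (is.character(feature)) {
    i <- which(ft$name == feature)
    if (!length(i)) stop("no feature named '", feature, "'")
    return(ft[i[1L], , drop = FALSE])
  }
  ft[feature, , drop = FALSE]
}

## deposited-strand bases start..end, unwrapped coordinates (end may
## exceed the genome length on a circular molecule)
.spanSequence <- function(genome, start, end) {
  L <- genomeLength(genome)
  seq <- genomeSequence(genome)
  if (end <= L)
    return(as.character(Biostrings::subseq(seq, start, end)))
  paste0(as.character(Biostrings::subseq(seq, start, L)),
         as.character(Biostrings::subseq(seq, 1L, end - L)))
}

#' Reading-strand sequences of all protein-coding genes
#'
#' @param genome a \code{Mitogenome}.
#' @return Named character vector of CDS strings, in genome order.
#' @export
pcgSequences <- function(genome) {
  ft <- featuresOfKind(genome, "PCG")
  if (!nrow(ft)) return(setNames(character(), character()))
  out <- vapply(seq_len(nrow(ft)), function(i)
    featureSequence(genome, ft[i, , drop = FALSE]), character(1))
  names(out) <- ft$name
  out
}

#' Concatenated protein-coding genes
#'
#' Concatenates the reading-strand CDS sequences in the fixed canonical
#' order (\code{PCG_CONCAT_ORDER}); genes absent from the record are
#' skipped with a warning so partially annotated records still yield a
#' usable concatenation.
#'
#' @param genome a \code{Mitogenome}.
#' @param order character vector of gene names; default the canonical
#'   13-gene order.
#' @return A single character string; its \code{nchar} is the combined
#'   PCG length.
#' @export
concatPCGs <- function(genome, order = PCG_CONCAT_ORDER) {
  seqs <- pcgSequences(genome)
  missing <- setdiff(order, names(seqs))
  if (length(missing))
    warning(genomeId(genome), ": missing PCGs skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  paste(seqs[intersect(order, names(seqs))], collapse = "")
}

#' Translate a CDS under the package genetic code
#'
#' Trims the sequence to complete codons, translates under the given
#' code (invertebrate mitochondrial by default), and drops a trailing
#' stop if present. Codons containing N translate to X.
#'
#' @param cds reading-strand CDS string.
#' @param code a \code{GeneticCode}.
#' @return Amino-acid string.
#' @export
translateCDS <- function(cds, code = mitoGeneticCode()) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(code$aa[codons])
  aa[is.na(aa)] <- "X"
  if (aa[n] == "*") aa <- aa[-n]
  aa[aa == "*"] <- "X"   # internal stops should not occur; mask defensively
  paste(aa, collapse = "")
}
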