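#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importClassesFrom Biostrings DNAString
#' @importFrom stats setNames
NULL

#' Mitogenome: an annotated (usually circular) mitochondrial DNA record
#'
#' The central container of the package: one deposited-strand DNA
#' sequence plus an ordered feature table. Features carry canonical gene
#' symbols (the 13 protein-coding genes ND1-ND6, ND4L, COI-COIII, ATP6,
#' ATP8, CYTB; the 22 tRNAs \code{trnX} with the Leu/Ser isotypes
#' disambiguated as trnL1/trnL2/trnS1/trnS2; rrnL; rrnS; the control
#' region CR), a kind in \{PCG, tRNA, rRNA, CR, other\}, a strand, and
#' 1-based inclusive coordinates on the deposited strand. A feature
#' wrapping the circular origin is stored unwrapped, with \code{end}
#' greater than the genome length.
#'
#' @slot id accession-style identifier.
#' @slot organism free-text organism name.
#' @slot circular logical; whether the molecule is closed circular.
#' @slot sequence a \code{DNAString} over A/C/G/T/N (deposited strand).
#' @slot features a \code{data.frame} with columns \code{name},
#'   \code{kind}, \code{strand} ("+"/"-"), \code{start}, \code{end}
#'   (1-based inclusive; \code{end > length} encodes an origin wrap),
#'   \code{anticodon} (3-mer or \code{NA}).
#'
#' @export
setClass("Mitogenome",
  representation(
    id = "character",
    organism = "character",
    circular = "logical",
    sequence = "DNAString",
    features = "data.frame"
  )
)

FEATURE_COLS <- c("name", "kind", "strand", "start", "end", "anticodon")
FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "CR", "other")

setValidity("Mitogenome", function(object) {
  msg <- character()
  ft <- object@features
  L <- length(object@sequence)
  if (!all(FEATURE_COLS %in% names(ft)))
    msg <- c(msg, paste("features must have columns:",
                        paste(FEATURE_COLS, collapse = ", ")))
  else if (nrow(ft)) {
    if (!all(ft$kind %in% FEATURE_KINDS))
      msg <- c(msg, "feature kind must be one of PCG/tRNA/rRNA/CR/other")
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
    if (any(ft$start < 1L) || any(ft$end < ft$start))
      msg <- c(msg, "feature coordinates must satisfy 1 <= start <= end")
    if (any(ft$start > L))
      msg <- c(msg, "feature start beyond sequence length")
    if (any(ft$end > L) && !object@circular)
      msg <- c(msg, "origin-wrapping feature on a non-circular record")
    if (any(ft$end - ft$start + 1L > L))
      msg <- c(msg, "feature longer than the genome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Mitogenome
#'
#' @param id,organism,circular,sequence,features see the class slots;
#'   \code{sequence} may be a plain character string.
#' @return A validated \code{Mitogenome}.
#' @examples
#' g <- Mitogenome("toy", sequence = "ATGAAATAA",
#'                 features = data.frame(name = "ND2", kind = "PCG",
#'                                       strand = "+", start = 1, end = 9,
#'                                       anticodon = NA))
#' genomeLength(g)
#' @export
Mitogenome <- function(id, organism = NA_character_, circular = TRUE,
                       sequence, features = emptyFeatureTable()) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  features <- as.data.frame(features)
  if (!"anticodon" %in% names(features) && nrow(features))
    features$anticodon <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  rownames(features) <- NULL
  new("Mitogenome", id = as.character(id), organism = as.character(organism),
      circular = isTRUE(circular), sequence = sequence, features = features)
}

#' @export
emptyFeatureTable <- function() {
  data.frame(name = character(), kind = character(), strand = character(),
             start = integer(), end = integer(), anticodon = character(),
             stringsAsFactors = FALSE)
}

#' @describeIn Mitogenome accession of the record
#' @param x,object a \code{Mitogenome}
#' @export
genomeId <- function(x) x@id

#' @describeIn Mitogenome organism name
#' @export
organism <- function(x) x@organism

#' @describeIn Mitogenome genome length in bp
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn Mitogenome deposited-strand sequence as a DNAString
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn Mitogenome is the molecule circular?
#' @export
isCircular <- function(x) x@circular

#' @describeIn Mitogenome the feature table (data.frame)
#' @export
features <- function(x) x@features

#' @describeIn Mitogenome number of annotated features
#' @export
setMethod("length", "Mitogenome", function(x) nrow(x@features))

setMethod("show", "Mitogenome", function(object) {
  ft <- object@features
  cat("Mitogenome", object@id,
      if (!is.na(object@organism)) paste0("(", object@organism, ")"), "\n")
  cat(" ", length(object@sequence), "bp,",
      if (object@circular) "circular" else "linear", "\n")
  cat(" ", nrow(ft), "features:",
      sum(ft$kind == "PCG"), "PCG,",
      sum(ft$kind == "tRNA"), "tRNA,",
      sum(ft$kind == "rRNA"), "rRNA,",
      sum(ft$kind == "CR"), "CR,",
      sum(ft$kind == "other"), "other\n")
})

#' Features of a given kind
#'
#' @param x a \code{Mitogenome}; @param kind one of PCG/tRNA/rRNA/CR/other.
#' @return The feature-table rows of that kind, in genome order.
#' @export
featuresOfKind <- function(x, kind) {
  ft <- x@features
  ft[ft$kind %in% kind, , drop = FALSE]
}
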