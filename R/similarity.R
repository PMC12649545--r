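#' Global-alignment percent identity of two sequences
#'
#' Needleman-Wunsch global alignment via
#' \code{Biostrings::pairwiseAlignment}: nucleotide mode scores match
#' +1 / mismatch -1 with affine gaps (open 2, extend 0.5); protein mode
#' uses BLOSUM62 with gap open 11 / extend 1, on invertebrate-
#' mitochondrial translations. Identity is the fraction of alignment
#' columns whose two characters are identical (gap columns count
#' against identity).
#'
#' @param a,b sequences (character). In protein mode pass amino-acid
#'   strings, e.g. from \code{\link{translateCDS}}.
#' @param mode "nucleotide" or "protein".
#' @return Identity fraction in [0, 1], with attribute \code{score}
#'   (the alignment score).
#' @examples
#' pairwiseIdentity("AAAA", "AATA")  # 0.75
#' @export
pairwiseIdentity <- function(a, b, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  stopifnot(nzchar(a), nzchar(b))
  ## canonical pair order: the scoring is symmetric but optimal
  ## alignments can tie with different column counts, so fixing the
  ## orientation makes identity(a, b) == identity(b, a) exactly
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  if (mode == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 0.5)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  structure(sum(pa == pb & pa != "-") / length(pa),
            score = Biostrings::score(aln))
}

#' Rank a panel of genomes by PCG similarity to a reference
#'
#' For each subject genome, every protein-coding gene shared with the
#' reference (paired by canonical name, not homology search) is
#' globally aligned and its identity recorded; the genome identity is
#' the reference-gene-length-weighted mean, and subjects are ranked by
#' it in descending order. A subject missing a gene has that gene
#' skipped and its weight renormalized (flagged in \code{missing}).
#'
#' @param reference a \code{Mitogenome}.
#' @param panel list of \code{Mitogenome} (may include the reference).
#' @param mode "nucleotide" or "protein" (translations under table 5).
#' @param code a \code{GeneticCode} (protein mode).
#' @return data.frame, one row per subject in rank order: reference,
#'   subject, rank, genome_identity, mode, missing, plus one column per
#'   reference PCG with the per-gene identity.
#' @export
rankAgainstReference <- function(reference, panel,
                                 mode = c("nucleotide", "protein"),
                                 code = mitoGeneticCode()) {
  mode <- match.arg(mode)
  ref_seqs <- pcgSequences(reference)
  if (!length(ref_seqs)) stop("reference has no protein-coding genes")
  if (mode == "protein")
    ref_cmp <- vapply(ref_seqs, translateCDS, character(1), code = code)
  else ref_cmp <- ref_seqs
  w <- nchar(ref_seqs)
  rows <- lapply(panel, function(subj) {
    subj_seqs <- pcgSequences(subj)
    shared <- intersect(names(ref_seqs), names(subj_seqs))
    miss <- setdiff(names(ref_seqs), shared)
    if (length(miss))
      warning(genomeId(subj), ": missing gene(s) skipped: ",
              paste(miss, collapse = ", "), call. = FALSE)
    ids <- setNames(rep(NA_real_, length(ref_seqs)), names(ref_seqs))
    for (g in shared) {
      sb <- if (mode == "protein") translateCDS(subj_seqs[[g]], code)
            else subj_seqs[[g]]
      ids[g] <- as.numeric(pairwiseIdentity(ref_cmp[[g]], sb, mode))
    }
    gid <- sum(w[shared] * ids[shared]) / sum(w[shared])
    c(list(reference = genomeId(reference), subject = genomeId(subj),
           genome_identity = gid, mode = mode,
           missing = paste(miss, collapse = ",")),
      as.list(ids))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  out <- out[order(-out$genome_identity), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("reference", "subject", "rank", "genome_identity", "mode",
          "missing", names(ref_seqs))]
}
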