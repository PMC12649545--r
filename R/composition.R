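#' Base counts, AT content and strand skews of a sequence
#'
#' Counts A/C/G/T (ambiguity characters are part of the component's
#' length but excluded from every denominator) and derives
#' \deqn{AT\textrm{-}skew = (A - T)/(A + T), \qquad
#'       GC\textrm{-}skew = (G - C)/(G + C),}
#' the signed measures of strand compositional asymmetry, plus
#' AT content \eqn{(A + T)/(A + C + G + T)}. A skew whose denominator
#' is zero is reported as \code{NA}, never as 0.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param component optional label carried into the result.
#' @return A one-row data.frame: component, length, n_A, n_C, n_G,
#'   n_T, at_content, at_skew, gc_skew.
#' @examples
#' baseStats("AAAT")$at_skew   # (3-1)/(3+1) = 0.5
#' @export
baseStats <- function(seq, component = NA_character_) {
  stopifnot(nchar(seq) > 0)
  counts <- .baseCounts(seq)
  a <- counts[["A"]]; c_ <- counts[["C"]]
  g <- counts[["G"]]; t <- counts[["T"]]
  tot <- a + c_ + g + t
  if (tot == 0) stop("sequence contains no unambiguous bases")
  data.frame(
    component = component, length = nchar(seq),
    n_A = a, n_C = c_, n_G = g, n_T = t,
    at_content = (a + t) / tot,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
    stringsAsFactors = FALSE
  )
}

.baseCounts <- function(seq) {
  tab <- table(strsplit(toupper(seq), "")[[1]])
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (b in names(out)) if (b %in% names(tab)) out[b] <- tab[[b]]
  out
}

#' Split concatenated coding sequence into codon-position streams
#'
#' Splits each gene at its own reading frame (every gene starts at its
#' position 1) and concatenates the per-position streams across genes;
#' a trailing incomplete codon contributes only the positions it
#' possesses, so an incomplete T-- stop still counts toward position 1.
#'
#' @param cds_list character vector of reading-strand gene sequences.
#' @return List of three strings: positions 1, 2, 3.
#' @examples
#' codonPositionSplit("ATGAAA")  # list("AA", "TA", "GA")
#' @export
codonPositionSplit <- function(cds_list) {
  streams <- lapply(1:3, function(p) {
    vapply(cds_list, function(s) {
      n <- nchar(s)
      idx <- seq(p, n, by = 3L)
      if (p > n) "" else paste(substring(s, idx, idx), collapse = "")
    }, character(1))
  })
  lapply(streams, paste, collapse = "")
}

#' Per-component composition profile of one genome
#'
#' One \code{\link{baseStats}} row for the whole genome (deposited
#' strand), the concatenated protein-coding genes and their three codon
#' positions (PCG1/PCG2/PCG3), the concatenated tRNAs and rRNAs, the
#' control region, and every individual gene (reading strand).
#' Concatenated components pool counts; they are not averages of
#' per-gene fractions. Missing components are omitted with a warning.
#'
#' @param genome a \code{Mitogenome}.
#' @return data.frame with a genome_id column plus the
#'   \code{baseStats} columns.
#' @export
componentProfile <- function(genome) {
  rows <- list(baseStats(as.character(genomeSequence(genome)), "whole"))
  pcg <- pcgSequences(genome)
  if (length(pcg)) {
    ord <- intersect(PCG_CONCAT_ORDER, names(pcg))
    rows <- c(rows, list(baseStats(paste(pcg[ord], collapse = ""), "PCG")))
    pos <- codonPositionSplit(unname(pcg[ord]))
    for (p in 1:3)
      rows <- c(rows, list(baseStats(pos[[p]], paste0("PCG", p))))
  } else warning(genomeId(genome), ": no PCGs annotated", call. = FALSE)
  for (comp in c("tRNA", "rRNA")) {
    ft <- featuresOfKind(genome, comp)
    if (nrow(ft)) {
      s <- paste(vapply(seq_len(nrow(ft)), function(i)
        featureSequence(genome, ft[i, , drop = FALSE]), character(1)),
        collapse = "")
      rows <- c(rows, list(baseStats(s, comp)))
    } else warning(genomeId(genome), ": no ", comp, " features",
                   call. = FALSE)
  }
  cr <- featuresOfKind(genome, "CR")
  if (nrow(cr)) {
    rows <- c(rows, list(
      baseStats(featureSequence(genome, cr[1, , drop = FALSE]), "CR")))
  } else warning(genomeId(genome), ": no control region", call. = FALSE)
  genes <- featuresOfKind(genome, c("PCG", "tRNA", "rRNA"))
  for (i in seq_len(nrow(genes)))
    rows <- c(rows, list(
      baseStats(featureSequence(genome, genes[i, , drop = FALSE]),
                genes$name[i])))
  out <- do.call(rbind, rows)
  cbind(genome_id = genomeId(genome), out, stringsAsFactors = FALSE)
}

#' Panel summary of composition statistics
#'
#' Per-component mean, standard deviation, minimum and maximum (with
#' the genome attaining each extreme identified) of AT content, AT-skew
#' and GC-skew across a panel of genomes: the data behind
#' genome-size/AT scatter and per-component AT bar comparisons.
#'
#' @param genomes list of \code{Mitogenome}.
#' @param profiles optional pre-computed list of
#'   \code{\link{componentProfile}} tables (to avoid recomputation).
#' @return data.frame: component, metric, mean, sd, min, min_genome,
#'   max, max_genome, n.
#' @export
panelSummary <- function(genomes, profiles = NULL) {
  if (is.null(profiles))
    profiles <- lapply(genomes, function(g)
      suppressWarnings(componentProfile(g)))
  all <- do.call(rbind, profiles)
  metrics <- c("at_content", "at_skew", "gc_skew", "length")
  comps <- unique(all$component)
  out <- list()
  for (comp in comps) {
    sub <- all[all$component == comp, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      ok <- !is.na(v)
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        component = comp, metric = m,
        mean = mean(v[ok]), sd = if (sum(ok) > 1) stats::sd(v[ok]) else 0,
        min = min(v[ok]), min_genome = sub$genome_id[ok][which.min(v[ok])],
        max = max(v[ok]), max_genome = sub$genome_id[ok][which.max(v[ok])],
        n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a composition TSV
#'
#' Columns: genome_id, component, length, A, C, G, T, AT_pct, AT_skew,
#' GC_skew. Percentages are rounded to 1 decimal and skews to 3
#' decimals in the display columns; full-precision values are kept in
#' at_content/at_skew/gc_skew.
#'
#' @param profiles a \code{componentProfile} table or rbind of several.
#' @param path output file.
#' @export
writeCompositionTable <- function(profiles, path = NULL) {
  tab <- data.frame(
    genome_id = profiles$genome_id, component = profiles$component,
    length = profiles$length,
    A = profiles$n_A, C = profiles$n_C, G = profiles$n_G, T = profiles$n_T,
    AT_pct = round(100 * profiles$at_content, 1),
    AT_skew = round(profiles$at_skew, 3),
    GC_skew = round(profiles$gc_skew, 3),
    at_content = profiles$at_content, at_skew = profiles$at_skew,
    gc_skew = profiles$gc_skew, stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
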