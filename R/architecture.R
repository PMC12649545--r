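#' The ancestral insect mitochondrial gene order
#'
#' The plesiomorphic arrangement of the 37 genes plus control region
#' shared by most insects, anchored at trnI; minus-strand genes are
#' marked in the strand vector.
#'
#' @return data.frame: name, strand.
#' @export
ancestralInsectOrder <- function() {
  spec <- c("trnI", "trnQ-", "trnM", "ND2", "trnW", "trnC-", "trnY-",
            "COI", "trnL2", "COII", "trnK", "trnD", "ATP8", "ATP6",
            "COIII", "trnG", "ND3", "trnA", "trnR", "trnN", "trnS1",
            "trnE", "trnF-", "ND5-", "trnH-", "ND4-", "ND4L-", "trnT",
            "trnP-", "ND6", "CYTB", "trnS2", "ND1-", "trnL1-", "rrnL-",
            "trnV-", "rrnS-", "CR")
  data.frame(name = sub("-$", "", spec),
             strand = ifelse(grepl("-$", spec), "-", "+"),
             stringsAsFactors = FALSE)
}

## features sorted by normalized start position (genome order)
.orderedFeatures <- function(genome, kinds = c("PCG", "tRNA", "rRNA", "CR")) {
  ft <- featuresOfKind(genome, kinds)
  ft[order(ft$start, ft$end), , drop = FALSE]
}

#' Gene order of a genome, compared with the ancestral arrangement
#'
#' Sorts genes by start position, rotates the circular order to anchor
#' at trnI, and compares (name, strand) pairs against the ancestral
#' insect arrangement. Duplicated gene names are reported and the
#' comparison proceeds on first copies.
#'
#' @param genome a \code{Mitogenome}.
#' @return List: \code{order} (data.frame name/strand/start/end in
#'   rotated genome order), \code{ancestral_match} (logical),
#'   \code{mismatches} (data.frame position/expected/observed),
#'   \code{duplicated} (character).
#' @export
geneOrder <- function(genome) {
  ft <- .orderedFeatures(genome)
  dup <- unique(ft$name[duplicated(ft$name)])
  if (length(dup)) {
    warning(genomeId(genome), ": duplicated gene name(s): ",
            paste(dup, collapse = ", "), call. = FALSE)
    ft <- ft[!duplicated(ft$name), , drop = FALSE]
  }
  anchor <- which(ft$name == "trnI")
  if (length(anchor))
    ft <- ft[c(anchor[1]:nrow(ft),
               if (anchor[1] > 1) 1:(anchor[1] - 1)), , drop = FALSE]
  rownames(ft) <- NULL
  anc <- ancestralInsectOrder()
  n <- max(nrow(ft), nrow(anc))
  obs <- paste(ft$name, ft$strand)[seq_len(n)]
  exp <- paste(anc$name, anc$strand)[seq_len(n)]
  bad <- which(is.na(obs) | is.na(exp) | obs != exp)
  mism <- data.frame(position = bad,
                     expected = exp[bad], observed = obs[bad],
                     stringsAsFactors = FALSE)
  list(order = ft[, c("name", "strand", "start", "end")],
       ancestral_match = nrow(mism) == 0L && nrow(ft) == nrow(anc),
       mismatches = mism, duplicated = dup)
}

#' Overlaps and intergenic spacers of a circular genome
#'
#' Walks consecutive features in genome order (circularly, the control
#' region included as a junction partner) and classifies each junction:
#' overlap length \code{max(0, prev_end - next_start + 1)} or spacer
#' length \code{max(0, next_start - prev_end - 1)} in 1-based inclusive
#' terms; a junction with both zero is abutting. Junctions whose
#' downstream or upstream partner is the control region are reported
#' but excluded from the spacer inventory (the CR is not an intergenic
#' spacer). A feature nested inside its predecessor is reported
#' separately and excluded from the pairwise inventory.
#'
#' @param genome a \code{Mitogenome} (circular, >= 2 features).
#' @return List: \code{junctions} (data.frame upstream/downstream/
#'   overlap/spacer/cr_junction), \code{overlaps}, \code{spacers}
#'   (subset data.frames), \code{nested} (data.frame), and summary
#'   counts \code{n_overlaps}, \code{overlap_total}, \code{n_spacers},
#'   \code{spacer_total}.
#' @export
junctions <- function(genome) {
  ft <- .orderedFeatures(genome)
  stopifnot(nrow(ft) >= 2)
  L <- genomeLength(genome)
  n <- nrow(ft)
  ## drop features nested inside another feature's span
  nested_idx <- integer()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && ft$start[j] <= ft$start[i] && ft$end[i] <= ft$end[j]) {
        nested_idx <- c(nested_idx, i); break
      }
    }
  }
  nested <- ft[nested_idx, , drop = FALSE]
  if (length(nested_idx)) ft <- ft[-nested_idx, , drop = FALSE]
  n <- nrow(ft)
  up <- seq_len(n)
  down <- c(seq_len(n)[-1], 1L)
  overlap <- integer(n); spacer <- integer(n)
  for (k in seq_len(n)) {
    pe <- ft$end[up[k]]
    ns <- ft$start[down[k]]
    if (down[k] == 1L && isCircular(genome)) ns <- ns + L  # across origin
    overlap[k] <- max(0L, pe - ns + 1L)
    spacer[k] <- max(0L, ns - pe - 1L)
  }
  jt <- data.frame(upstream = ft$name[up], downstream = ft$name[down],
                   overlap = overlap, spacer = spacer,
                   cr_junction = ft$kind[up] == "CR" |
                                 ft$kind[down] == "CR",
                   stringsAsFactors = FALSE)
  if (!isCircular(genome)) jt <- jt[-n, , drop = FALSE]
  ov <- jt[jt$overlap > 0, , drop = FALSE]
  sp <- jt[jt$spacer > 0 & !jt$cr_junction, , drop = FALSE]
  list(junctions = jt, overlaps = ov, spacers = sp, nested = nested,
       n_overlaps = nrow(ov), overlap_total = sum(ov$overlap),
       n_spacers = nrow(sp), spacer_total = sum(sp$spacer))
}

START_CODON_CLASSES <- c("ATN", "GTG", "TTG", "CAA", "TCG")

#' Start/stop codon classification of protein-coding genes
#'
#' The start is the first three bases of the reading-strand CDS,
#' classified as ATN, GTG, TTG, CAA, TCG or other. The stop is the
#' remainder after the last complete sense codon: a final TAA/TAG is a
#' complete stop; a CDS of length 3k+1 ending in T is the incomplete
#' "T" stop (completed to UAA by polyadenylation); 3k+2 ending in TA is
#' the incomplete "TA" stop; anything else is flagged.
#'
#' @param genome a \code{Mitogenome}.
#' @param code a \code{GeneticCode}.
#' @return data.frame: gene, start_codon, start_class, stop_codon,
#'   stop_completeness (complete / T / TA / other).
#' @export
boundaryCodons <- function(genome, code = mitoGeneticCode()) {
  ft <- featuresOfKind(genome, "PCG")
  stopifnot(nrow(ft) > 0)
  rows <- lapply(seq_len(nrow(ft)), function(i) {
    cds <- featureSequence(genome, ft[i, , drop = FALSE])
    if (nchar(cds) < 6)
      stop("CDS of ", ft$name[i], " shorter than 6 bases")
    start <- substr(cds, 1, 3)
    start_class <-
      if (substr(start, 1, 2) == "AT") "ATN"
      else if (start %in% START_CODON_CLASSES) start
      else "other"
    r <- nchar(cds) %% 3L
    tail1 <- substr(cds, nchar(cds), nchar(cds))
    tail2 <- substr(cds, nchar(cds) - 1L, nchar(cds))
    last3 <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (r == 0L && last3 %in% code$stop_codons) {
      stopc <- last3; compl <- "complete"
    } else if (r == 1L && tail1 == "T") {
      stopc <- "T"; compl <- "T"
    } else if (r == 2L && tail2 == "TA") {
      stopc <- "TA"; compl <- "TA"
    } else {
      stopc <- if (r == 0L) last3 else if (r == 1L) tail1 else tail2
      compl <- "other"
      warning(genomeId(genome), ": ", ft$name[i],
              " has no recognizable stop codon (", stopc, ")",
              call. = FALSE)
    }
    data.frame(gene = ft$name[i], start_codon = start,
               start_class = start_class, stop_codon = stopc,
               stop_completeness = compl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full architecture report for one genome
#'
#' Gene order against the ancestral arrangement, the overlap/spacer
#' inventory, the per-PCG boundary codons, and the circular
#' length-accounting identity
#' \deqn{\sum \textrm{gene lengths} - \sum \textrm{overlaps} +
#'       \sum \textrm{spacers} + \textrm{CR length} =
#'       \textrm{genome length},}
#' which holds exactly for a fully annotated circular genome.
#'
#' @param genome a \code{Mitogenome}.
#' @param code a \code{GeneticCode}.
#' @return List of class \code{ArchitectureReport}: order, junctions,
#'   boundary_codons, and an \code{accounting} list (gene_total,
#'   overlap_total, spacer_total, cr_length, cr_gap_total,
#'   genome_length, identity_holds).
#' @export
architectureReport <- function(genome, code = mitoGeneticCode()) {
  ord <- geneOrder(genome)
  jn <- junctions(genome)
  bc <- boundaryCodons(genome, code)
  genes <- featuresOfKind(genome, c("PCG", "tRNA", "rRNA"))
  cr <- featuresOfKind(genome, "CR")
  gene_total <- sum(genes$end - genes$start + 1L)
  cr_length <- if (nrow(cr)) sum(cr$end - cr$start + 1L) else 0L
  cr_gaps <- jn$junctions$spacer[jn$junctions$cr_junction]
  lhs <- gene_total - jn$overlap_total + jn$spacer_total + cr_length +
    sum(cr_gaps)
  structure(list(
    order = ord, junctions = jn, boundary_codons = bc,
    accounting = list(gene_total = gene_total,
                      overlap_total = jn$overlap_total,
                      spacer_total = jn$spacer_total,
                      cr_length = cr_length,
                      cr_gap_total = sum(cr_gaps),
                      genome_length = genomeLength(genome),
                      identity_holds = lhs == genomeLength(genome))
  ), class = "ArchitectureReport")
}

#' @export
print.ArchitectureReport <- function(x, ...) {
  a <- x$accounting
  cat("ArchitectureReport:",
      nrow(x$order$order), "genes;",
      if (x$order$ancestral_match) "ancestral order"
      else paste0(nrow(x$order$mismatches), " order mismatches"), "\n ",
      x$junctions$n_overlaps, "overlaps (", x$junctions$overlap_total,
      "bp);", x$junctions$n_spacers, "spacers (",
      x$junctions$spacer_total, "bp); CR", a$cr_length, "bp\n ",
      "length identity:", if (a$identity_holds) "holds" else "violated",
      "\n")
  invisible(x)
}
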