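## Synthetic annotated mitogenomes with exact truth records.
##
## The generator lays the 37 genes + control region out in the
## ancestral insect order, builds protein-coding genes codon by codon
## from position-specific base weights (sense codons only, planned
## start and stop codons, incomplete T--/TA stops included), draws
## tRNA/rRNA/control-region/spacer sequences i.i.d. at the genome AT
## target, and assembles the deposited strand with the planned
## overlaps. The two protein-protein overlaps (ATP8|ATP6 and
## ND4|ND4L, 7 bp each) are made sequence-consistent by pinning the
## junction codons of both partners so that the shared bases read as
## sense codons in both frames.

STD_ANTICODONS <- c(
  trnI = "GAT", trnQ = "TTG", trnM = "CAT", trnW = "TCA", trnC = "GCA",
  trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
  trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
  trnL1 = "TAG", trnV = "TAC")

DEFAULT_PCG_LENGTHS <- c(
  ND2 = 1023, COI = 1536, COII = 688, ATP8 = 160, ATP6 = 678,
  COIII = 786, ND3 = 357, ND5 = 1718, ND4 = 1339, ND4L = 290,
  ND6 = 525, CYTB = 1135, ND1 = 946)

DEFAULT_TRNA_LENGTHS <- c(
  trnI = 69, trnQ = 68, trnM = 68, trnW = 68, trnC = 66, trnY = 66,
  trnL2 = 66, trnK = 70, trnD = 68, trnG = 65, trnA = 64, trnR = 65,
  trnN = 66, trnS1 = 68, trnE = 66, trnF = 66, trnH = 66, trnT = 65,
  trnP = 66, trnS2 = 68, trnL1 = 64, trnV = 72)

DEFAULT_START_PLAN <- c(
  ND2 = "ATT", COI = "TCG", COII = "ATG", ATP8 = "ATT", ATP6 = "ATG",
  COIII = "ATG", ND3 = "ATT", ND5 = "GTG", ND4 = "ATG", ND4L = "ATA",
  ND6 = "ATT", CYTB = "ATG", ND1 = "TTG")

DEFAULT_OVERLAP_PLAN <- data.frame(
  upstream = c("trnW", "trnY", "ATP8", "trnG", "trnE", "ND4"),
  downstream = c("trnC", "COI", "ATP6", "ND3", "trnF", "ND4L"),
  bp = c(8L, 3L, 7L, 1L, 1L, 7L), stringsAsFactors = FALSE)

DEFAULT_SPACER_PLAN <- data.frame(
  upstream = c("trnI", "trnQ", "trnM", "ND2", "trnC", "COI", "trnL2",
               "COII", "trnK", "trnD", "ATP6", "COIII", "ND3", "trnA",
               "trnR", "trnN", "trnS1", "trnF", "ND5", "trnH"),
  downstream = c("trnQ", "trnM", "ND2", "trnW", "trnY", "trnL2",
                 "COII", "trnK", "trnD", "ATP8", "COIII", "trnG",
                 "trnA", "trnR", "trnN", "trnS1", "trnE", "ND5",
                 "trnH", "ND4"),
  bp = c(27L, 15L, 12L, 10L, 9L, 8L, 7L, 6L, 6L, 5L, 5L, 4L, 4L, 91L,
         3L, 3L, 2L, 2L, 2L, 1L), stringsAsFactors = FALSE)

#' Parameters for the synthetic mitogenome generator
#'
#' Defaults mirror the features of real dacine fruit-fly mitogenomes:
#' 37 genes + control region in the ancestral insect order, ~16.6 kb,
#' protein-coding total 11,181 bp, tRNAs totalling 1470 bp, rRNAs
#' 1334 + 797 bp, CR 1623 bp, genome AT content 0.74, codon bias
#' toward A/T-ending codons, 6 gene overlaps of 1--8 bp (27 bp total,
#' the largest the conserved 8 bp trnW|trnC junction), 20 intergenic
#' spacers totalling 222 bp, and incomplete T--/TA stop codons on the
#' genes whose lengths are not codon multiples.
#'
#' @param seed integer; the single random stream per genome is seeded
#'   with it.
#' @param id,organism record identifiers (labelled synthetic).
#' @param at_content whole-genome AT target in (0,1).
#' @param at_skew,gc_skew deposited-strand composition skew targets for
#'   non-coding sequence.
#' @param third_pos_weights base weights at synonymous third codon
#'   positions (drives codon usage bias); need not be normalized.
#' @param pcg_at_skew,pcg_gc_skew reading-strand skews for codon
#'   positions 1--2.
#' @param rna_at_skew,rna_gc_skew reading-strand skews for tRNA/rRNA.
#' @param pcg_lengths,trna_lengths,rrn_lengths,cr_length lengths in bp;
#'   a PCG length mod 3 of 1 or 2 implies an incomplete T or TA stop.
#' @param start_plan named start codons per PCG.
#' @param overlap_plan,spacer_plan data.frames (upstream, downstream,
#'   bp) over adjacent ancestral-order junctions.
#' @return List of class \code{SimulationParams}.
#' @export
simulationParams <- function(seed = 1L,
                             id = sprintf("SYNMT%03d", seed %% 1000L),
                             organism = "synthetic dacine mitogenome",
                             at_content = 0.74,
                             at_skew = 0.01, gc_skew = -0.17,
                             third_pos_weights = c(A = 0.42, T = 0.38,
                                                   G = 0.12, C = 0.08),
                             pcg_at_skew = -0.05, pcg_gc_skew = 0.05,
                             rna_at_skew = -0.05, rna_gc_skew = 0.15,
                             pcg_lengths = DEFAULT_PCG_LENGTHS,
                             trna_lengths = DEFAULT_TRNA_LENGTHS,
                             rrn_lengths = c(rrnL = 1334L, rrnS = 797L),
                             cr_length = 1623L,
                             start_plan = DEFAULT_START_PLAN,
                             overlap_plan = DEFAULT_OVERLAP_PLAN,
                             spacer_plan = DEFAULT_SPACER_PLAN) {
  stopifnot(at_content > 0, at_content < 1,
            all(pcg_lengths > 0), all(trna_lengths > 0),
            cr_length > 0, all(names(DEFAULT_PCG_LENGTHS) %in%
                                 names(pcg_lengths)))
  storage.mode(pcg_lengths) <- "integer"
  storage.mode(trna_lengths) <- "integer"
  storage.mode(rrn_lengths) <- "integer"
  p <- list(seed = as.integer(seed), id = id, organism = organism,
            at_content = at_content, at_skew = at_skew,
            gc_skew = gc_skew,
            third_pos_weights = third_pos_weights / sum(third_pos_weights),
            pcg_at_skew = pcg_at_skew, pcg_gc_skew = pcg_gc_skew,
            rna_at_skew = rna_at_skew, rna_gc_skew = rna_gc_skew,
            pcg_lengths = pcg_lengths, trna_lengths = trna_lengths,
            rrn_lengths = rrn_lengths, cr_length = as.integer(cr_length),
            start_plan = start_plan, overlap_plan = overlap_plan,
            spacer_plan = spacer_plan)
  class(p) <- "SimulationParams"
  .validateSimulationParams(p)
  p
}

.stopPlanFromLengths <- function(pcg_lengths) {
  r <- pcg_lengths %% 3L
  ifelse(r == 0L, "TAA", ifelse(r == 1L, "T", "TA"))
}

.validateSimulationParams <- function(p) {
  anc <- ancestralInsectOrder()
  junc <- paste(anc$name, c(anc$name[-1], anc$name[1]), sep = "|")
  all_len <- c(p$pcg_lengths, p$trna_lengths, p$rrn_lengths,
               CR = p$cr_length)
  for (plan in list(p$overlap_plan, p$spacer_plan)) {
    key <- paste(plan$upstream, plan$downstream, sep = "|")
    if (!all(key %in% junc))
      stop("plan names a junction not adjacent in the ancestral order: ",
           paste(setdiff(key, junc), collapse = ", "))
  }
  op <- p$overlap_plan
  for (i in seq_len(nrow(op))) {
    if (op$bp[i] >= min(all_len[op$upstream[i]], all_len[op$downstream[i]]))
      stop("overlap ", op$upstream[i], "|", op$downstream[i],
           " longer than a participating gene")
    both_pcg <- op$upstream[i] %in% names(p$pcg_lengths) &&
      op$downstream[i] %in% names(p$pcg_lengths)
    if (both_pcg &&
        !(paste(op$upstream[i], op$downstream[i]) %in%
            c("ATP8 ATP6", "ND4 ND4L") && op$bp[i] == 7L))
      stop("protein-protein overlaps are only supported at ATP8|ATP6 ",
           "and ND4|ND4L with 7 bp (sequence-consistent construction)")
  }
  invisible(TRUE)
}

## base probabilities from an AT target and signed skews
.baseProbs <- function(at, at_skew, gc_skew) {
  c(A = at * (1 + at_skew) / 2, T = at * (1 - at_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2, C = (1 - at) * (1 - gc_skew) / 2)
}

.randSeq <- function(n, probs) {
  if (n <= 0) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

## sense-codon sampling distribution from position weights
.codonProbs <- function(p, code) {
  at3 <- p$third_pos_weights[["A"]] + p$third_pos_weights[["T"]]
  at12 <- (3 * p$at_content - at3) / 2
  at12 <- min(max(at12, 0.05), 0.95)
  w12 <- .baseProbs(at12, p$pcg_at_skew, p$pcg_gc_skew)
  w3 <- p$third_pos_weights
  sense <- code$sense_codons
  pr <- unname(w12[substr(sense, 1, 1)]) *
    unname(w12[substr(sense, 2, 2)]) * unname(w3[substr(sense, 3, 3)])
  names(pr) <- sense
  pr / sum(pr)
}

.sampleCodons <- function(n, codon_probs) {
  if (n <= 0) return(character())
  sample(names(codon_probs), n, replace = TRUE, prob = codon_probs)
}

#' Simulate one annotated circular mitogenome
#'
#' Builds a genome whose order, lengths, strands, overlaps, spacers and
#' boundary codons match the plan in \code{params} exactly, with
#' composition targeted by the AT/skew parameters, and returns it with
#' a truth record holding the planned architecture and the realized
#' per-gene codon counts and per-component base counts. Reproducible:
#' one global random stream seeded from \code{params$seed}.
#'
#' @param params a \code{\link{simulationParams}} object.
#' @return List with elements \code{genome} (a \code{Mitogenome}) and
#'   \code{truth} (list: params echo, layout, overlaps, spacers,
#'   boundary plan, per-gene codon counts, per-component base counts).
#' @export
simulateMitogenome <- function(params = simulationParams()) {
  stopifnot(inherits(params, "SimulationParams"))
  .validateSimulationParams(params)
  set.seed(params$seed)
  code <- mitoGeneticCode()
  anc <- ancestralInsectOrder()
  stop_plan <- .stopPlanFromLengths(params$pcg_lengths)
  cprobs <- .codonProbs(params, code)
  rna_probs <- .baseProbs(params$at_content, params$rna_at_skew,
                          params$rna_gc_skew)
  nc_probs <- .baseProbs(params$at_content, params$at_skew,
                         params$gc_skew)

  glen <- function(nm) {
    if (nm %in% names(params$pcg_lengths)) params$pcg_lengths[[nm]]
    else if (nm %in% names(params$trna_lengths)) params$trna_lengths[[nm]]
    else if (nm %in% names(params$rrn_lengths)) params$rrn_lengths[[nm]]
    else params$cr_length
  }
  okey <- paste(params$overlap_plan$upstream,
                params$overlap_plan$downstream, sep = "|")
  skey <- paste(params$spacer_plan$upstream,
                params$spacer_plan$downstream, sep = "|")

  ## --- layout ---
  n <- nrow(anc)
  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    if (i > 1L) {
      key <- paste(anc$name[i - 1L], anc$name[i], sep = "|")
      ov <- if (key %in% okey)
        params$overlap_plan$bp[match(key, okey)] else 0L
      sp <- if (key %in% skey)
        params$spacer_plan$bp[match(key, skey)] else 0L
      pos <- end[i - 1L] + 1L + sp - ov
    }
    start[i] <- pos
    end[i] <- pos + glen(anc$name[i]) - 1L
    pos <- start[i]
  }
  L <- max(end)

  ## --- reading-strand gene sequences ---
  seqs <- list()
  codon_truth <- list()
  for (i in seq_len(n)) {
    nm <- anc$name[i]
    if (nm %in% names(params$pcg_lengths)) {
      len <- params$pcg_lengths[[nm]]
      stp <- stop_plan[[nm]]
      n_body <- (len - 3L - nchar(stp)) / 3L
      stopifnot(n_body == round(n_body), n_body >= 2)
      body <- .sampleCodons(n_body, cprobs)
      ## junction-consistent pinned codons for the two PCG|PCG overlaps
      if (nm == "ATP8" && "ATP8|ATP6" %in% okey) {
        body[n_body - 1L] <- "ATG"; body[n_body] <- "ATA"
        stopifnot(stp == "T")
      }
      if (nm == "ATP6" && "ATP8|ATP6" %in% okey) {
        body[1L] <- "ATA"; body[2L] <- "TTA"
      }
      if (nm == "ND4" && "ND4|ND4L" %in% okey) {
        body[1L] <- "CAT"; body[2L] <- "ATT"
      }
      if (nm == "ND4L" && "ND4|ND4L" %in% okey) {
        body[n_body - 1L] <- "CAT"; body[n_body] <- "GCA"
        stopifnot(stp == "TA")
      }
      codons <- c(params$start_plan[[nm]], body)
      seqs[[nm]] <- paste0(paste(codons, collapse = ""), stp)
      tt <- table(c(codons, if (nchar(stp) == 3L) stp))
      codon_truth[[nm]] <- tt
    } else if (nm %in% names(params$trna_lengths)) {
      seqs[[nm]] <- .randSeq(params$trna_lengths[[nm]], rna_probs)
    } else if (nm %in% names(params$rrn_lengths)) {
      seqs[[nm]] <- .randSeq(params$rrn_lengths[[nm]], rna_probs)
    } else {
      seqs[[nm]] <- .randSeq(params$cr_length, nc_probs)
    }
    stopifnot(nchar(seqs[[nm]]) == glen(nm))
  }

  ## --- assembly ---
  ## Genes are written in genome order, so at an overlap the downstream
  ## gene's bases win; the junction-pinned codons make that harmless at
  ## the two protein-protein overlaps, and RNA genes have no sequence
  ## constraints. When a protein gene sits upstream of an RNA gene in
  ## the overlap plan, its bases are rewritten afterwards so the coding
  ## sequence (and its stop codon) stays exact.
  deposited <- list()
  genome <- character(L)
  for (i in seq_len(n)) {
    if (i > 1L && start[i] > end[i - 1L] + 1L) {
      gap <- (end[i - 1L] + 1L):(start[i] - 1L)
      genome[gap] <- strsplit(.randSeq(length(gap), nc_probs), "")[[1]]
    }
    s <- seqs[[anc$name[i]]]
    if (anc$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    deposited[[anc$name[i]]] <- s
    genome[start[i]:end[i]] <- strsplit(s, "")[[1]]
  }
  for (k in seq_len(nrow(params$overlap_plan))) {
    upn <- params$overlap_plan$upstream[k]
    dnn <- params$overlap_plan$downstream[k]
    if (upn %in% names(params$pcg_lengths) &&
        !dnn %in% names(params$pcg_lengths)) {
      i <- match(upn, anc$name)
      genome[start[i]:end[i]] <- strsplit(deposited[[upn]], "")[[1]]
    }
  }
  stopifnot(!anyNA(genome), all(nzchar(genome)))
  seq_str <- paste(genome, collapse = "")

  ft <- data.frame(
    name = anc$name,
    kind = ifelse(anc$name %in% names(params$pcg_lengths), "PCG",
           ifelse(anc$name %in% names(params$trna_lengths), "tRNA",
           ifelse(anc$name %in% names(params$rrn_lengths), "rRNA",
                  "CR"))),
    strand = anc$strand, start = start, end = end,
    anticodon = unname(STD_ANTICODONS[anc$name]),
    stringsAsFactors = FALSE)
  g <- Mitogenome(params$id, organism = params$organism, circular = TRUE,
                  sequence = seq_str, features = ft)

  ## realized per-component base counts, tallied directly off the
  ## assembled string (generation-side truth, not the analysis code)
  comp_counts <- .truthBaseCounts(seq_str, ft)

  truth <- list(
    params = params, layout = ft, genome_length = L,
    overlaps = params$overlap_plan, spacers = params$spacer_plan,
    boundary = data.frame(gene = names(params$pcg_lengths),
                          start_codon = unname(
                            params$start_plan[names(params$pcg_lengths)]),
                          stop = unname(stop_plan),
                          stringsAsFactors = FALSE),
    codon_counts = codon_truth,
    base_counts = comp_counts,
    at_target = params$at_content)
  list(genome = g, truth = truth)
}

.truthBaseCounts <- function(seq_str, ft) {
  tally <- function(s) {
    v <- strsplit(s, "")[[1]]
    vapply(c("A", "C", "G", "T"), function(b) sum(v == b), integer(1))
  }
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list(whole = tally(seq_str))
  for (i in seq_len(nrow(ft))) {
    s <- substr(seq_str, ft$start[i], ft$end[i])
    if (ft$strand[i] == "-") s <- rc(s)
    out[[ft$name[i]]] <- tally(s)
  }
  out
}

#' Simulate a panel: one ancestor plus mutated derivatives
#'
#' Derived genomes differ from the ancestor by independent per-site
#' substitutions only (uniform over the three alternative bases), so
#' all gene boundaries are preserved; the truth record carries the
#' realized substitution count per genome.
#'
#' @param params ancestor \code{\link{simulationParams}}.
#' @param rates per-site substitution rate for each derived genome
#'   (each must be < 0.75: beyond that substitutions saturate).
#' @param n total panel size; defaults to \code{length(rates) + 1}
#'   (ancestor first). When larger, rates are recycled.
#' @return List of \code{list(genome, truth)}, the ancestor first;
#'   derived truths add \code{rate} and \code{n_substitutions}.
#' @export
simulatePanel <- function(params = simulationParams(),
                          n = length(rates) + 1L,
                          rates = c(0.01, 0.10)) {
  stopifnot(n >= 1)
  if (any(rates >= 0.75)) stop("substitution rate >= 0.75 rejected ",
                               "(saturation)")
  anc <- simulateMitogenome(params)
  if (n == 1L) return(list(anc))
  rates <- rep_len(rates, n - 1L)
  out <- vector("list", n)
  out[[1L]] <- anc
  base_seq <- strsplit(as.character(genomeSequence(anc$genome)), "")[[1]]
  for (i in seq_len(n - 1L)) {
    set.seed(params$seed + i)
    hit <- which(stats::runif(length(base_seq)) < rates[i])
    seq2 <- base_seq
    for (j in hit)
      seq2[j] <- sample(setdiff(c("A", "C", "G", "T"), base_seq[j]), 1L)
    g2 <- Mitogenome(paste0(params$id, "_r", i),
                     organism = paste(params$organism, "derived"),
                     circular = TRUE,
                     sequence = paste(seq2, collapse = ""),
                     features = features(anc$genome))
    tr <- anc$truth
    tr$rate <- rates[i]
    tr$n_substitutions <- length(hit)
    out[[i + 1L]] <- list(genome = g2, truth = tr)
  }
  out
}

#' Simulate genes with a planted GC12-on-GC3 relationship
#'
#' Generates coding sequences whose designed GC at codon positions 1--2
#' follows \code{intercept + slope * gc3} plus Gaussian noise, with GC3
#' uniform over \code{gc3_range}: the parameter-recovery fixture for
#' the neutrality regression.
#'
#' @param n number of genes; @param slope,intercept the planted linear
#'   relation; @param sigma Gaussian noise sd on the designed GC12;
#' @param n_codons codons per gene; @param gc3_range range of designed
#'   GC3; @param seed RNG seed.
#' @return character vector of CDS strings.
#' @export
simulateNeutralityGenes <- function(n = 200, slope = 0.30,
                                    intercept = 0.1, sigma = 0.01,
                                    n_codons = 300,
                                    gc3_range = c(0.1, 0.9),
                                    seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    gc3 <- stats::runif(1, gc3_range[1], gc3_range[2])
    gc12 <- intercept + slope * gc3 + stats::rnorm(1, 0, sigma)
    gc12 <- min(max(gc12, 0.02), 0.98)
    draw <- function(p_gc, m) {
      gc <- stats::runif(m) < p_gc
      ifelse(gc, sample(c("G", "C"), m, replace = TRUE),
             sample(c("A", "T"), m, replace = TRUE))
    }
    b1 <- draw(gc12, n_codons); b2 <- draw(gc12, n_codons)
    b3 <- draw(gc3, n_codons)
    paste(paste0(b1, b2, b3), collapse = "")
  }, character(1))
}
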