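#' Count codons of a reading-strand CDS
#'
#' Reads complete codons in frame from position 1. Trailing 1--2 bases
#' (an incomplete T--/TA stop) are ignored; codons containing ambiguity
#' characters are skipped and tallied. All codon occurrences, stops
#' included, appear in the returned 64-vector; downstream index
#' functions exclude the stop codons, leaving the 62 sense codons of
#' the invertebrate mitochondrial code. The start codon is counted as
#' its ordinary table translation (no initiator-Met special case).
#'
#' @param cds reading-strand CDS string, length >= 3.
#' @param code a \code{GeneticCode}.
#' @return Named integer vector over the 64 codons (fixed order), with
#'   attributes \code{n_skipped} (codons containing N) and
#'   \code{n_trailing} (0--2 ignored trailing bases).
#' @examples
#' cc <- codonCounts("ATGAAATAA")
#' cc[cc > 0]   # ATG 1, AAA 1, TAA 1
#' @export
codonCounts <- function(cds, code = mitoGeneticCode()) {
  stopifnot(nchar(cds) >= 3)
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  known <- codons %in% code$codons
  counts <- integer(64)
  names(counts) <- code$codons
  tab <- table(codons[known])
  counts[names(tab)] <- as.integer(tab)
  structure(counts,
            n_skipped = sum(!known),
            n_trailing = nchar(cds) - 3L * n)
}

## counts restricted to sense codons (names kept, stops dropped)
.senseCounts <- function(counts, code) counts[code$sense_codons]

#' Relative synonymous codon usage
#'
#' For codon \eqn{c} in amino-acid family \eqn{F}: \eqn{RSCU(c) =
#' n_c |F| / \sum_{c' \in F} n_{c'}}. Synonymy here is by amino acid,
#' so under table 5 Leu spans 6 codons and Ser 8 (the split boxes are
#' pooled, the convention of standard codon-usage software); a family
#' with zero total yields \code{NA} for all its members. Within any
#' used family the RSCU values average 1 and sum to the family size.
#'
#' @param counts 64-vector from \code{\link{codonCounts}}.
#' @param code a \code{GeneticCode}.
#' @return Named numeric vector over the 62 sense codons.
#' @export
rscu <- function(counts, code = mitoGeneticCode()) {
  cnt <- .senseCounts(counts, code)
  fam <- code$aa_family
  fam_tot <- tapply(cnt, fam, sum)
  fam_size <- table(fam)
  tot <- as.numeric(fam_tot[fam])
  size <- as.numeric(fam_size[fam])
  out <- ifelse(tot > 0, as.numeric(cnt) * size / tot, NA_real_)
  names(out) <- names(cnt)
  out
}

#' Amino-acid usage counts and ratios
#'
#' Pools sense-codon counts by encoded amino acid; the ratio is the
#' amino-acid count over total sense codons. This is the data behind
#' per-species amino-acid usage heatmaps.
#'
#' @inheritParams rscu
#' @return data.frame: aa, count, ratio.
#' @export
aaUsage <- function(counts, code = mitoGeneticCode()) {
  cnt <- .senseCounts(counts, code)
  byaa <- tapply(cnt, code$aa_family, sum)
  tot <- sum(cnt)
  data.frame(aa = names(byaa), count = as.integer(byaa),
             ratio = if (tot > 0) as.numeric(byaa) / tot else NA_real_,
             stringsAsFactors = FALSE)
}

#' Third-position base statistics of synonymous codons
#'
#' Base frequencies at the third position of synonymously degenerate
#' codons; under table 5 every amino acid is degenerate, so the
#' restriction removes only the stop codons. \code{gc3s = g3s + c3s}.
#'
#' @inheritParams rscu
#' @return Named numeric vector: a3s, t3s, g3s, c3s, gc3s (all
#'   \code{NA} when there are no synonymous codons).
#' @export
thirdPositionStats <- function(counts, code = mitoGeneticCode()) {
  cnt <- .senseCounts(counts, code)
  tot <- sum(cnt)
  if (tot == 0)
    return(c(a3s = NA_real_, t3s = NA_real_, g3s = NA_real_,
             c3s = NA_real_, gc3s = NA_real_))
  third <- substr(names(cnt), 3, 3)
  freq <- tapply(cnt, factor(third, levels = c("A", "T", "G", "C")),
                 sum) / tot
  freq[is.na(freq)] <- 0
  c(a3s = freq[["A"]], t3s = freq[["T"]], g3s = freq[["G"]],
    c3s = freq[["C"]], gc3s = freq[["G"]] + freq[["C"]])
}

#' GC content by codon position
#'
#' GC fraction at each codon position over complete codons, stop codons
#' excluded (keeping GC3 comparable with GC3s); \code{gc12} is the mean
#' of positions 1 and 2 -- the ordinate of the neutrality plot.
#'
#' @param cds reading-strand CDS string (or a 64-vector of codon
#'   counts).
#' @param code a \code{GeneticCode}.
#' @return Named numeric vector: gc1, gc2, gc3, gc12.
#' @export
gcByPosition <- function(cds, code = mitoGeneticCode()) {
  counts <- if (is.character(cds)) codonCounts(cds, code) else cds
  cnt <- .senseCounts(counts, code)
  tot <- sum(cnt)
  if (tot == 0)
    return(c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
             gc12 = NA_real_))
  gc_at <- function(p) {
    b <- substr(names(cnt), p, p)
    sum(cnt[b %in% c("G", "C")]) / tot
  }
  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2)
}

#' Wright's effective number of codons (Nc)
#'
#' Sub-family homozygosity estimator: for a synonymous sub-family (same
#' amino acid and same first two codon bases) with total count
#' \eqn{n > 1} and codon proportions \eqn{p_i},
#' \deqn{\hat F = (n \sum p_i^2 - 1) / (n - 1).}
#' Class averages \eqn{\bar F_2, \bar F_4} are taken over the 13
#' two-fold and 9 four-fold sub-families of table 5, and
#' \eqn{N_c = 13/\bar F_2 + 9/\bar F_4}, capped at 62 (the number of
#' sense codons). Sub-families with \eqn{n \le 1} or \eqn{\hat F \le 0}
#' are excluded from their class average; a class with no usable
#' sub-family borrows the other class's mean homozygosity (flagged via
#' the \code{imputed} attribute). Nc runs from 22 (one codon per
#' sub-family: maximal bias) to 62 (uniform usage); values at or below
#' 35 are conventionally read as strong codon preference.
#'
#' @inheritParams rscu
#' @return Numeric Nc (attribute \code{imputed}: which class, if any,
#'   borrowed the other's mean), or \code{NA} if neither class has a
#'   usable sub-family.
#' @export
encWright <- function(counts, code = mitoGeneticCode()) {
  cnt <- .senseCounts(counts, code)
  subs <- split(cnt, code$subfamily)
  fhat <- vapply(subs, function(x) {
    n <- sum(x)
    if (n <= 1) return(NA_real_)
    f <- (n * sum((x / n)^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  }, numeric(1))
  size <- vapply(subs, length, integer(1))
  f2 <- fhat[size == 2]; f4 <- fhat[size == 4]
  m2 <- if (any(!is.na(f2))) mean(f2, na.rm = TRUE) else NA_real_
  m4 <- if (any(!is.na(f4))) mean(f4, na.rm = TRUE) else NA_real_
  imputed <- character()
  if (is.na(m2) && is.na(m4)) {
    out <- NA_real_
    return(structure(out, imputed = "none usable"))
  }
  if (is.na(m2)) { m2 <- m4; imputed <- c(imputed, "twofold") }
  if (is.na(m4)) { m4 <- m2; imputed <- c(imputed, "fourfold") }
  nc <- 13 / m2 + 9 / m4
  structure(min(nc, 62), imputed = imputed)
}

#' Expected ENC under mutation alone
#'
#' The closed-form expected curve of the ENC-GC3s plot,
#' \deqn{ENC = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2).}
#' Genes falling on or near this curve are consistent with codon bias
#' shaped by mutation pressure alone; genes well below it suggest
#' selection.
#'
#' @param gc3s numeric in [0, 1] (vectorized).
#' @return Expected Nc.
#' @examples
#' encExpected(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
encExpected <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean GC at codon positions 1 and 2)
#' on GC3. A slope near 1 with high r-squared indicates mutation
#' pressure acting on all positions alike; a slope near 0 indicates
#' selection constraining positions 1--2.
#'
#' @param points data.frame (or matrix) with columns \code{gc3} and
#'   \code{gc12}; at least 3 rows.
#' @return List of class \code{NeutralityFit}: slope, intercept, r2,
#'   n_points, zero_variance flag, and the points used.
#' @export
neutralityFit <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("gc3", "gc12") %in% names(points)),
            nrow(points) >= 3)
  if (stats::var(points$gc3) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r2 = 0, n_points = nrow(points),
                          zero_variance = TRUE, points = points),
                     class = "NeutralityFit"))
  fit <- stats::lm(gc12 ~ gc3, data = points)
  ## r2 computed directly so a perfect toy fit raises no warning
  sst <- sum((points$gc12 - mean(points$gc12))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 0
  flag <- stats::var(points$gc12) == 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = if (flag) 0 else r2,
                 n_points = nrow(points), zero_variance = flag,
                 points = points),
            class = "NeutralityFit")
}

#' @export
print.NeutralityFit <- function(x, ...) {
  cat("Neutrality fit (GC12 ~ GC3):",
      "slope", signif(x$slope, 4),
      "intercept", signif(x$intercept, 4),
      "r2", signif(x$r2, 4), "on", x$n_points, "points\n")
  invisible(x)
}

#' Parity-rule-2 bias coordinates
#'
#' \eqn{x = G3s/(G3s + C3s)}, \eqn{y = A3s/(A3s + T3s)} at synonymous
#' third positions. The point (0.5, 0.5) is the PR2 equilibrium where
#' complementary bases are used equally; the quadrant relative to it
#' summarizes the direction of bias (ties land on a boundary label).
#'
#' @param x a 64-vector of codon counts, or a named vector containing
#'   a3s/t3s/g3s/c3s as returned by \code{\link{thirdPositionStats}}.
#' @param code a \code{GeneticCode}.
#' @return List: x, y, quadrant (I: x>0.5,y>0.5; II: x<0.5,y>0.5;
#'   III: x<0.5,y<0.5; IV: x>0.5,y<0.5; or a boundary/center label).
#' @export
pr2Point <- function(x, code = mitoGeneticCode()) {
  s <- if (all(c("a3s", "t3s", "g3s", "c3s") %in% names(x))) x
       else thirdPositionStats(x, code)
  gx <- if (s[["g3s"]] + s[["c3s"]] > 0)
          s[["g3s"]] / (s[["g3s"]] + s[["c3s"]]) else NA_real_
  ay <- if (s[["a3s"]] + s[["t3s"]] > 0)
          s[["a3s"]] / (s[["a3s"]] + s[["t3s"]]) else NA_real_
  quad <- if (is.na(gx) || is.na(ay)) NA_character_
          else if (gx == 0.5 && ay == 0.5) "center"
          else if (gx == 0.5 || ay == 0.5) "boundary"
          else if (gx > 0.5 && ay > 0.5) "I"
          else if (gx < 0.5 && ay > 0.5) "II"
          else if (gx < 0.5 && ay < 0.5) "III"
          else "IV"
  list(x = gx, y = ay, quadrant = quad)
}

#' Full codon-usage profile for a gene or pooled gene set
#'
#' Bundles every codon-usage-bias index for one scope: a single gene or
#' the pooled 13 protein-coding genes of a species (counts are summed
#' across genes, not averaged).
#'
#' @param cds a CDS string, a character vector of CDS strings (pooled),
#'   or a 64-vector of codon counts.
#' @param scope label for the profile.
#' @param code a \code{GeneticCode}.
#' @return List of class \code{CodonUsageProfile}: scope, codon_counts,
#'   rscu, aa_usage, enc, thirdpos (a3s..gc3s), gc_pos (gc1..gc12),
#'   pr2 (x, y, quadrant).
#' @export
codonUsageProfile <- function(cds, scope = "all-PCGs",
                              code = mitoGeneticCode()) {
  counts <- if (is.numeric(cds)) cds
            else if (length(cds) > 1)
              Reduce(`+`, lapply(cds, codonCounts, code = code))
            else codonCounts(cds, code)
  tp <- thirdPositionStats(counts, code)
  structure(list(
    scope = scope,
    codon_counts = counts,
    rscu = rscu(counts, code),
    aa_usage = aaUsage(counts, code),
    enc = encWright(counts, code),
    thirdpos = tp,
    gc_pos = gcByPosition(counts, code),
    pr2 = pr2Point(tp, code)
  ), class = "CodonUsageProfile")
}

#' @export
print.CodonUsageProfile <- function(x, ...) {
  cat("CodonUsageProfile [", x$scope, "]: ",
      sum(.senseCounts(x$codon_counts, mitoGeneticCode())),
      " sense codons; ENC ", round(as.numeric(x$enc), 2),
      "; GC3s ", round(x$thirdpos[["gc3s"]], 3), "\n", sep = "")
  invisible(x)
}
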