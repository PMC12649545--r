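---
title: "Comparative mitogenome characterization with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome characterization with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

# Scope

Insect mitochondrial genomes are closed circular molecules of roughly
15--17 kb carrying 37 genes — 13 protein-coding genes (PCGs), 22 tRNAs
and 2 rRNAs — plus one non-coding A+T-rich control region (CR).
`mitochar` implements the standard comparative characterization of such
records: per-component nucleotide composition and strand skew, a
codon-usage-bias (CUB) index suite under the invertebrate mitochondrial
genetic code, genome-architecture accounting (gene order, overlaps,
spacers, boundary codons), and reference-anchored pairwise PCG
similarity. A synthetic-genome generator with exact truth records lets
every analysis run and be verified without downloading any sequence.

# Data model and I/O

The central object is the S4 class `Mitogenome`: one deposited-strand
`DNAString` plus an ordered feature table with canonical gene symbols
(`ND1`--`ND6`, `ND4L`, `COI`--`COIII`, `ATP6`, `ATP8`, `CYTB`; `trnX`
with the Leu/Ser isotypes split as `trnL1`/`trnL2`/`trnS1`/`trnS2`;
`rrnL`, `rrnS`, `CR`), kinds, strands and 1-based inclusive
coordinates. A feature crossing the circular origin is stored
unwrapped with `end` beyond the genome length, which keeps all overlap
and spacer arithmetic in one coordinate convention with no conversion
at the GenBank boundary (GenBank is also 1-based inclusive).

`readGenBank()` builds features from CDS/tRNA/rRNA/D-loop entries,
canonicalizing the many deposited synonyms (`COX1`, `CO1`, `cob`,
`16S rRNA`, `D-loop`, ...) and resolving Leu/Ser tRNA isotypes by
anticodon when one is annotated, else by a 1/2 suffix or an anticodon
embedded in the label. When a fully annotated record leaves the CR
implicit, the largest unannotated gap is assigned to it — in the
ancestral arrangement that gap sits between `rrnS` and `trnI`, which is
where the CR lies. Ambiguity characters count toward component lengths
but never enter a composition denominator.

# Composition and skew

For each component (whole genome on the deposited strand; pooled PCGs
and their three codon-position streams PCG1/PCG2/PCG3; pooled tRNAs;
pooled rRNAs; CR; each gene on its reading strand):

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C}$$

A skew whose denominator is zero is reported missing, never as 0.
Pooled components sum base counts across genes rather than averaging
per-gene fractions, matching how single per-component values are
conventionally reported; the codon-position split is performed per gene
(each gene restarts its frame, and an incomplete final codon
contributes only the positions it has) before the position streams are
concatenated. Stop codons, complete or incomplete, belong to the
annotated gene span and therefore count toward component composition;
they are excluded only from the codon-usage indices below.

# Codon-usage-bias indices

All indices run on NCBI translation table 5, where ATA is Met, TGA is
Trp, AGA/AGG are Ser, and the only stops are TAA/TAG, leaving 62 sense
codons. Two different notions of synonymy are deliberately kept apart:

* **RSCU** uses full amino-acid families — Leu spans 6 codons and Ser
  8 under table 5 — so
  $\mathrm{RSCU}(c) = n_c\,|F| / \sum_{c'\in F} n_{c'}$ averages to 1
  within any used family. This matches the behavior of the standard
  codon-usage tools for alternative codes.
* **ENC** uses synonymous sub-families (same amino acid *and* same
  first two codon bases): table 5 partitions the sense codons into 13
  two-fold and 9 four-fold sub-families, which is what keeps Wright's
  class algebra valid. Per sub-family with total $n > 1$ the
  homozygosity is $\hat F = (n\sum p_i^2 - 1)/(n-1)$; class means give
  $N_c = 13/\bar F_2 + 9/\bar F_4$, capped at 62. Sub-families with
  $n \le 1$ or $\hat F \le 0$ are dropped from their class mean, and a
  class with no usable sub-family borrows the other class's mean
  (flagged in the output) rather than leaving $N_c$ undefined on short
  genes such as `ATP8`. The attainable range is 22 (one codon per
  sub-family) to 62 (uniform usage); values at or below 35 are read as
  strong bias.

The ENC--GC3s expected curve is the closed form
$N_c = 2 + \mathrm{GC3s} + 29/(\mathrm{GC3s}^2 + (1-\mathrm{GC3s})^2)$;
the neutrality plot regresses GC12 (mean GC at positions 1--2) on GC3
by ordinary least squares; the PR2 bias plot uses
$x = G_{3s}/(G_{3s}+C_{3s})$, $y = A_{3s}/(A_{3s}+T_{3s})$ with
quadrants assigned relative to the (0.5, 0.5) equilibrium. Stop codons
are excluded from every CUB denominator, including GC3 for the
neutrality points, so GC3 stays comparable with GC3s; the start codon
is translated as its ordinary table entry with no initiator special
case. Per-species "all-PCGs" profiles pool codon counts over the 13
genes. The three analysis scopes (pooled per species, one gene across
species, 13 genes within one species) are all exposed through
`codonUsageProfile()` and the `runCharacterize()` tables.

# Architecture

`geneOrder()` anchors the circular order at `trnI` and compares
(name, strand) pairs against the built-in ancestral insect arrangement,
itemizing mismatches; duplicated names are reported and compared on
first copies. `junctions()` classifies every consecutive pair
(circularly): overlap $\max(0,\ \mathrm{prev\_end} -
\mathrm{next\_start} + 1)$, spacer $\max(0,\ \mathrm{next\_start} -
\mathrm{prev\_end} - 1)$. Junction classification ignores strand (the
conserved 8 bp trnW/trnC overlap pairs a plus- with a minus-strand
gene); the CR participates as a junction partner but is not itself
counted as an intergenic spacer; nested features are reported
separately and excluded. Start codons are classified as ATN, GTG, TTG,
CAA, TCG or other; stops as complete TAA/TAG, incomplete `T` (length
mod 3 = 1 ending in T) or `TA` (mod 3 = 2 ending in TA) — a purely
positional, annotation-driven classification, since the
polyadenylation that completes truncated stops is inferred rather than
observed. The circular accounting identity
$\sum \mathrm{gene} - \sum \mathrm{overlap} + \sum \mathrm{spacer} +
\mathrm{CR} = \mathrm{genome\ length}$
is checked exactly on every fully annotated genome.

# Similarity ranking

Published CCT/BLAST similarity percentages depend on tool versions and
scoring parameters, so `mitochar` substitutes deterministic global
(Needleman--Wunsch) alignment and promises the qualitative ranking
structure, not any published percentage: nucleotide mode scores match
+1 / mismatch −1 with affine gaps (open 2, extend 0.5); protein mode
uses BLOSUM62 (open 11, extend 1) on table-5 translations. Identity is
identical columns over alignment columns; because co-optimal alignments
can tie with different column counts, each pair is aligned in a
canonical orientation, making identity exactly symmetric. Genes are
paired by canonical name, and a subject missing a gene has the
reference-length weights renormalized. Both modes are provided;
neither is claimed to reproduce any external pipeline.

# The synthetic generator

`simulateMitogenome()` emulates the study conditions of real dacine
mitogenomes: ancestral order and strands; PCG lengths totalling
11,181 bp with the incomplete-stop classes implied by each length mod
3; tRNAs of 64--72 bp (1470 bp total), rRNAs of 1334 and 797 bp, CR of
1623 bp; six overlaps of 1--8 bp totalling 27 bp (trnW|trnC 8,
ATP8|ATP6 7, ND4|ND4L 7, trnY|COI 3, trnG|ND3 1, trnE|trnF 1); twenty
spacers totalling 222 bp with the longest at trnA|trnR; a default AT
target of 0.74 (the printed 46-genome average is 74.14%); and
third-position base weights favoring A/T so codon bias, PR2 offsets and
ENC below the expected curve all emerge as in real data. These values
were fixed once from the printed comparative tables and are not tuning
knobs.

Design choices worth knowing:

* PCGs are built codon-by-codon from sense codons only (no internal
  stops) with planned start and stop codons. At the two
  protein-protein overlaps the junction codons of both partners are
  pinned to constants chosen so the shared bases read as sense codons
  in both frames — this is why arbitrary protein-protein overlap plans
  are rejected at validation rather than silently emitting
  inconsistent sequence.
* tRNA/rRNA/CR/spacer sequences are i.i.d. base draws at the genome AT
  target: no secondary structure, no CR repeats. Every component uses
  the same AT target so the whole-genome AT lands within ±0.02 of it;
  real CRs are AT-richer than the rest of the genome, a feature the
  generator deliberately does not reproduce. Consequently, passing
  tests demonstrate the correctness of the arithmetic on realistic
  scale and structure, not that real genomes look like the simulation.
* Minus-strand genes are generated as reading-strand sequence and
  reverse-complemented into place; one global RNG stream per genome
  (no per-gene reseeding) makes output byte-identical for a fixed
  seed.
* `simulatePanel()` derives panel members by independent per-site
  substitutions (no indels; boundaries preserved), rejecting rates
  ≥ 0.75 as saturated. `simulateNeutralityGenes()` plants a linear
  GC12-on-GC3 relationship for regression-recovery checks.

The truth record carries the planned architecture plus
generation-side tallies (per-gene codon counts, per-component base
counts) computed independently of the analysis code, so
"analysis recovers truth exactly" is a genuine cross-module check.

# Numerical conventions and degenerate inputs

Percentages are displayed to 1 decimal and skews to 3 (the precision
of the comparative literature); underlying values are kept at full
precision in every table. Undefined ratios (all-N sequence, empty
synonymous classes, zero-variance regressors, zero PR2 denominators)
are reported missing rather than coerced to 0, except the flat-line
regression where $r^2$ is reported 0 with a flag. ENC class borrowing
is flagged through the `imputed` attribute and surfaced in the
`runCharacterize()` warnings file.

# Problem sizes used by the test suite

The suite verifies oracle equivalence on hundreds of random small
instances, ENC bounds on 1000 random codon tables, architecture truth
recovery on 20 full-size simulated genomes, slope recovery on 200
generated genes, and rate-ordering recovery over 100 replicate panels.
The replicate panels use proportionally shortened PCGs (same
stop-codon classes, same junction plans) so that 2,600 global
alignments stay quick; all composition and architecture guarantees are
unchanged by the scaling, and the full-size defaults are exercised
everywhere else.

# A worked example

```{r example, eval = FALSE}
sim <- simulateMitogenome(simulationParams(seed = 1))
g <- sim$genome
architectureReport(g)
head(suppressWarnings(componentProfile(g))[, 2:6])
codonUsageProfile(unname(pcgSequences(g)))
```

# Known limitations

No de-novo annotation, tRNA folding, alignment heterogeneity scoring
or phylogenetic inference; multi-segment (non-origin) `join` locations
are rejected rather than modeled; heatmap clustering and all figure
rendering are left to dedicated tools — the package emits the
underlying tables.
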