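sim1 <- simulateMitogenome(simulationParams(seed = 1))

test_that("a simulated genome matches the ancestral gene order", {
  go <- geneOrder(sim1$genome)
  expect_true(go$ancestral_match)
  expect_identical(nrow(go$mismatches), 0L)
  expect_identical(go$order$name[1], "trnI")
  expect_identical(nrow(go$order), 38L)
})

test_that("a transposition is itemized and duplications flagged", {
  g <- sim1$genome
  ft <- features(g)
  iw <- which(ft$name == "trnW"); ic <- which(ft$name == "trnC")
  ft2 <- ft
  ft2[c(iw, ic), c("name", "strand", "anticodon")] <-
    ft[c(ic, iw), c("name", "strand", "anticodon")]
  g2 <- Mitogenome("SWAP", circular = TRUE,
                   sequence = as.character(genomeSequence(g)),
                   features = ft2)
  go <- geneOrder(g2)
  expect_false(go$ancestral_match)
  expect_identical(sort(go$mismatches$observed),
                   sort(c("trnC -", "trnW +")))

  ft3 <- rbind(ft, transform(ft[ft$name == "trnM", ],
                             start = start + 1L, end = end + 1L))
  g3 <- Mitogenome("DUP", circular = TRUE,
                   sequence = as.character(genomeSequence(g)),
                   features = ft3)
  expect_warning(go3 <- geneOrder(g3), "duplicated")
  expect_identical(go3$duplicated, "trnM")
})

test_that("junction arithmetic reproduces hand-computed toys", {
  mk <- function(starts, ends, strands = "+", circ = TRUE, L = 60) {
    n <- length(starts)
    Mitogenome("J", circular = circ, sequence = strrep("ACGT", L / 4),
               features = data.frame(
                 name = paste0("g", seq_len(n)), kind = "tRNA",
                 strand = strands, start = starts, end = ends,
                 anticodon = NA))
  }
  j1 <- junctions(mk(c(1, 8), c(10, 20)))
  expect_identical(j1$junctions$overlap[1], 3L)      # 1..10 vs 8..20
  j2 <- junctions(mk(c(1, 15), c(10, 20)))
  expect_identical(j2$junctions$spacer[1], 4L)       # 1..10 vs 15..20
  ## the conserved trnW/trnC-style 8 bp overlap
  j3 <- junctions(mk(c(1, 61), c(68, 130), L = 200))
  expect_identical(j3$junctions$overlap[1], 8L)
  ## circular wrap junction: last feature back to the first
  j4 <- junctions(mk(c(5, 30), c(20, 58), L = 60))
  expect_identical(j4$junctions$spacer[2], 6L)       # 58 .. 60+5
})

test_that("junction inventory is invariant under rotation of the origin", {
  g <- sim1$genome
  L <- genomeLength(g)
  ## rotate at a point inside the first intergenic spacer so that no
  ## feature is bisected
  rot <- features(g)$end[features(g)$name == "trnI"] + 5L
  s <- as.character(genomeSequence(g))
  s2 <- paste0(substr(s, rot + 1L, L), substr(s, 1L, rot))
  ft <- features(g)
  ft$start <- ft$start - rot; ft$end <- ft$end - rot
  wrap <- ft$start < 1L
  ft$start[wrap] <- ft$start[wrap] + L
  ft$end[wrap] <- ft$end[wrap] + L
  g2 <- Mitogenome("ROT", circular = TRUE, sequence = s2, features = ft)
  j1 <- junctions(g)
  j2 <- junctions(g2)
  key <- function(j) {
    jt <- j$junctions[order(j$junctions$upstream, j$junctions$downstream), ]
    jt[, c("upstream", "downstream", "overlap", "spacer")]
  }
  k1 <- key(j1); k2 <- key(j2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
})

test_that("overlap and spacer totals match per-base occupancy counts", {
  for (seed in c(1L, 4L)) {
    sim <- simulateMitogenome(simulationParams(seed = seed))
    g <- sim$genome
    L <- genomeLength(g)
    cover <- integer(L)
    ft <- features(g)
    for (i in seq_len(nrow(ft))) {
      pos <- (seq(ft$start[i], ft$end[i]) - 1L) %% L + 1L
      cover[pos] <- cover[pos] + 1L
    }
    jn <- junctions(g)
    expect_identical(sum(cover >= 2L), jn$overlap_total)
    expect_identical(sum(cover == 0L), jn$spacer_total)
  }
})

test_that("boundary codons classify starts and complete/incomplete stops", {
  mk1 <- function(cds) {
    Mitogenome("B", circular = TRUE,
               sequence = paste0(cds, strrep("ACGT", 5)),
               features = data.frame(name = "ND2", kind = "PCG",
                                     strand = "+", start = 1,
                                     end = nchar(cds), anticodon = NA))
  }
  b1 <- boundaryCodons(mk1("ATGAAATAA"))
  expect_identical(b1$start_class, "ATN")
  expect_identical(b1$stop_completeness, "complete")
  expect_identical(b1$stop_codon, "TAA")
  b2 <- boundaryCodons(mk1("ATTAAAT"))
  expect_identical(b2$stop_completeness, "T")
  b3 <- boundaryCodons(mk1("GTGAAATAG"))
  expect_identical(b3$start_class, "GTG")
  expect_identical(b3$stop_codon, "TAG")
  b4 <- boundaryCodons(mk1("ATTAAATA"))
  expect_identical(b4$stop_completeness, "TA")
  expect_warning(b5 <- boundaryCodons(mk1("CGAAAACCC")),
                 "no recognizable stop")
  expect_identical(b5$start_class, "other")
  expect_identical(b5$stop_completeness, "other")
  expect_error(boundaryCodons(mk1("ATGAA")), "shorter")
})

test_that("the length-accounting identity holds on simulated genomes", {
  for (seed in c(2L, 8L, 15L)) {
    rep <- suppressWarnings(architectureReport(
      simulateMitogenome(simulationParams(seed = seed))$genome))
    a <- rep$accounting
    expect_true(a$identity_holds)
    expect_identical(a$gene_total - a$overlap_total + a$spacer_total +
                       a$cr_length + a$cr_gap_total, a$genome_length)
  }
})
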