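test_that("skew and AT-content formulas reproduce hand tallies", {
  expect_equal(baseStats("AATT")$at_content, 1.0)
  expect_equal(baseStats("AATT")$at_skew, 0.0)
  expect_true(is.na(baseStats("AATT")$gc_skew))
  expect_equal(baseStats("AAAT")$at_skew, 0.5)       # (3-1)/(3+1)
  expect_equal(baseStats("GGGC")$gc_skew, 0.5)
  expect_equal(baseStats("GGGC")$at_content, 0.0)
  expect_true(is.na(baseStats("GGGC")$at_skew))
  expect_equal(baseStats("AACGT")$at_content, 3 / 5)
})

test_that("N is counted in length but not in any denominator", {
  s <- baseStats("AANNTT")
  expect_identical(s$length, 6L)
  expect_equal(s$at_content, 1.0)
  expect_error(baseStats("NNNN"), "no unambiguous")
})

test_that("skews are permutation-invariant, bounded, and negate under
           complementation", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(60, probs = c(A = .4, C = .1, G = .15, T = .35))
    st <- baseStats(s)
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(baseStats(perm)$at_skew, st$at_skew)
    expect_equal(baseStats(perm)$gc_skew, st$gc_skew)
    expect_true(abs(st$at_skew) <= 1 && abs(st$gc_skew) <= 1)
    compl <- chartr("ACGT", "TGCA", s)
    expect_equal(baseStats(compl)$at_skew, -st$at_skew)
    expect_equal(baseStats(compl)$gc_skew, -st$gc_skew)
    expect_equal(st$at_content + (st$n_G + st$n_C) /
                   (st$n_A + st$n_C + st$n_G + st$n_T), 1)
  }
})

test_that("codon-position split respects per-gene frames", {
  expect_identical(codonPositionSplit("ATGAAA"), list("AA", "TA", "GA"))
  ## incomplete tail contributes only the positions it has
  expect_identical(codonPositionSplit("ATGA"), list("AA", "T", "G"))
  ## two genes: each restarts its own frame
  expect_identical(codonPositionSplit(c("ATGA", "CCT")),
                   list("AAC", "TC", "GT"))
  ## position streams exactly repartition the input
  set.seed(3)
  genes <- replicate(10, random_dna(sample(30:60, 1)))
  split <- codonPositionSplit(genes)
  expect_identical(sum(nchar(unlist(split))), sum(nchar(genes)))
  pooled <- sort(strsplit(paste(genes, collapse = ""), "")[[1]])
  expect_identical(sort(strsplit(paste(unlist(split), collapse = ""),
                                 "")[[1]]), pooled)
})

test_that("component profile pools counts rather than averaging genes", {
  g <- toy_genome()
  prof <- suppressWarnings(componentProfile(g))
  pcg_row <- prof[prof$component == "PCG", ]
  gene_row <- prof[prof$component == "ND2", ]
  expect_equal(pcg_row$at_content, gene_row$at_content)
  whole <- prof[prof$component == "whole", ]
  expect_identical(whole$length, 40L)
  ## rows for the three codon positions are present
  expect_true(all(c("PCG1", "PCG2", "PCG3") %in% prof$component))
})

test_that("simulated third-position AT matches the generator target", {
  p <- simulationParams(seed = 9)
  g <- simulateMitogenome(p)$genome
  prof <- suppressWarnings(componentProfile(g))
  at3_target <- sum(p$third_pos_weights[c("A", "T")])
  pcg3 <- prof[prof$component == "PCG3", "at_content"]
  expect_lt(abs(pcg3 - at3_target), 0.02)
})

test_that("panel summary reduces correctly at the edges", {
  g <- toy_genome()
  one <- suppressWarnings(panelSummary(list(g)))
  whole_at <- one[one$component == "whole" & one$metric == "at_content", ]
  expect_equal(whole_at$mean, whole_at$min)
  expect_equal(whole_at$sd, 0)
  expect_identical(whole_at$min_genome, "TOY1")

  p1 <- suppressWarnings(componentProfile(g))
  g2 <- g; g2@id <- "TOY2"
  two <- suppressWarnings(panelSummary(list(g, g2)))
  expect_equal(two[two$component == "whole" &
                     two$metric == "at_content", "mean"],
               p1[p1$component == "whole", "at_content"])
})

test_that("a two-genome panel with known AT contents averages exactly", {
  ga <- Mitogenome("A70", sequence = paste(c(rep("A", 70), rep("G", 30)),
                                           collapse = ""))
  gb <- Mitogenome("B80", sequence = paste(c(rep("A", 80), rep("G", 20)),
                                           collapse = ""))
  s <- suppressWarnings(panelSummary(list(ga, gb)))
  at <- s[s$component == "whole" & s$metric == "at_content", ]
  expect_equal(at$mean, 0.75)
  expect_identical(at$max_genome, "B80")
})
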