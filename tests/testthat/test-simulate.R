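test_that("identical params and seed give byte-identical GenBank output", {
  p <- simulationParams(seed = 42)
  l1 <- writeGenBank(simulateMitogenome(p)$genome)
  l2 <- writeGenBank(simulateMitogenome(p)$genome)
  expect_identical(l1, l2)
  l3 <- writeGenBank(simulateMitogenome(simulationParams(seed = 43))$genome)
  expect_false(identical(l1, l3))
})

test_that("the default genome realizes the planned architecture", {
  sim <- simulateMitogenome(simulationParams(seed = 1))
  g <- sim$genome
  ft <- features(g)
  expect_identical(nrow(ft), 38L)
  expect_identical(sum(ft$kind == "PCG"), 13L)
  expect_identical(sum(ft$kind == "tRNA"), 22L)
  expect_identical(sum(ft$kind == "rRNA"), 2L)
  expect_identical(sum(ft$kind == "CR"), 1L)
  expect_identical(nchar(concatPCGs(g)), 11181L)
  ## tRNA lengths within the biological envelope
  tl <- with(featuresOfKind(g, "tRNA"), end - start + 1L)
  expect_true(all(tl >= 50 & tl <= 100))
})

test_that("planned overlaps, spacers and boundary codons are recovered
           exactly by the analysis modules", {
  for (seed in c(1L, 7L, 23L)) {
    sim <- simulateMitogenome(simulationParams(seed = seed))
    g <- sim$genome
    jn <- junctions(g)
    ov <- jn$overlaps[, c("upstream", "downstream", "overlap")]
    rownames(ov) <- NULL
    plan_ov <- sim$truth$overlaps
    plan_ov <- plan_ov[order(match(plan_ov$upstream, ov$upstream)), ]
    rownames(plan_ov) <- NULL
    expect_identical(ov$overlap, plan_ov$bp)
    expect_identical(ov$upstream, plan_ov$upstream)

    sp <- jn$spacers
    expect_identical(nrow(sp), nrow(sim$truth$spacers))
    expect_identical(sum(sp$spacer), sum(sim$truth$spacers$bp))

    bc <- boundaryCodons(g)
    plan_bc <- sim$truth$boundary
    m <- match(bc$gene, plan_bc$gene)
    expect_identical(bc$start_codon, plan_bc$start_codon[m])
    got_stop <- ifelse(bc$stop_completeness == "complete", "TAA",
                       bc$stop_codon)
    expect_identical(got_stop, plan_bc$stop[m])
  }
})

test_that("realized codon counts match the truth record exactly", {
  sim <- simulateMitogenome(simulationParams(seed = 13))
  g <- sim$genome
  for (gene in names(sim$truth$codon_counts)) {
    cc <- codonCounts(featureSequence(g, gene))
    truth <- sim$truth$codon_counts[[gene]]
    expect_identical(unname(cc[names(truth)]),
                     as.integer(truth), label = gene)
    expect_identical(sum(cc), sum(as.integer(truth)), label = gene)
  }
})

test_that("realized base counts match the truth tally per component", {
  sim <- simulateMitogenome(simulationParams(seed = 17))
  g <- sim$genome
  prof <- suppressWarnings(componentProfile(g))
  for (nm in c("whole", "CR", "ND2", "trnI", "rrnL", "ND5")) {
    row <- prof[prof$component == nm, ]
    truth <- sim$truth$base_counts[[if (nm == "whole") "whole" else nm]]
    expect_identical(as.integer(c(row$n_A, row$n_C, row$n_G, row$n_T)),
                     unname(truth[c("A", "C", "G", "T")]), label = nm)
  }
})

test_that("whole-genome AT content lands within 0.02 of its target", {
  for (target in c(0.70, 0.74, 0.78)) {
    p <- simulationParams(seed = 7, at_content = target)
    g <- simulateMitogenome(p)$genome
    at <- baseStats(as.character(genomeSequence(g)))$at_content
    expect_lt(abs(at - target), 0.02,
              label = paste("target", target))
  }
})

test_that("an infeasible overlap plan is rejected before emission", {
  expect_error(
    simulationParams(overlap_plan = data.frame(
      upstream = "trnW", downstream = "trnC", bp = 70L)),
    "longer than a participating gene")
  expect_no_error(
    simulationParams(overlap_plan = data.frame(
      upstream = "ND2", downstream = "trnW", bp = 2L)))
  expect_error(
    simulationParams(overlap_plan = data.frame(
      upstream = "COI", downstream = "trnL2", bp = 3L,
      stringsAsFactors = FALSE) |>
        rbind(data.frame(upstream = "ND6", downstream = "CYTB", bp = 5L))),
    "protein-protein")
  expect_error(
    simulationParams(spacer_plan = data.frame(
      upstream = "trnI", downstream = "ND2", bp = 5L)),
    "not adjacent")
})

test_that("a zero-rate derivative is identical and positive rates follow
           the binomial expectation", {
  p0 <- scaled_params(seed = 3)
  panel0 <- simulatePanel(p0, rates = 0)
  expect_identical(as.character(genomeSequence(panel0[[2]]$genome)),
                   as.character(genomeSequence(panel0[[1]]$genome)))

  p <- simulationParams(seed = 3)
  panel <- simulatePanel(p, rates = c(0.1))
  L <- genomeLength(panel[[1]]$genome)
  nsub <- panel[[2]]$truth$n_substitutions
  expect_lt(abs(nsub - 0.1 * L), 3 * sqrt(L * 0.1 * 0.9))
  expect_error(simulatePanel(p, rates = 0.8), "saturation")
})

test_that("neutrality genes carry their planted slope", {
  genes <- simulateNeutralityGenes(n = 60, slope = 0.5, intercept = 0.2,
                                   sigma = 0.005, seed = 5)
  pts <- as.data.frame(t(vapply(genes, gcByPosition, numeric(4))))
  names(pts) <- c("gc1", "gc2", "gc3", "gc12")
  f <- neutralityFit(pts)
  expect_lt(abs(f$slope - 0.5), 0.05)
  expect_gt(f$r2, 0.8)
})
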