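code <- mitoGeneticCode()

test_that("codon counting handles stops, incomplete tails and N", {
  cc <- codonCounts("ATGAAATAA")
  expect_identical(unname(cc[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_identical(sum(cc), 3L)
  cc2 <- codonCounts("ATGAAAT")        # T-- incomplete stop
  expect_identical(sum(cc2), 2L)
  expect_identical(attr(cc2, "n_trailing"), 1L)
  cc3 <- codonCounts("ATGANATTT")
  expect_identical(attr(cc3, "n_skipped"), 1L)
  expect_identical(sum(cc3), 2L)
})

test_that("codon counts match a brute-force recount on random genes", {
  set.seed(21)
  for (i in 1:120) {
    cds <- random_dna(3 * sample(5:60, 1) + sample(0:2, 1),
                      probs = c(A = .35, C = .12, G = .15, T = .38))
    cc <- codonCounts(cds)
    oc <- oracle_codon_counts(cds)
    for (cod in names(oc))
      expect_identical(unname(cc[cod]), oc[[cod]])
    expect_identical(sum(cc), sum(unlist(oc)))
  }
})

test_that("RSCU follows count * family size / family total", {
  ## two-codon family with counts (3, 1): Phe TTT/TTC
  counts <- setNames(integer(64), code$codons)
  counts["TTT"] <- 3L; counts["TTC"] <- 1L
  r <- rscu(counts)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1.5, 0.5))
  expect_true(all(is.na(r[setdiff(names(r), c("TTT", "TTC"))])))

  ## uniform usage in every family gives RSCU 1 everywhere
  uni <- setNames(rep(2L, 64), code$codons)
  r2 <- rscu(uni)
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("RSCU treats Leu and Ser as 6- and 8-codon families", {
  counts <- setNames(integer(64), code$codons)
  leu <- codonFamilies(code)[["L"]]
  counts[leu] <- 1L
  expect_equal(unname(rscu(counts)[leu]), rep(1, 6))
  counts2 <- setNames(integer(64), code$codons)
  counts2["TTA"] <- 8L   # all Leu usage on one codon of the 6
  expect_equal(unname(rscu(counts2)["TTA"]), 6)
})

test_that("RSCU conservation holds on random codon tables", {
  set.seed(5)
  fams <- codonFamilies(code)
  for (i in 1:100) {
    counts <- random_codon_table(code)
    r <- rscu(counts)
    for (aa in names(fams)) {
      tot <- sum(counts[fams[[aa]]])
      if (tot > 0) {
        expect_equal(sum(r[fams[[aa]]]), length(fams[[aa]]))
        expect_equal(mean(r[fams[[aa]]]), 1)
      }
    }
  }
})

test_that("amino-acid usage ratios are count fractions", {
  cc <- codonCounts("ATGAAA")
  au <- aaUsage(cc)
  expect_equal(au$ratio[au$aa == "M"], 0.5)
  expect_equal(au$ratio[au$aa == "K"], 0.5)
  ## all 62 sense codons once: ratios proportional to family sizes
  all_once <- setNames(rep(1L, 64), code$codons)
  au2 <- aaUsage(all_once)
  fams <- codonFamilies(code)
  for (aa in au2$aa)
    expect_equal(au2$ratio[au2$aa == aa], length(fams[[aa]]) / 62)
})

test_that("third-position stats match the brute-force tally", {
  ## hand case: third positions A, A, T, G
  cc <- codonCounts("AAATCATTTGGG")
  tp <- thirdPositionStats(cc)
  expect_equal(unname(tp[c("a3s", "t3s", "g3s", "c3s", "gc3s")]),
               c(0.5, 0.25, 0.25, 0, 0.25))
  set.seed(31)
  for (i in 1:120) {
    cds <- random_dna(3 * sample(10:80, 1),
                      probs = c(A = .3, C = .2, G = .2, T = .3))
    got <- thirdPositionStats(codonCounts(cds))
    want <- oracle_thirdpos(cds)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
  }
})

test_that("GC by position matches a per-character oracle and gc12 is the
           mean of gc1 and gc2", {
  ## hand tally of ATG + AAA: GC appears only at position 3 of ATG
  g <- gcByPosition("ATGAAA")
  expect_equal(unname(g), c(0, 0, 0.5, 0))
  expect_equal(unname(gcByPosition(strrep("GCG", 10))),
               c(1, 1, 1, 1))
  set.seed(41)
  for (i in 1:120) {
    cds <- random_dna(3 * sample(10:80, 1),
                      probs = c(A = .3, C = .2, G = .25, T = .25))
    got <- gcByPosition(cds)
    want <- oracle_gc_by_pos(cds)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
    expect_equal(got[["gc12"]], (got[["gc1"]] + got[["gc2"]]) / 2)
  }
})

test_that("the expected-ENC curve evaluates the printed closed form", {
  expect_equal(encExpected(0), 31)
  expect_equal(encExpected(0.5), 60.5)
  expect_equal(encExpected(1), 32)
  expect_error(encExpected(1.2))
})

test_that("extreme bias gives Nc exactly 22 and uniform usage approaches
           62", {
  subs <- codonSubfamilies(code)
  one_per_family <- setNames(integer(64), code$codons)
  for (members in subs) one_per_family[members[1]] <- 50L
  expect_equal(as.numeric(encWright(one_per_family)), 22)

  uni <- setNames(rep(1000L, 64), code$codons)
  expect_gt(as.numeric(encWright(uni)), 61.9)
  expect_lte(as.numeric(encWright(uni)), 62)
})

test_that("Nc stays within [22, 62] on random tables and scales with
           counts", {
  set.seed(51)
  for (i in 1:200) {
    counts <- random_codon_table(code, lambda = sample(c(2, 10, 40), 1))
    nc <- as.numeric(encWright(counts))
    if (!is.na(nc)) {
      expect_gte(nc, 22)
      expect_lte(nc, 62)
    }
  }
  ## at large counts Nc is scale-invariant up to the 1/(n-1) correction:
  ## dNc/dF ~ 13/F^2 and dF ~ 1/(n-1), so with family totals near 80
  ## and F near 0.5 the doubled-count shift stays within ~1.3
  for (i in 1:50) {
    counts <- random_codon_table(code, lambda = 40)
    nc <- as.numeric(encWright(counts))
    nc2 <- as.numeric(encWright(counts * 2L))
    expect_lt(abs(nc - nc2), 1.3)
  }
})

test_that("ENC class borrowing is flagged on degenerate input", {
  counts <- setNames(integer(64), code$codons)
  counts[codonSubfamilies(code)[["TT:F"]]] <- c(5L, 5L)  # only a 2-fold
  nc <- encWright(counts)
  expect_identical(attr(nc, "imputed"), "fourfold")
  empty <- setNames(integer(64), code$codons)
  expect_true(is.na(as.numeric(encWright(empty))))
})

test_that("neutrality regression recovers exact and degenerate cases", {
  pts <- data.frame(gc3 = c(.1, .3, .5, .8), gc12 = c(.1, .3, .5, .8))
  f <- neutralityFit(pts)
  expect_equal(f$slope, 1)
  expect_equal(f$r2, 1)
  flat <- data.frame(gc3 = c(.1, .4, .7), gc12 = c(.4, .4, .4))
  f2 <- neutralityFit(flat)
  expect_equal(f2$slope, 0)
  expect_equal(f2$r2, 0)
  expect_true(f2$zero_variance)
  degen <- data.frame(gc3 = c(.5, .5, .5), gc12 = c(.1, .2, .3))
  expect_true(is.na(neutralityFit(degen)$slope))
})

test_that("PR2 coordinates and quadrants follow the 0.5 center", {
  balanced <- c(a3s = .25, t3s = .25, g3s = .25, c3s = .25)
  p <- pr2Point(balanced)
  expect_equal(c(p$x, p$y), c(0.5, 0.5))
  expect_identical(p$quadrant, "center")
  skewed <- c(a3s = .5, t3s = 0, g3s = .3, c3s = .2)
  p2 <- pr2Point(skewed)
  expect_equal(p2$y, 1)
  expect_identical(p2$quadrant, "I")
  tu <- c(a3s = .2, t3s = .4, g3s = .3, c3s = .1)  # T > A, G > C
  expect_identical(pr2Point(tu)$quadrant, "IV")
  none <- c(a3s = 1, t3s = 0, g3s = 0, c3s = 0)
  expect_true(is.na(pr2Point(none)$x))
})

test_that("a generator-biased four-fold family shows the analytic RSCU", {
  ## probability 0.8 on the A-ending codon of a 4-codon family -> 3.2
  set.seed(61)
  fam <- codonSubfamilies(code)[["GG:G"]]     # Gly GGN
  prob <- c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3)
  names(prob) <- c("GGA", setdiff(fam, "GGA"))
  draws <- sample(names(prob), 6000, replace = TRUE, prob = prob)
  cds <- paste(draws, collapse = "")
  r <- rscu(codonCounts(cds))
  expect_lt(abs(r[["GGA"]] - 3.2), 0.1)
})
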