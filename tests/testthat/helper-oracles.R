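## Independent brute-force oracles, deliberately naive: each walks the
## input character by character and never shares code with the package.

oracle_codon_counts <- function(cds) {
  cds <- toupper(cds)
  out <- list()
  i <- 1L
  while (i + 2L <= nchar(cds)) {
    cod <- substr(cds, i, i + 2L)
    out[[cod]] <- (if (is.null(out[[cod]])) 0L else out[[cod]]) + 1L
    i <- i + 3L
  }
  out
}

oracle_thirdpos <- function(cds, stops = c("TAA", "TAG")) {
  cc <- oracle_codon_counts(cds)
  tal <- c(A = 0, T = 0, G = 0, C = 0)
  for (cod in names(cc)) {
    if (cod %in% stops || grepl("N", cod)) next
    b <- substr(cod, 3, 3)
    tal[b] <- tal[b] + cc[[cod]]
  }
  tot <- sum(tal)
  c(a3s = tal[["A"]] / tot, t3s = tal[["T"]] / tot,
    g3s = tal[["G"]] / tot, c3s = tal[["C"]] / tot,
    gc3s = (tal[["G"]] + tal[["C"]]) / tot)
}

oracle_gc_by_pos <- function(cds, stops = c("TAA", "TAG")) {
  cc <- oracle_codon_counts(cds)
  gc <- c(0, 0, 0); tot <- 0
  for (cod in names(cc)) {
    if (cod %in% stops || grepl("N", cod)) next
    tot <- tot + cc[[cod]]
    for (p in 1:3)
      if (substr(cod, p, p) %in% c("G", "C"))
        gc[p] <- gc[p] + cc[[cod]]
  }
  c(gc1 = gc[1] / tot, gc2 = gc[2] / tot, gc3 = gc[3] / tot,
    gc12 = (gc[1] + gc[2]) / (2 * tot))
}

## global affine-gap alignment score by exhaustive Gotoh recursion;
## a gap of length L costs open + ext * L, end gaps included
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq(2, n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in seq(2, m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in seq(2, n + 1)) for (j in seq(2, m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

## random 64-codon count table (includes stops, as codonCounts yields)
random_codon_table <- function(code, lambda = 30) {
  counts <- stats::rpois(64, lambda)
  names(counts) <- code$codons
  counts
}
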