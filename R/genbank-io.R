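#' Read annotated mitogenome records from a GenBank flat file
#'
#' Parses one or more GenBank records (LOCUS..//) into
#' \code{\link{Mitogenome}} objects. Gene features are built from CDS,
#' tRNA, rRNA, D-loop and control-region-annotated misc_feature
#' entries (plus bare \code{gene} entries that pair with none of
#' those); names are canonicalized via
#' \code{\link{canonicalGeneName}}; \code{complement()} and
#' origin-wrapping \code{join()} locations are normalized to 1-based
#' inclusive coordinates, with wrapping encoded as \code{end} beyond
#' the genome length. Unmappable features are retained with kind
#' \code{other} and excluded from downstream statistics. When a
#' fully annotated record (37 genes) lacks an explicit control region,
#' the largest unannotated gap is assigned CR, with a warning.
#'
#' @param path file path (or character vector of lines via
#'   \code{text}).
#' @param text optional character vector of GenBank lines, used instead
#'   of \code{path}.
#' @return A list of \code{Mitogenome} objects.
#' @export
readGenBank <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  starts <- grep("^LOCUS ", lines)
  if (!length(starts)) stop("no GenBank records found")
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts))
    ends <- c(ends, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    end_i <- ends[ends >= starts[i]][1]
    out[[i]] <- .parseGenBankRecord(lines[starts[i]:end_i])
  }
  out
}

.parseGenBankRecord <- function(rec) {
  locus <- strsplit(trimws(rec[1]), "\\s+")[[1]]
  id <- locus[2]
  declared_len <- suppressWarnings(as.integer(locus[3]))
  circular <- any(grepl("circular", rec[1], ignore.case = TRUE))
  org <- NA_character_
  oi <- grep("^\\s{2}ORGANISM\\s", rec)
  if (length(oi)) org <- trimws(sub("^\\s*ORGANISM\\s*", "", rec[oi[1]]))
  fi <- grep("^FEATURES", rec)
  si <- grep("^ORIGIN", rec)
  if (!length(si)) stop("record ", id, ": no ORIGIN sequence block")
  seq <- toupper(paste(gsub("[^A-Za-z]", "", rec[(si[1] + 1):length(rec)]),
                       collapse = ""))
  seq <- sub("//$", "", seq)
  if (!is.na(declared_len) && nchar(seq) != declared_len)
    stop("record ", id, ": LOCUS declares ", declared_len,
         " bp but sequence block has ", nchar(seq))
  feats <- if (length(fi)) .parseFeatureTable(rec[(fi[1] + 1):(si[1] - 1)],
                                              id, nchar(seq))
           else emptyFeatureTable()
  g <- Mitogenome(id, organism = org, circular = circular,
                  sequence = seq, features = feats)
  g <- .ensureControlRegion(g)
  g
}

.parseFeatureTable <- function(lines, id, genome_len) {
  ## fold continuation lines; a new feature starts with key at col 6
  keyline <- grepl("^ {5}\\S", lines)
  idx <- cumsum(keyline)
  keep <- idx > 0
  entries <- split(trimws(lines[keep]), idx[keep])
  rows <- lapply(entries, .parseFeatureEntry, id = id,
                 genome_len = genome_len)
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(emptyFeatureTable())
  ft <- do.call(rbind, rows)
  ## drop bare gene entries duplicating a typed feature at the same start
  typed <- ft[!ft$from_gene_key, , drop = FALSE]
  bare <- ft[ft$from_gene_key, , drop = FALSE]
  if (nrow(bare))
    bare <- bare[!(paste(bare$start, bare$strand) %in%
                     paste(typed$start, typed$strand)), , drop = FALSE]
  ft <- rbind(typed, bare)
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  ft$from_gene_key <- NULL
  rownames(ft) <- NULL
  ft
}

.parseFeatureEntry <- function(entry, id, genome_len) {
  header <- strsplit(entry[1], "\\s+")[[1]]
  key <- header[1]
  if (key %in% c("source", "STS", "repeat_region")) return(NULL)
  if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature"))
    return(NULL)
  ## location may continue onto following lines until a '/' qualifier
  body <- entry[-1]
  qstart <- grep("^/", body)[1]
  loc <- paste(c(header[-1],
                 if (is.na(qstart)) body else body[seq_len(qstart - 1)]),
               collapse = "")
  quals <- .parseQualifiers(if (is.na(qstart)) character()
                            else body[qstart:length(body)])
  pos <- .parseLocation(loc, id, key, genome_len)
  gene <- quals[["gene"]]
  product <- quals[["product"]]
  note <- quals[["note"]]
  anticodon <- .anticodonFromQualifier(quals[["anticodon"]])
  label <- if (!is.null(gene)) gene else if (!is.null(product)) product
           else if (!is.null(note)) note else key
  if (key == "D-loop" ||
      (key == "misc_feature" &&
       any(grepl("control region|A\\+?T[- ]rich", c(product, note),
                 ignore.case = TRUE)))) {
    nm <- list(name = "CR", kind = "CR", mapped = TRUE)
  } else if (key == "misc_feature") {
    nm <- list(name = label, kind = "other", mapped = FALSE)
  } else {
    nm <- canonicalGeneName(label, product = product,
                            anticodon = anticodon)
    if (key == "CDS" && nm$kind == "other") nm$kind <- "other"
  }
  data.frame(name = nm$name, kind = nm$kind, strand = pos$strand,
             start = pos$start, end = pos$end,
             anticodon = if (is.null(anticodon)) NA_character_
                         else toupper(anticodon),
             from_gene_key = (key == "gene"),
             stringsAsFactors = FALSE)
}

.parseQualifiers <- function(lines) {
  if (!length(lines)) return(list())
  ## re-join qualifiers split across lines
  joined <- character()
  for (l in lines) {
    if (grepl("^/", l) || !length(joined)) joined <- c(joined, l)
    else joined[length(joined)] <- paste(joined[length(joined)], l)
  }
  out <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q))[[1]]
    if (length(m)) out[[m[2]]] <- m[3]
  }
  out
}

.anticodonFromQualifier <- function(q) {
  if (is.null(q)) return(NULL)
  m <- regmatches(q, regexec("seq:([A-Za-z]{3})", q))[[1]]
  if (length(m)) return(m[2])
  if (grepl("^[A-Za-z]{3}$", q)) return(q)
  NULL
}

.parseLocation <- function(loc, id, key, genome_len) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    seg <- lapply(parts, .parseSpan, id = id, key = key)
    ## origin-wrapping join: ... x..L, 1..y ...
    if (length(seg) == 2 && seg[[1]]$end == genome_len &&
        seg[[2]]$start == 1L)
      return(list(start = seg[[1]]$start,
                  end = genome_len + seg[[2]]$end, strand = strand))
    stop("record ", id, ": unsupported join location for ", key,
         ": ", loc)
  }
  s <- .parseSpan(loc, id, key)
  list(start = s$start, end = s$end, strand = strand)
}

.parseSpan <- function(span, id, key) {
  m <- regmatches(span, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", span))[[1]]
  if (!length(m))
    stop("record ", id, ": malformed location for feature ", key,
         ": ", span)
  start <- as.integer(m[2])
  end <- if (nzchar(m[4])) as.integer(m[4]) else start
  list(start = start, end = end)
}

## Assign an implicit control region: the largest unannotated gap of a
## fully annotated circular record (typically between rrnS and trnI).
.ensureControlRegion <- function(g) {
  ft <- features(g)
  n_genes <- sum(ft$kind %in% c("PCG", "tRNA", "rRNA"))
  if (any(ft$kind == "CR")) {
    if (n_genes >= 37 && sum(ft$kind == "CR") > 1)
      warning(genomeId(g), ": more than one control-region feature",
              call. = FALSE)
    return(g)
  }
  if (n_genes < 37) {
    if (n_genes > 0)
      warning(genomeId(g), ": no control region annotated on a ",
              "partially annotated record", call. = FALSE)
    return(g)
  }
  L <- genomeLength(g)
  cov <- logical(L)
  for (i in seq_len(nrow(ft))) {
    pos <- seq(ft$start[i], ft$end[i])
    cov[(pos - 1L) %% L + 1L] <- TRUE
  }
  if (all(cov)) {
    warning(genomeId(g), ": no control region and no unannotated gap",
            call. = FALSE)
    return(g)
  }
  ## find maximal uncovered runs on the circle
  r <- rle(cov[c(which.max(cov):L, seq_len(which.max(cov) - 1L))])
  offset <- which.max(cov) - 1L
  ends_rel <- cumsum(r$lengths)
  starts_rel <- ends_rel - r$lengths + 1L
  gaps <- which(!r$values)
  k <- gaps[which.max(r$lengths[gaps])]
  gstart <- (starts_rel[k] + offset - 1L) %% L + 1L
  glen <- r$lengths[k]
  gend <- gstart + glen - 1L  # may exceed L: wrap
  warning(genomeId(g), ": control region assigned to the largest ",
          "unannotated gap (", glen, " bp)", call. = FALSE)
  ft2 <- rbind(ft, data.frame(name = "CR", kind = "CR", strand = "+",
                              start = gstart, end = gend,
                              anticodon = NA_character_,
                              stringsAsFactors = FALSE))
  ft2 <- ft2[order(ft2$start, ft2$end), , drop = FALSE]
  Mitogenome(genomeId(g), organism = organism(g),
             circular = isCircular(g),
             sequence = as.character(genomeSequence(g)), features = ft2)
}

TRNA_PRODUCT <- local({
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  function(name) paste0("tRNA-", aa3[[substr(name, 4, 4)]])
})

PCG_PRODUCT <- c(
  ND1 = "NADH dehydrogenase subunit 1", ND2 = "NADH dehydrogenase subunit 2",
  ND3 = "NADH dehydrogenase subunit 3", ND4 = "NADH dehydrogenase subunit 4",
  ND4L = "NADH dehydrogenase subunit 4L",
  ND5 = "NADH dehydrogenase subunit 5", ND6 = "NADH dehydrogenase subunit 6",
  COI = "cytochrome c oxidase subunit I",
  COII = "cytochrome c oxidase subunit II",
  COIII = "cytochrome c oxidase subunit III",
  ATP6 = "ATP synthase F0 subunit 6", ATP8 = "ATP synthase F0 subunit 8",
  CYTB = "cytochrome b")

#' Write Mitogenome objects as a GenBank flat file
#'
#' Emits a minimal, re-readable GenBank record per genome: LOCUS,
#' DEFINITION/SOURCE, a feature table (CDS for protein-coding genes,
#' tRNA with anticodon, rRNA, D-loop for the control region,
#' misc_feature otherwise), and the ORIGIN sequence block.
#' \code{readGenBank(writeGenBank(g))} reproduces the feature table and
#' sequence exactly.
#'
#' @param genomes a \code{Mitogenome} or list of them.
#' @param path output file; when \code{NULL} the lines are returned.
#' @return Invisibly (or visibly when \code{path} is NULL) the lines.
#' @export
writeGenBank <- function(genomes, path = NULL) {
  if (is(genomes, "Mitogenome")) genomes <- list(genomes)
  lines <- unlist(lapply(genomes, .formatGenBankRecord))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

.formatGenBankRecord <- function(g) {
  L <- genomeLength(g)
  topo <- if (isCircular(g)) "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %5d bp    DNA     %-8s INV", genomeId(g),
            L, topo),
    sprintf("DEFINITION  %s mitochondrion, complete genome.",
            if (is.na(organism(g))) genomeId(g) else organism(g)),
    sprintf("ACCESSION   %s", genomeId(g)),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s",
            if (is.na(organism(g))) "." else organism(g)),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    sprintf("                     /organism=\"%s\"",
            if (is.na(organism(g))) "." else organism(g)),
    "                     /organelle=\"mitochondrion\""
  )
  ft <- features(g)
  for (i in seq_len(nrow(ft))) {
    out <- c(out, .formatFeature(ft[i, ], L))
  }
  out <- c(out, "ORIGIN", .formatOrigin(as.character(genomeSequence(g))),
           "//")
  out
}

.formatFeature <- function(f, L) {
  loc <- if (f$end <= L) sprintf("%d..%d", f$start, f$end)
         else sprintf("join(%d..%d,1..%d)", f$start, L, f$end - L)
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                CR = "D-loop", "misc_feature")
  out <- sprintf("     %-15s %s", key, loc)
  q <- sprintf("                     /gene=\"%s\"", f$name)
  out <- c(out, q)
  if (f$kind == "PCG")
    out <- c(out, sprintf("                     /product=\"%s\"",
                          PCG_PRODUCT[[f$name]]),
             "                     /transl_table=5")
  if (f$kind == "tRNA") {
    out <- c(out, sprintf("                     /product=\"%s\"",
                          TRNA_PRODUCT(f$name)))
    if (!is.na(f$anticodon))
      out <- c(out, sprintf(
        "                     /anticodon=(pos:complement(0..0),aa:%s,seq:%s)",
        sub("tRNA-", "", TRNA_PRODUCT(f$name)), tolower(f$anticodon)))
  }
  if (f$kind == "rRNA")
    out <- c(out, sprintf("                     /product=\"%s\"",
                          if (f$name == "rrnL") "16S ribosomal RNA"
                          else "12S ribosomal RNA"))
  out
}

.formatOrigin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1))
}

#' Write per-component FASTA
#'
#' Exports the reading-strand sequence of every feature of the given
#' kinds as FASTA, one entry per feature, headers
#' \code{<genome_id>|<gene>}.
#'
#' @param genome a \code{Mitogenome}; @param path output file.
#' @param kinds feature kinds to export.
#' @export
writeComponentFasta <- function(genome, path,
                                kinds = c("PCG", "tRNA", "rRNA", "CR")) {
  ft <- featuresOfKind(genome, kinds)
  seqs <- vapply(seq_len(nrow(ft)), function(i)
    featureSequence(genome, ft[i, , drop = FALSE]), character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0(genomeId(genome), "|", ft$name)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a TSV feature table
#'
#' Columns: genome_id, name, kind, strand, start, end, length.
#'
#' @param genomes list of \code{Mitogenome}; @param path output file.
#' @return The table, invisibly.
#' @export
writeFeatureTable <- function(genomes, path = NULL) {
  if (is(genomes, "Mitogenome")) genomes <- list(genomes)
  tabs <- lapply(genomes, function(g) {
    ft <- features(g)
    data.frame(genome_id = genomeId(g), name = ft$name, kind = ft$kind,
               strand = ft$strand, start = ft$start, end = ft$end,
               length = ft$end - ft$start + 1L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
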