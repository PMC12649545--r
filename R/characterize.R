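#' Run the full characterization pipeline over a set of genomes
#'
#' Executes every analysis stage on one or more annotated mitogenomes
#' and writes the report bundle as tab-separated tables (UTF-8, header
#' row): feature table, per-component composition, panel summary,
#' per-codon counts with RSCU, per-profile codon-usage indices,
#' neutrality fits, PR2 coordinates, junction inventory, boundary
#' codons, plus a similarity ranking when a reference is named, a run
#' log, and a machine-readable warnings file. Numeric outputs carry
#' full precision plus rounded display columns (percentages to 1
#' decimal, skews to 3).
#'
#' @param inputs character vector of GenBank file paths, or a list of
#'   \code{Mitogenome} objects.
#' @param outDir output directory (created if needed).
#' @param reference optional genome id to rank the others against.
#' @param mode similarity mode, "nucleotide" or "protein".
#' @param tableId genetic-code table (default 5).
#' @return Invisibly, a list with the tables and the per-genome parse
#'   failures; files are written under \code{outDir}.
#' @export
runCharacterize <- function(inputs, outDir, reference = NULL,
                            mode = "nucleotide", tableId = 5L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  code <- mitoGeneticCode(tableId)
  warnings_log <- list()
  note <- function(genome, stage, msg)
    warnings_log[[length(warnings_log) + 1L]] <<-
      list(genome = genome, stage = stage, message = msg)

  failures <- character()
  if (is.character(inputs)) {
    genomes <- list()
    for (f in inputs) {
      gs <- tryCatch(
        withCallingHandlers(readGenBank(f), warning = function(w) {
          note(f, "read", conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
        error = function(e) {
          failures <<- c(failures, paste0(f, ": ", conditionMessage(e)))
          NULL
        })
      genomes <- c(genomes, gs)
    }
  } else genomes <- inputs
  if (!length(genomes)) stop("no parseable genomes")
  ids <- vapply(genomes, genomeId, character(1))

  capture <- function(genome, stage, expr)
    withCallingHandlers(expr, warning = function(w) {
      note(genome, stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  tsv <- function(tab, file) {
    utils::write.table(tab, file.path(outDir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  }

  ## features + composition
  feat <- tsv(writeFeatureTable(genomes), "features.tsv")
  profiles <- lapply(seq_along(genomes), function(i)
    capture(ids[i], "composition", componentProfile(genomes[[i]])))
  comp <- writeCompositionTable(do.call(rbind, profiles))
  tsv(comp, "composition.tsv")
  tsv(panelSummary(genomes, profiles = profiles), "panel_summary.tsv")

  ## codon usage: per-gene and pooled profiles per genome
  codon_rows <- list(); index_rows <- list(); neut_points <- list()
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    seqs <- pcgSequences(g)
    profs <- c(lapply(names(seqs), function(nm)
      codonUsageProfile(seqs[[nm]], scope = nm, code = code)),
      list(codonUsageProfile(unname(seqs), scope = "all-PCGs",
                             code = code)))
    for (pr in profs) {
      cnt <- pr$codon_counts
      rs <- pr$rscu
      codon_rows[[length(codon_rows) + 1L]] <- data.frame(
        genome_id = ids[i], scope = pr$scope, codon = names(cnt),
        aa = unname(code$aa[names(cnt)]), count = as.integer(cnt),
        rscu = unname(rs[names(cnt)]), stringsAsFactors = FALSE)
      if (length(attr(pr$enc, "imputed")))
        note(ids[i], "enc", paste0(pr$scope, ": ENC class imputed (",
             paste(attr(pr$enc, "imputed"), collapse = ","), ")"))
      index_rows[[length(index_rows) + 1L]] <- data.frame(
        genome_id = ids[i], scope = pr$scope,
        enc = as.numeric(pr$enc), gc3s = pr$thirdpos[["gc3s"]],
        enc_expected = encExpected(pr$thirdpos[["gc3s"]]),
        gc12 = pr$gc_pos[["gc12"]], gc3 = pr$gc_pos[["gc3"]],
        pr2_x = pr$pr2$x, pr2_y = pr$pr2$y,
        pr2_quadrant = pr$pr2$quadrant, stringsAsFactors = FALSE)
      if (pr$scope != "all-PCGs")
        neut_points[[length(neut_points) + 1L]] <- data.frame(
          genome_id = ids[i], gene = pr$scope,
          gc3 = pr$gc_pos[["gc3"]], gc12 = pr$gc_pos[["gc12"]])
    }
  }
  codon_tab <- do.call(rbind, codon_rows)
  index_tab <- do.call(rbind, index_rows)
  tsv(codon_tab, "codon_usage.tsv")
  tsv(index_tab, "cub_indices.tsv")
  pr2_tab <- index_tab[, c("genome_id", "scope", "pr2_x", "pr2_y",
                           "pr2_quadrant")]
  tsv(pr2_tab, "pr2.tsv")

  ## neutrality fits: 13 genes within each genome; plus across-genome
  ## fit on pooled all-PCGs points when the panel is large enough
  np <- do.call(rbind, neut_points)
  neut_rows <- list()
  for (id in ids) {
    sub <- np[np$genome_id == id, , drop = FALSE]
    if (nrow(sub) >= 3) {
      f <- neutralityFit(sub)
      neut_rows[[length(neut_rows) + 1L]] <- data.frame(
        scope = id, slope = f$slope, intercept = f$intercept, r2 = f$r2,
        n_points = f$n_points, stringsAsFactors = FALSE)
    }
  }
  allp <- index_tab[index_tab$scope == "all-PCGs", , drop = FALSE]
  if (nrow(allp) >= 3) {
    f <- neutralityFit(allp[, c("gc3", "gc12")])
    neut_rows[[length(neut_rows) + 1L]] <- data.frame(
      scope = "panel:all-PCGs", slope = f$slope, intercept = f$intercept,
      r2 = f$r2, n_points = f$n_points, stringsAsFactors = FALSE)
  }
  tsv(do.call(rbind, neut_rows), "neutrality.tsv")

  ## architecture
  junc_rows <- list(); bc_rows <- list()
  for (i in seq_along(genomes)) {
    rep <- capture(ids[i], "architecture",
                   architectureReport(genomes[[i]], code))
    jt <- rep$junctions$junctions
    junc_rows[[length(junc_rows) + 1L]] <-
      cbind(genome_id = ids[i], jt, stringsAsFactors = FALSE)
    bc_rows[[length(bc_rows) + 1L]] <-
      cbind(genome_id = ids[i], rep$boundary_codons,
            stringsAsFactors = FALSE)
  }
  tsv(do.call(rbind, junc_rows), "junctions.tsv")
  tsv(do.call(rbind, bc_rows), "boundary_codons.tsv")

  ## similarity (optional)
  sim_tab <- NULL
  if (!is.null(reference)) {
    ri <- match(reference, ids)
    if (is.na(ri)) stop("reference id not among the inputs: ", reference)
    sim_tab <- capture(reference, "similarity",
      rankAgainstReference(genomes[[ri]], genomes, mode = mode,
                           code = code))
    tsv(sim_tab, "similarity.tsv")
  }

  jsonlite::write_json(warnings_log, file.path(outDir, "warnings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_lines <- c(
    paste("mitochar", as.character(utils::packageVersion("mitochar"))),
    paste("genomes:", paste(ids, collapse = ", ")),
    paste("genetic code table:", tableId),
    if (!is.null(reference)) paste("similarity reference:", reference),
    paste("warnings:", length(warnings_log)),
    if (length(failures)) paste("FAILED:", failures))
  writeLines(log_lines, file.path(outDir, "run.log"))

  invisible(list(genomes = genomes, features = feat, composition = comp,
                 codon_usage = codon_tab, indices = index_tab,
                 similarity = sim_tab, warnings = warnings_log,
                 failures = failures))
}

#' Simulate genomes and write them with their truth records
#'
#' Wraps the synthetic-data generator: writes one GenBank file per
#' genome plus a JSON truth record.
#'
#' @param outDir output directory.
#' @param params a \code{\link{simulationParams}}.
#' @param n panel size (1 = single genome).
#' @param rates substitution rates for derived panel members.
#' @return Invisibly, the list of \code{list(genome, truth)}.
#' @export
runSimulate <- function(outDir, params = simulationParams(), n = 1L,
                        rates = c(0.01, 0.10)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sims <- if (n <= 1L) list(simulateMitogenome(params))
          else simulatePanel(params, n = n, rates = rates)
  for (s in sims) {
    id <- genomeId(s$genome)
    writeGenBank(s$genome, file.path(outDir, paste0(id, ".gb")))
    tr <- s$truth
    tr$params <- unclass(tr$params)
    tr$codon_counts <- lapply(tr$codon_counts, as.list)
    tr$base_counts <- lapply(tr$base_counts, as.list)
    jsonlite::write_json(tr, file.path(outDir, paste0(id, "_truth.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(sims)
}
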