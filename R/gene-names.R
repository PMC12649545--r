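## Canonical gene nomenclature for the 37 mitochondrial genes + CR.

PCG_NAMES <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
               "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB")

TRNA_NAMES <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL2",
                "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                "trnV")

#' The canonical order used when concatenating protein-coding genes
#' @export
PCG_CONCAT_ORDER <- c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
                      "ND3", "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")

## amino-acid 3-letter -> tRNA one-letter suffix
AA3_TO_1 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
              gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
              leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
              ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

## Leu/Ser isotypes by anticodon (standard insect arrangement):
## trnL1 reads CUN (anticodon UAG), trnL2 reads UUR (UAA),
## trnS1 reads AGN (GCU), trnS2 reads UCN (UGA).
LEUSER_BY_ANTICODON <- c(L.TAG = "trnL1", L.TAA = "trnL2",
                         S.GCT = "trnS1", S.TGA = "trnS2")

.squash <- function(x) gsub("[^a-z0-9]", "", tolower(x))

PCG_SYNONYMS <- local({
  syn <- c(
    nd1 = "ND1", nad1 = "ND1", nadh1 = "ND1",
    nd2 = "ND2", nad2 = "ND2", nadh2 = "ND2",
    nd3 = "ND3", nad3 = "ND3", nadh3 = "ND3",
    nd4 = "ND4", nad4 = "ND4", nadh4 = "ND4",
    nd4l = "ND4L", nad4l = "ND4L", nadh4l = "ND4L",
    nd5 = "ND5", nad5 = "ND5", nadh5 = "ND5",
    nd6 = "ND6", nad6 = "ND6", nadh6 = "ND6",
    coi = "COI", co1 = "COI", cox1 = "COI", coxi = "COI",
    coii = "COII", co2 = "COII", cox2 = "COII", coxii = "COII",
    coiii = "COIII", co3 = "COIII", cox3 = "COIII", coxiii = "COIII",
    atp6 = "ATP6", atpase6 = "ATP6", atp8 = "ATP8", atpase8 = "ATP8",
    cytb = "CYTB", cob = "CYTB", cb = "CYTB"
  )
  names(syn) <- .squash(names(syn))
  syn
})

RNA_SYNONYMS <- local({
  syn <- c(
    rrnl = "rrnL", lrrna = "rrnL", "16s" = "rrnL", "16srrna" = "rrnL",
    "16sribosomalrna" = "rrnL", largesubunitribosomalrna = "rrnL",
    rrn16 = "rrnL",
    rrns = "rrnS", srrna = "rrnS", "12s" = "rrnS", "12srrna" = "rrnS",
    "12sribosomalrna" = "rrnS", smallsubunitribosomalrna = "rrnS",
    rrn12 = "rrnS"
  )
  names(syn) <- .squash(names(syn))
  syn
})

CR_SYNONYMS <- c("dloop", "controlregion", "atrichregion", "cr",
                 "atcontrolregion", "putativecontrolregion")

.trna_from_label <- function(lab, anticodon = NA_character_) {
  ## Case matters here: "trnA" is the Ala gene symbol while "tRNA-Ala"
  ## uses the prefix form, and both lowercase to "trna...".
  one <- NULL; suffix <- ""
  m <- regmatches(lab, regexec("^trn([A-Z])([12]?)", lab))[[1]]
  if (length(m)) { one <- m[2]; suffix <- m[3] }
  low <- tolower(lab)
  if (is.null(one)) {
    m <- regmatches(low, regexec("^trna[-_ ]?([a-z]{3})[^0-9]*([12]?)",
                                 low))[[1]]
    if (length(m) && m[2] %in% names(AA3_TO_1)) {
      one <- AA3_TO_1[[m[2]]]; suffix <- m[3]
    }
  }
  if (is.null(one)) {
    m <- regmatches(low, regexec("^trn([a-z])([12]?)$", low))[[1]]
    if (length(m)) { one <- toupper(m[2]); suffix <- m[3] }
  }
  if (is.null(one) || !one %in% AA3_TO_1) return(NULL)
  if (one %in% c("L", "S")) {
    if (!is.na(anticodon) && nzchar(anticodon)) {
      ac <- chartr("Uu", "Tt", toupper(anticodon))
      key <- paste0(one, ".", ac)
      if (key %in% names(LEUSER_BY_ANTICODON))
        return(LEUSER_BY_ANTICODON[[key]])
    }
    if (suffix %in% c("1", "2")) return(paste0("trn", one, suffix))
    ## anticodon embedded in the label, e.g. trnL(uaa) or trnS-tga
    for (key in names(LEUSER_BY_ANTICODON)) {
      ac3 <- tolower(substr(key, 3, 5))
      acu <- chartr("t", "u", ac3)
      if (substr(key, 1, 1) == one &&
          grepl(paste0("[^a-z](", ac3, "|", acu, ")([^a-z]|$)"),
                paste0(" ", low)))
        return(LEUSER_BY_ANTICODON[[key]])
    }
    return(NULL)  # unresolvable isotype
  }
  paste0("trn", one)
}

#' Canonicalize a gene annotation label
#'
#' Maps the many synonyms seen in deposited mitogenome records (COX1 /
#' CO1 / COI; cob / CYTB; 16S / l-rRNA / rrnL; D-loop / control region /
#' CR; tRNA-Leu with an anticodon ...) onto the package's canonical
#' 37-gene nomenclature, resolving the duplicated Leu and Ser tRNA
#' isotypes by anticodon when one is given, else by a 1/2 suffix or an
#' anticodon embedded in the label.
#'
#' @param raw annotation label (gene qualifier).
#' @param product free-text product qualifier, used as fallback.
#' @param anticodon anticodon 3-mer (DNA or RNA alphabet) or \code{NA}.
#' @return list with \code{name} (canonical symbol, or the raw label
#'   when unmappable), \code{kind} (PCG/tRNA/rRNA/CR/other) and
#'   \code{mapped} (logical).
#' @examples
#' canonicalGeneName("cox1")                        # COI, PCG
#' canonicalGeneName("tRNA-Leu", anticodon = "UAA") # trnL2, tRNA
#' canonicalGeneName("D-loop")                      # CR
#' @export
canonicalGeneName <- function(raw, product = NA_character_,
                              anticodon = NA_character_) {
  stopifnot(nzchar(raw))
  for (lab in c(raw, product)) {
    if (is.na(lab) || !nzchar(lab)) next
    sq <- .squash(lab)
    if (sq %in% names(PCG_SYNONYMS))
      return(list(name = PCG_SYNONYMS[[sq]], kind = "PCG", mapped = TRUE))
    if (sq %in% names(RNA_SYNONYMS))
      return(list(name = RNA_SYNONYMS[[sq]], kind = "rRNA", mapped = TRUE))
    if (sq %in% CR_SYNONYMS)
      return(list(name = "CR", kind = "CR", mapped = TRUE))
    if (grepl("^trn", sq)) {
      nm <- .trna_from_label(lab, anticodon)
      if (!is.null(nm)) return(list(name = nm, kind = "tRNA", mapped = TRUE))
    }
    ## product-style long names
    if (grepl("cytochromecoxidasesubunit(i{1,3}|[123])$", sq)) {
      n <- sub(".*subunit", "", sq)
      idx <- c(i = 1, ii = 2, iii = 3)[n]
      if (is.na(idx)) idx <- as.integer(n)
      return(list(name = c("COI", "COII", "COIII")[idx], kind = "PCG",
                  mapped = TRUE))
    }
    if (grepl("nadhdehydrogenasesubunit", sq)) {
      n <- toupper(sub(".*subunit", "", sq))
      return(list(name = paste0("ND", n), kind = "PCG", mapped = TRUE))
    }
    if (grepl("atpsynthase.*subunit([68])$", sq))
      return(list(name = paste0("ATP", sub(".*subunit", "", sq)),
                  kind = "PCG", mapped = TRUE))
    if (grepl("cytochromeb", sq))
      return(list(name = "CYTB", kind = "PCG", mapped = TRUE))
  }
  warning("unmappable gene label: ", raw, call. = FALSE)
  list(name = raw, kind = "other", mapped = FALSE)
}
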