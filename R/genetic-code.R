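# Genetic-code helpers shared by the transcript, variant and simulation layers.
# The code table itself comes from Biostrings (standard table 1); everything
# built on top of it (codon translation with N -> X, the single-base change
# classifier, the enumeration table the simulator samples from) is local.

.gv <- new.env(parent = emptyenv())

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

.genetic_code <- function() {
  if (is.null(.gv$code)) .gv$code <- Biostrings::GENETIC_CODE
  .gv$code
}

.sense_codons <- function() {
  if (is.null(.gv$sense)) {
    .gv$sense <- setdiff(names(.genetic_code()), .STOP_CODONS)
  }
  .gv$sense
}

#' Translate codons to amino acids
#'
#' Standard genetic code (translation table 1).  Codons containing any
#' character outside `A/C/G/T` (e.g. `N`) translate to `"X"`; stop codons
#' translate to `"*"`.
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector of single amino-acid letters.
#' @keywords internal
translate_codons <- function(codons) {
  aa <- unname(.genetic_code()[toupper(codons)])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate coding sequences
#'
#' Translates each CDS string with the standard genetic code.  A codon
#' containing `N` (or any non-`ACGT` character) becomes `'X'`; stop codons
#' become `'*'` (a CDS that retains its terminal stop therefore ends in
#' `'*'`).
#'
#' @param cds character vector of CDS strings; each length must be a
#'   multiple of 3.
#' @return character vector of protein strings.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
translate_cds <- function(cds) {
  vapply(as.character(cds), function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) stop("CDS length not a multiple of 3: ", n)
    if (n == 0L) return("")
    idx <- seq(1L, n, 3L)
    paste(translate_codons(substring(toupper(s), idx, idx + 2L)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (IUPAC letters allowed).
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.complement_base <- function(b) chartr("ACGTNacgtn", "TGCANtgcan", b)

#' Classify a single-base codon change
#'
#' Core effect classifier: substitutes `alt` into `codon` at `codon_pos`
#' (0-based) and compares translations.  Effects: `synonymous` (same amino
#' acid, not stop), `missense`, `nonsense` (sense codon to stop), or
#' `unassessable` (reference stop codon, or any ambiguous base).
#'
#' Classification is done by direct translation of both codons, not by a
#' lookup of precomputed changes, so it can be checked against an
#' independent exhaustive enumeration.
#'
#' @param codon character vector of reference codons.
#' @param codon_pos integer vector, 0-based position within the codon (0..2).
#' @param alt character vector of alternate bases.
#' @return data.frame with columns `ref_aa`, `alt_aa`, `alt_codon`, `effect`.
#' @export
snv_effect <- function(codon, codon_pos, alt) {
  codon <- toupper(as.character(codon))
  alt <- toupper(as.character(alt))
  stopifnot(all(codon_pos %in% 0:2))
  ref_aa <- translate_codons(codon)
  alt_codon <- paste0(
    substring(codon, 1L, codon_pos),
    alt,
    substring(codon, codon_pos + 2L, 3L)
  )
  alt_aa <- translate_codons(alt_codon)
  effect <- rep("missense", length(ref_aa))
  effect[ref_aa == alt_aa & ref_aa != "*"] <- "synonymous"
  effect[alt_aa == "*" & ref_aa != "*"] <- "nonsense"
  effect[ref_aa == "*" | ref_aa == "X" | alt_aa == "X"] <- "unassessable"
  data.frame(ref_aa = ref_aa, alt_aa = alt_aa, alt_codon = alt_codon,
             effect = effect, stringsAsFactors = FALSE)
}

# Enumeration of all 576 single-base codon changes, with effect labels.
# Used by the simulator to sample sites of a target class; the annotation
# path never reads this table.
codon_change_table <- function() {
  if (!is.null(.gv$changes)) return(.gv$changes)
  codons <- names(.genetic_code())
  rows <- vector("list", 576L)
  k <- 0L
  for (cod in codons) {
    for (pos in 0:2) {
      ref <- substr(cod, pos + 1L, pos + 1L)
      for (alt in setdiff(.BASES, ref)) {
        k <- k + 1L
        rows[[k]] <- c(cod, pos, ref, alt)
      }
    }
  }
  m <- do.call(rbind, rows)
  tab <- data.frame(codon = m[, 1], codon_pos = as.integer(m[, 2]),
                    ref = m[, 3], alt = m[, 4], stringsAsFactors = FALSE)
  eff <- snv_effect(tab$codon, tab$codon_pos, tab$alt)
  tab <- cbind(tab, eff)
  .gv$changes <- tab
  tab
}
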