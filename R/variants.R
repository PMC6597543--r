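# Variant filtering, effect annotation on coding regions, and the three
# SNV-composition indices (syn/kb, nonsynonymous fraction, nonsense
# fraction).

#' Read SNVs from a VCF file
#'
#' Parses with `vcfR` and applies [filter_snvs()].  The first sample column
#' supplies genotypes.
#'
#' @param path VCF file path.
#' @param mq_threshold RMS mapping-quality threshold; records are retained
#'   only when `MQ > mq_threshold` (strict), default 30.
#' @return see [filter_snvs()].
#' @export
read_vcf_snvs <- function(path, mq_threshold = 30) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix)) || nrow(fix) == 0L) {
    records <- data.frame(transcript_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          mq = numeric(0), gt = character(0),
                          stringsAsFactors = FALSE)
    return(filter_snvs(records, mq_threshold))
  }
  mq <- suppressWarnings(vcfR::extract.info(vcf, "MQ", as.numeric = TRUE))
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT")[, 1L],
                 error = function(e) rep(NA_character_, nrow(fix)))
  records <- data.frame(
    transcript_id = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    mq = mq,
    gt = unname(gt),
    stringsAsFactors = FALSE
  )
  filter_snvs(records, mq_threshold)
}

#' Filter variant records to high-confidence biallelic SNVs
#'
#' Retains biallelic single-nucleotide records with RMS mapping quality
#' strictly above `mq_threshold` and a called diploid genotype; zygosity is
#' read from the genotype (`0/1`-like values are heterozygous, `1/1`
#' homozygous).  Indels, multiallelic records, reference-only genotypes,
#' half calls and missing genotypes are dropped and counted.
#'
#' @param records data.frame with columns `transcript_id`, `pos`, `ref`,
#'   `alt`, `mq`, `gt`.
#' @param mq_threshold strict lower bound on MQ (default 30).
#' @return data.frame of retained SNVs (`transcript_id`, `pos`, `ref`,
#'   `alt`, `zygosity`, `mq`), with a `counts` attribute recording how many
#'   records each filter removed.
#' @export
filter_snvs <- function(records, mq_threshold = 30) {
  n <- nrow(records)
  is_nt <- function(x) nchar(x) == 1L & toupper(x) %in% .BASES
  snv <- is_nt(records$ref) & is_nt(records$alt)
  multi <- grepl(",", records$alt, fixed = TRUE)
  gt <- sub("\\|", "/", as.character(records$gt))
  zyg <- rep(NA_character_, n)
  zyg[gt %in% c("0/1", "1/0")] <- "het"
  zyg[gt == "1/1"] <- "hom"
  refonly <- !is.na(gt) & gt == "0/0"
  missing_gt <- is.na(zyg) & !refonly
  mq_ok <- !is.na(records$mq) & records$mq > mq_threshold
  keep <- snv & !multi & !is.na(zyg) & mq_ok
  out <- data.frame(
    transcript_id = records$transcript_id[keep],
    pos = records$pos[keep],
    ref = toupper(records$ref[keep]),
    alt = toupper(records$alt[keep]),
    zygosity = zyg[keep],
    mq = records$mq[keep],
    stringsAsFactors = FALSE
  )
  if (any(out$ref == out$alt)) stop("malformed record: ref equals alt")
  attr(out, "counts") <- list(
    n_records = n,
    n_not_snv = sum(!snv | multi),
    n_low_mq = sum(snv & !multi & !mq_ok),
    n_missing_gt = sum(missing_gt & snv & !multi),
    n_ref_only = sum(refonly & snv & !multi),
    n_retained = nrow(out)
  )
  out
}

#' Annotate SNVs against coding regions
#'
#' Maps each SNV onto its transcript's coding region, substitutes the
#' alternate base into the reference codon (alleles are complemented for
#' minus-strand CDS) and classifies the effect by comparing translations:
#' `synonymous`, `missense`, `nonsense`, `noncoding` (outside the coding
#' span, including the terminal stop codon), or `unassessable` (codon
#' containing `N`, or a reference-allele mismatch with the assembly).
#'
#' @param snvs data.frame from [filter_snvs()].
#' @param regions data.frame from [find_coding_regions()].
#' @param known_ids optional character vector of all transcript IDs in the
#'   assembly; SNVs on IDs outside it raise an error.  SNVs on known
#'   transcripts without a retained coding region are `noncoding`.
#' @return the `snvs` data.frame with added columns `cds_offset`,
#'   `codon_index` (0-based), `codon_pos` (0..2), `ref_aa`, `alt_aa`,
#'   `effect`.
#' @export
annotate_snvs <- function(snvs, regions, known_ids = NULL) {
  if (!is.null(known_ids)) {
    unknown <- setdiff(unique(snvs$transcript_id), known_ids)
    if (length(unknown)) {
      stop("VCF references transcript(s) absent from the assembly: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  i <- match(snvs$transcript_id, regions$transcript_id)
  strand <- regions$strand[i]
  start <- regions$start[i]
  end <- regions$end[i]
  plen <- regions$protein_len[i]
  tx_len <- regions$tx_len[i]
  beyond <- !is.na(tx_len) & snvs$pos > tx_len
  if (any(beyond)) {
    stop("SNV position beyond transcript length for ",
         paste(utils::head(unique(snvs$transcript_id[beyond]), 5L),
               collapse = ", "))
  }
  pos0 <- snvs$pos - 1L
  off <- ifelse(strand == "+", pos0 - start, (end - 1L) - pos0)
  coding <- !is.na(off) & off >= 0L & off < 3L * plen
  n <- nrow(snvs)
  out <- snvs
  out$cds_offset <- ifelse(coding, off, NA_integer_)
  out$codon_index <- ifelse(coding, off %/% 3L, NA_integer_)
  out$codon_pos <- ifelse(coding, off %% 3L, NA_integer_)
  out$ref_aa <- NA_character_
  out$alt_aa <- NA_character_
  out$effect <- "noncoding"
  if (any(coding)) {
    j <- which(coding)
    ref_or <- ifelse(strand[j] == "-", .complement_base(out$ref[j]), out$ref[j])
    alt_or <- ifelse(strand[j] == "-", .complement_base(out$alt[j]), out$alt[j])
    cstart <- 3L * out$codon_index[j] + 1L
    codon <- substring(regions$cds[i[j]], cstart, cstart + 2L)
    eff <- snv_effect(codon, out$codon_pos[j], alt_or)
    # the assembly base must match the VCF reference allele
    obs <- substring(codon, out$codon_pos[j] + 1L, out$codon_pos[j] + 1L)
    mismatch <- obs != ref_or & obs %in% .BASES
    eff$effect[mismatch] <- "unassessable"
    if (any(mismatch)) {
      warning(sum(mismatch), " SNV(s) whose reference allele disagrees ",
              "with the assembly were marked unassessable")
    }
    out$ref_aa[j] <- eff$ref_aa
    out$alt_aa[j] <- eff$alt_aa
    out$effect[j] <- eff$effect
  }
  stopifnot(nrow(out) == n)
  out
}

#' Per-transcript SNV composition summary
#'
#' Counts heterozygous coding SNVs per transcript by effect class and
#' derives the per-transcript indices.  Only `zygosity == "het"` SNVs enter
#' the counts (homozygous records are assembly-vs-individual differences).
#' Transcripts with no coding heterozygous SNV appear with zero counts and
#' `NA` fractions.
#'
#' @param annotated data.frame from [annotate_snvs()].
#' @param regions data.frame from [find_coding_regions()].
#' @return data.frame with one row per transcript in `regions`:
#'   `transcript_id`, `gene_id`, `cds_len_bp`, `n_syn`, `n_missense`,
#'   `n_nonsense`, `n_total`, `syn_per_kb`, `nonsyn_fraction`,
#'   `nonsense_fraction`.
#' @export
summarize_transcripts <- function(annotated, regions) {
  het <- annotated[annotated$zygosity == "het" &
                     annotated$effect %in% c("synonymous", "missense",
                                             "nonsense"), , drop = FALSE]
  count_by <- function(eff) {
    tab <- table(factor(het$transcript_id[het$effect == eff],
                        levels = regions$transcript_id))
    as.integer(tab)
  }
  out <- data.frame(
    transcript_id = regions$transcript_id,
    gene_id = regions$gene_id,
    cds_len_bp = 3L * regions$protein_len,
    n_syn = count_by("synonymous"),
    n_missense = count_by("missense"),
    n_nonsense = count_by("nonsense"),
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_syn + out$n_missense + out$n_nonsense
  n_nonsyn <- out$n_missense + out$n_nonsense
  out$syn_per_kb <- 1000 * out$n_syn / out$cds_len_bp
  out$nonsyn_fraction <- ifelse(out$n_total > 0, n_nonsyn / out$n_total, NA)
  out$nonsense_fraction <- ifelse(n_nonsyn > 0, out$n_nonsense / n_nonsyn, NA)
  out
}

#' Per-specimen SNV indices
#'
#' Aggregates per-transcript summaries to the three specimen-level SNV
#' indices by unweighted means over transcripts.  The transcript universe
#' is restricted to genes with plant-database homology when `classes` is
#' supplied (labels `duplicated`/`singleton`); `syn_per_kb` averages over
#' every universe transcript (zero-SNV transcripts contribute 0), while the
#' two fraction indices average over transcripts carrying at least one
#' coding heterozygous SNV (the nonsense fraction additionally needs at
#' least one nonsynonymous SNV to be defined).
#'
#' @param summaries data.frame from [summarize_transcripts()].
#' @param classes optional data.frame from [classify_duplication()]; when
#'   given, only genes not labelled `excluded_no_plant_homology` are used.
#'   Pass a `classes` restricted to `label == "singleton"` rows to
#'   recompute the indices excluding candidate paralogs.
#' @return one-row data.frame: `n_transcripts`, `n_with_snv`, `syn_per_kb`,
#'   `nonsyn_fraction`, `nonsense_fraction`.
#' @export
specimen_indices <- function(summaries, classes = NULL) {
  s <- summaries
  if (!is.null(classes)) {
    keep_genes <- classes$gene_id[classes$label %in% c("duplicated",
                                                       "singleton")]
    s <- s[s$gene_id %in% keep_genes, , drop = FALSE]
  }
  with_snv <- s[s$n_total > 0, , drop = FALSE]
  data.frame(
    n_transcripts = nrow(s),
    n_with_snv = nrow(with_snv),
    syn_per_kb = if (nrow(s)) mean(s$syn_per_kb) else NA_real_,
    nonsyn_fraction = if (nrow(with_snv)) mean(with_snv$nonsyn_fraction)
                      else NA_real_,
    nonsense_fraction = if (any(!is.na(with_snv$nonsense_fraction)))
      mean(with_snv$nonsense_fraction, na.rm = TRUE) else NA_real_
  )
}
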