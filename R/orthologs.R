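# Interspecies layer: reciprocal-best-hit ortholog pairing (> 80% protein
# identity), species-specific homozygous substitution discovery with
# heterozygous loci masked out, and deleterious-substitution fractions
# computed with each species reciprocally used as the query.

#' Ingest one species' integrated reference
#'
#' Takes the species' integrated transcript assembly (all specimens pooled)
#' plus its pooled VCF, keeps the longest coding sequence per gene, and
#' builds a per-position heterozygosity mask from every heterozygous record
#' in the pooled calls (no mapping-quality filter on the mask: it is an
#' exclusion list, so masking conservatively is preferred).
#'
#' @param fasta path to the integrated FASTA, or a named `DNAStringSet`.
#' @param vcf path to the pooled VCF, or a pre-filtered SNV data.frame
#'   (see [filter_snvs()]); `NULL` means no variant data (empty mask).
#' @param min_protein_len retention filter, default 50 aa.
#' @return list with `regions` (longest-CDS-per-gene coding regions, see
#'   [find_coding_regions()]) and `mask` (data.frame `transcript_id`,
#'   `pos` of heterozygous sites).
#' @export
build_integrated_reference <- function(fasta, vcf = NULL,
                                       min_protein_len = 50L) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  longest <- select_longest_isoform(seqs)
  regions <- find_coding_regions(longest, min_protein_len)
  mask <- data.frame(transcript_id = character(0), pos = integer(0),
                     stringsAsFactors = FALSE)
  if (!is.null(vcf)) {
    snvs <- if (is.character(vcf)) {
      read_vcf_snvs(vcf, mq_threshold = -Inf)
    } else if ("zygosity" %in% names(vcf)) {
      vcf
    } else {
      filter_snvs(vcf, mq_threshold = -Inf)
    }
    unknown <- setdiff(unique(snvs$transcript_id), names(seqs))
    if (length(unknown)) {
      stop("pooled VCF references transcript(s) absent from the assembly: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    het <- snvs[snvs$zygosity == "het", , drop = FALSE]
    mask <- unique(data.frame(transcript_id = het$transcript_id,
                              pos = het$pos, stringsAsFactors = FALSE))
  }
  list(regions = regions, mask = mask)
}

.best_hits <- function(hits, min_identity, max_evalue) {
  qual <- hits[hits$percent_identity > min_identity &
                 hits$evalue < max_evalue &
                 hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(qual)) return(qual[0, ])
  score <- qual$percent_identity * qual$alignment_length
  ord <- order(qual$query_id, qual$evalue, -score, qual$subject_id)
  qual <- qual[ord, , drop = FALSE]
  qual[!duplicated(qual$query_id), , drop = FALSE]
}

#' Pair orthologs by reciprocal best hits
#'
#' A gene pair (a, b) is an ortholog pair when b is a's best qualifying hit
#' and a is b's, in the two direction-specific homology tables.  Qualifying
#' hits have protein identity strictly above `min_identity` (default 80)
#' and E-value below `max_evalue`; best = lowest E-value, ties broken by
#' identity x alignment length, then subject ID.
#'
#' @param hits_ab BLAST tabular data.frame, species A proteins vs B.
#' @param hits_ba the reciprocal table, B vs A.
#' @param min_identity percent-identity threshold, strict `>` (default 80).
#' @param max_evalue E-value threshold (default `1e-4`).
#' @return data.frame `gene_a`, `gene_b`, `percent_identity` (of the A->B
#'   hit).
#' @export
pair_orthologs <- function(hits_ab, hits_ba, min_identity = 80,
                           max_evalue = 1e-4) {
  .check_hits(hits_ab, "A->B hit")
  .check_hits(hits_ba, "B->A hit")
  best_ab <- .best_hits(hits_ab, min_identity, max_evalue)
  best_ba <- .best_hits(hits_ba, min_identity, max_evalue)
  m <- match(best_ab$subject_id, best_ba$query_id)
  recip <- !is.na(m) & best_ba$subject_id[m] == best_ab$query_id
  out <- data.frame(gene_a = best_ab$query_id[recip],
                    gene_b = best_ab$subject_id[recip],
                    percent_identity = best_ab$percent_identity[recip],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# transcript coordinates (1-based) covered by protein position `ppos`
# of a coding region row
.codon_tx_positions <- function(region, ppos) {
  if (region$strand == "+") {
    region$start + 3L * (ppos - 1L) + (1:3)
  } else {
    region$end - 3L * (ppos - 1L) - (2:0)
  }
}

#' Find species-specific substitutions in one ortholog pair
#'
#' Globally aligns the two proteins (BLOSUM62, affine gaps), back-projects
#' the alignment to codons, and reports gap-free codon columns where the
#' two coding sequences differ.  Codons overlapping a heterozygous position
#' in either species are excluded (species-specific *homozygous* alleles
#' only), as are codons within `gap_guard` columns of an alignment gap
#' (alignment-uncertainty guard).  Sites are classified `synonymous` or
#' `nonsynonymous` from the codon pair.
#'
#' @param region_a,region_b one-row coding-region data.frames for the two
#'   orthologs (rows of [find_coding_regions()] output).
#' @param mask_a,mask_b integer vectors of heterozygous transcript
#'   positions (1-based) for the two transcripts.
#' @param gap_guard codon columns excluded on each side of a gap
#'   (default 2).
#' @return data.frame with one row per substitution site: `pos_a`, `pos_b`
#'   (1-based protein positions), `codon_a`, `codon_b`, `aa_a`, `aa_b`,
#'   `effect`; attributes `n_masked` and `n_gap_guard` count exclusions.
#' @export
find_substitutions <- function(region_a, region_b,
                               mask_a = integer(0), mask_b = integer(0),
                               gap_guard = 2L) {
  pa <- region_a$protein
  pb <- region_b$protein
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ca <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  gap <- ca == "-" | cb == "-"
  near_gap <- rep(FALSE, length(gap))
  if (any(gap) && gap_guard > 0L) {
    for (g in which(gap)) {
      lo <- max(1L, g - gap_guard)
      hi <- min(length(gap), g + gap_guard)
      near_gap[lo:hi] <- TRUE
    }
  }
  cols <- which(!gap)
  apos <- ia[cols]
  bpos <- ib[cols]
  sa <- 3L * (apos - 1L) + 1L
  sb <- 3L * (bpos - 1L) + 1L
  codon_a <- substring(region_a$cds, sa, sa + 2L)
  codon_b <- substring(region_b$cds, sb, sb + 2L)
  differ <- codon_a != codon_b
  masked <- vapply(seq_along(cols), function(k) {
    any(.codon_tx_positions(region_a, apos[k]) %in% mask_a) ||
      any(.codon_tx_positions(region_b, bpos[k]) %in% mask_b)
  }, logical(1))
  keep <- differ & !masked & !near_gap[cols]
  aa_a <- translate_codons(codon_a[keep])
  aa_b <- translate_codons(codon_b[keep])
  assess <- !(aa_a %in% c("X", "*")) & !(aa_b %in% c("X", "*"))
  out <- data.frame(
    pos_a = apos[keep][assess], pos_b = bpos[keep][assess],
    codon_a = codon_a[keep][assess], codon_b = codon_b[keep][assess],
    aa_a = aa_a[assess], aa_b = aa_b[assess],
    effect = ifelse(aa_a[assess] == aa_b[assess], "synonymous",
                    "nonsynonymous"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_masked") <- sum(differ & masked)
  attr(out, "n_gap_guard") <- sum(differ & !masked & near_gap[cols])
  out
}

#' Find substitutions for every ortholog pair
#'
#' Runs [find_substitutions()] over a pair table, attaching transcript IDs.
#'
#' @param pairs data.frame from [pair_orthologs()] (`gene_a`, `gene_b`).
#' @param ref_a,ref_b lists from [build_integrated_reference()] for the two
#'   species.
#' @inheritParams find_substitutions
#' @return data.frame of all substitution sites with `gene_a`, `gene_b`,
#'   `transcript_a`, `transcript_b` prepended; attribute `counts` with
#'   totals of masked and gap-guarded exclusions.
#' @export
ortholog_substitutions <- function(pairs, ref_a, ref_b, gap_guard = 2L) {
  ga <- parse_trinity_id(ref_a$regions$transcript_id)$gene_id
  gb <- parse_trinity_id(ref_b$regions$transcript_id)$gene_id
  mask_split_a <- split(ref_a$mask$pos, ref_a$mask$transcript_id)
  mask_split_b <- split(ref_b$mask$pos, ref_b$mask$transcript_id)
  n_masked <- 0L
  n_guard <- 0L
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ra <- ref_a$regions[match(pairs$gene_a[k], ga), , drop = FALSE]
    rb <- ref_b$regions[match(pairs$gene_b[k], gb), , drop = FALSE]
    if (anyNA(ra$transcript_id) || anyNA(rb$transcript_id)) {
      stop("ortholog pair references gene without a coding region: ",
           pairs$gene_a[k], " / ", pairs$gene_b[k])
    }
    ma <- mask_split_a[[ra$transcript_id]]
    mb <- mask_split_b[[rb$transcript_id]]
    sites <- find_substitutions(ra, rb,
                                mask_a = if (is.null(ma)) integer(0) else ma,
                                mask_b = if (is.null(mb)) integer(0) else mb,
                                gap_guard = gap_guard)
    n_masked <<- n_masked + attr(sites, "n_masked")
    n_guard <<- n_guard + attr(sites, "n_gap_guard")
    if (!nrow(sites)) return(NULL)
    cbind(data.frame(gene_a = pairs$gene_a[k], gene_b = pairs$gene_b[k],
                     transcript_a = ra$transcript_id,
                     transcript_b = rb$transcript_id,
                     stringsAsFactors = FALSE), sites)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      transcript_a = character(0), transcript_b = character(0),
                      pos_a = integer(0), pos_b = integer(0),
                      codon_a = character(0), codon_b = character(0),
                      aa_a = character(0), aa_b = character(0),
                      effect = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "counts") <- list(n_masked = n_masked, n_gap_guard = n_guard)
  out
}

#' Per-gene deleterious-substitution fractions for one query direction
#'
#' Joins direction-specific effect scores to nonsynonymous substitution
#' sites (key: query transcript, query protein position, query amino acid
#' -> other species' amino acid) and computes per-gene proportions.  For
#' PROVEAN the numerator is substitutions with score at or below
#' `provean_threshold`; the denominator is, by default, substitutions with
#' a *negative* score (`provean_denominator = "negative_scores"`), because
#' a positive score marks an amino acid better supported in the database
#' species than the query's — `"all_nonsyn"` uses every scored
#' nonsynonymous substitution instead.  For SIFT the numerator is scores
#' below `sift_threshold` over all evaluated substitutions.
#'
#' @param sites data.frame from [ortholog_substitutions()].
#' @param scores data.frame (see [read_score_table()]) for the chosen
#'   query direction: `transcript_id`/`pos_1based` refer to the query
#'   species' transcript, `ref_aa` to its amino acid and `alt_aa` to the
#'   other species'.
#' @param query `"a"` or `"b"`: which species is the PROVEAN/SIFT query.
#' @param method `"provean"` or `"sift"`.
#' @param provean_denominator `"negative_scores"` (default) or
#'   `"all_nonsyn"`.
#' @param provean_threshold,sift_threshold cutoffs.
#' @return list `per_gene` (data.frame `gene`, `n_denominator`,
#'   `n_deleterious`, `fraction`), `species_mean`, `n_genes`.
#' @export
deleterious_substitution_fraction <- function(sites, scores,
    query = c("a", "b"), method = c("provean", "sift"),
    provean_denominator = c("negative_scores", "all_nonsyn"),
    provean_threshold = -2.5, sift_threshold = 0.05) {
  query <- match.arg(query)
  method <- match.arg(method)
  provean_denominator <- match.arg(provean_denominator)
  ns <- sites[sites$effect == "nonsynonymous", , drop = FALSE]
  tx <- if (query == "a") ns$transcript_a else ns$transcript_b
  ppos <- if (query == "a") ns$pos_a else ns$pos_b
  ref_aa <- if (query == "a") ns$aa_a else ns$aa_b
  alt_aa <- if (query == "a") ns$aa_b else ns$aa_a
  gene <- if (query == "a") ns$gene_a else ns$gene_b
  site_key <- paste(tx, ppos, ref_aa, alt_aa, sep = "|")
  score_key <- paste(scores$transcript_id, scores$pos_1based, scores$ref_aa,
                     scores$alt_aa, sep = "|")
  orphan <- setdiff(score_key, site_key)
  if (length(orphan)) {
    stop("substitution score row(s) with no matching site: ",
         paste(utils::head(orphan, 5L), collapse = "; "))
  }
  m <- match(site_key, score_key)
  raw <- if (method == "provean") scores$provean_score[m] else
    scores$sift_score[m]
  if (method == "provean") {
    denom <- if (provean_denominator == "negative_scores") {
      !is.na(raw) & raw < 0
    } else {
      !is.na(raw)
    }
    num <- denom & raw <= provean_threshold
  } else {
    denom <- !is.na(raw)
    num <- denom & raw < sift_threshold
  }
  per_gene <- do.call(rbind, lapply(split(seq_along(site_key), gene),
    function(idx) {
      data.frame(n_denominator = sum(denom[idx]),
                 n_deleterious = sum(num[idx]))
    }))
  if (is.null(per_gene)) {
    per_gene <- data.frame(gene = character(0), n_denominator = integer(0),
                           n_deleterious = integer(0), fraction = numeric(0))
  } else {
    per_gene <- cbind(gene = rownames(per_gene), per_gene,
                      stringsAsFactors = FALSE)
    rownames(per_gene) <- NULL
    per_gene$fraction <- ifelse(per_gene$n_denominator > 0,
                                per_gene$n_deleterious /
                                  per_gene$n_denominator, NA_real_)
  }
  usable <- per_gene$fraction[!is.na(per_gene$fraction)]
  list(per_gene = per_gene,
       species_mean = if (length(usable)) mean(usable) else NA_real_,
       n_genes = length(usable))
}
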