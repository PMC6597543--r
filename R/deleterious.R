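# PROVEAN / SIFT thresholding of nonsynonymous heterozygous SNVs and the
# per-gene deleterious-variant fractions.
#
# Scores are consumed as tables (running the predictors is out of scope).
# Only the reference->alternate direction is scored: in heterozygous data
# the ancestral allele of the two cannot be told apart, but an amino-acid
# change whose |score| clears the threshold flags a large functional
# difference between the two alleles regardless of direction.

#' Read a variant effect-score table
#'
#' TSV with columns `transcript_id`, `pos_1based` (1-based amino-acid
#' position), `ref_aa`, `alt_aa`, `provean_score`, `sift_score`; an empty
#' `sift_score` cell marks a variant SIFT could not evaluate.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_score_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("transcript_id", "pos_1based", "ref_aa", "alt_aa",
            "provean_score", "sift_score")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("score table lacks column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Classify PROVEAN scores
#'
#' Deleterious when the score is less than or equal to `threshold`
#' (boundary inclusive; the predictor's default cutoff of -2.5), neutral
#' above it.
#'
#' @param score numeric vector of PROVEAN scores.
#' @param threshold cutoff, default `-2.5`.
#' @return character vector, `"deleterious"` or `"neutral"` (`NA` in, `NA`
#'   out).
#' @export
classify_provean <- function(score, threshold = -2.5) {
  ifelse(is.na(score), NA_character_,
         ifelse(score <= threshold, "deleterious", "neutral"))
}

#' Classify SIFT scores
#'
#' Deleterious when the score is strictly below `threshold` (default 0.05),
#' tolerated otherwise; a missing score means the variant could not be
#' evaluated and is excluded from both numerator and denominator
#' downstream.
#'
#' @param score numeric vector of SIFT scores (or `NA`).
#' @param threshold cutoff, default `0.05`.
#' @return character vector, `"deleterious"`, `"tolerated"`, or
#'   `"unevaluated"`.
#' @export
classify_sift <- function(score, threshold = 0.05) {
  ifelse(is.na(score), "unevaluated",
         ifelse(score < threshold, "deleterious", "tolerated"))
}

#' Per-gene deleterious-variant fractions and specimen mean
#'
#' Joins effect scores to annotated nonsynonymous heterozygous SNVs by
#' transcript, amino-acid position and amino-acid pair, computes the
#' per-gene proportion of deleterious variants among evaluated
#' nonsynonymous SNVs, and averages (unweighted) over genes with at least
#' one evaluated SNV.  Score rows with no matching SNV are an error.  When
#' `classes` is given only genes with plant-database homology are used.
#'
#' @param annotated data.frame from [annotate_snvs()].
#' @param scores data.frame from [read_score_table()].
#' @param method `"provean"` or `"sift"`.
#' @param classes optional data.frame from [classify_duplication()].
#' @param provean_threshold,sift_threshold cutoffs (see
#'   [classify_provean()], [classify_sift()]).
#' @return list with `per_gene` (data.frame: `gene_id`, `n_evaluated`,
#'   `n_deleterious`, `fraction`), `specimen_mean` (`NA` when no gene has
#'   an evaluated SNV), and `n_genes`.
#' @export
deleterious_fraction <- function(annotated, scores,
                                 method = c("provean", "sift"),
                                 classes = NULL,
                                 provean_threshold = -2.5,
                                 sift_threshold = 0.05) {
  method <- match.arg(method)
  ns <- annotated[annotated$zygosity == "het" &
                    annotated$effect %in% c("missense", "nonsense"), ,
                  drop = FALSE]
  ns$gene_id <- parse_trinity_id(ns$transcript_id)$gene_id
  if (!is.null(classes)) {
    keep <- classes$gene_id[classes$label %in% c("duplicated", "singleton")]
    ns <- ns[ns$gene_id %in% keep, , drop = FALSE]
  }
  snv_key <- paste(ns$transcript_id, ns$codon_index + 1L, ns$ref_aa,
                   ns$alt_aa, sep = "|")
  score_key <- paste(scores$transcript_id, scores$pos_1based, scores$ref_aa,
                     scores$alt_aa, sep = "|")
  orphan <- setdiff(score_key, snv_key)
  # scores for genes filtered out by `classes` are not orphans
  if (!is.null(classes) && length(orphan)) {
    all_key <- with(annotated[annotated$effect %in% c("missense", "nonsense"),
                              , drop = FALSE],
                    paste(transcript_id, codon_index + 1L, ref_aa, alt_aa,
                          sep = "|"))
    orphan <- setdiff(orphan, all_key)
  }
  if (length(orphan)) {
    stop("score row(s) with no matching nonsynonymous SNV: ",
         paste(utils::head(orphan, 5L), collapse = "; "))
  }
  m <- match(snv_key, score_key)
  raw <- if (method == "provean") scores$provean_score[m] else
    scores$sift_score[m]
  del <- if (method == "provean") {
    classify_provean(raw, provean_threshold) == "deleterious"
  } else {
    classify_sift(raw, sift_threshold) == "deleterious"
  }
  evaluated <- !is.na(raw)
  per_gene <- do.call(rbind, lapply(split(seq_len(nrow(ns)), ns$gene_id),
    function(idx) {
      ev <- evaluated[idx]
      data.frame(n_evaluated = sum(ev),
                 n_deleterious = sum(del[idx][ev]),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(per_gene)) {
    per_gene <- data.frame(gene_id = character(0), n_evaluated = integer(0),
                           n_deleterious = integer(0), fraction = numeric(0))
  } else {
    per_gene <- cbind(gene_id = rownames(per_gene), per_gene,
                      stringsAsFactors = FALSE)
    rownames(per_gene) <- NULL
    per_gene$fraction <- ifelse(per_gene$n_evaluated > 0,
                                per_gene$n_deleterious / per_gene$n_evaluated,
                                NA_real_)
  }
  usable <- per_gene$fraction[!is.na(per_gene$fraction)]
  list(per_gene = per_gene,
       specimen_mean = if (length(usable)) mean(usable) else NA_real_,
       n_genes = length(usable))
}
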