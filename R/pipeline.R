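# End-to-end orchestration: one specimen's inputs -> the six indices;
# many specimens -> species values, congeneric comparisons and cross-genus
# sign tests; optional recomputation excluding candidate paralogs.  The
# same functions drive both real file inputs (paths) and simulator output
# (in-memory objects), and every default threshold equals the published
# analysis settings (MQ > 30, E < 1e-4, coverage > 30%, identity > 80%,
# PROVEAN <= -2.5, SIFT < 0.05, >= 50 aa).

.as_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) x else Biostrings::readDNAStringSet(x)
}
.as_hits <- function(x) if (is.character(x)) read_blast_tab(x) else x
.as_scores <- function(x) if (is.character(x)) read_score_table(x) else x

#' Compute the six vulnerability indices for one specimen
#'
#' Runs the full per-specimen pipeline: longest isoform per gene, reading
#' frames and the 50-aa filter, duplication classification and P_D, MQ
#' filtering, SNV effect annotation, the three SNV-composition indices and
#' the two deleterious fractions.  With `exclude_paralogs = TRUE` all
#' SNV-based indices are recomputed on singleton genes only (`pd` is then
#' `NA`: it is not meaningful on a set that excludes duplicates by
#' construction).
#'
#' @param fasta transcript FASTA path or named `DNAStringSet`.
#' @param vcf VCF path or a records data.frame (see [filter_snvs()]).
#' @param self_hits,plant_hits BLAST tabular paths or data.frames.
#' @param scores effect-score TSV path or data.frame.
#' @param species,specimen labels carried into the output row.
#' @param mq_threshold,max_evalue,min_coverage,min_protein_len,provean_threshold,sift_threshold
#'   analysis thresholds (defaults are the published settings).
#' @param exclude_paralogs recompute on singleton genes only.
#' @return list with `indices` (one-row data.frame of the six indices plus
#'   labels and counts), `classes`, `regions`, `summaries`, `annotated`,
#'   `deleterious` (per-gene tables per method).
#' @export
analyze_specimen <- function(fasta, vcf, self_hits, plant_hits, scores,
                             species = NA_character_,
                             specimen = NA_character_,
                             mq_threshold = 30, max_evalue = 1e-4,
                             min_coverage = 30, min_protein_len = 50L,
                             provean_threshold = -2.5, sift_threshold = 0.05,
                             exclude_paralogs = FALSE) {
  seqs <- .as_seqs(fasta)
  longest <- select_longest_isoform(seqs)
  regions <- find_coding_regions(longest, min_protein_len)
  classes <- classify_duplication(.as_hits(self_hits), .as_hits(plant_hits),
                                  regions$gene_id, max_evalue, min_coverage)
  pd_row <- compute_pd(classes)
  idx_classes <- classes
  if (exclude_paralogs) {
    idx_classes <- classes[classes$label == "singleton", , drop = FALSE]
  }
  snvs <- if (is.character(vcf)) read_vcf_snvs(vcf, mq_threshold) else
    filter_snvs(vcf, mq_threshold)
  snvs <- snvs[snvs$transcript_id %in% regions$transcript_id |
                 snvs$transcript_id %in% names(seqs), , drop = FALSE]
  annotated <- annotate_snvs(snvs, regions, known_ids = names(seqs))
  summaries <- summarize_transcripts(annotated, regions)
  snv_idx <- specimen_indices(summaries, idx_classes)
  prov <- deleterious_fraction(annotated, .as_scores(scores), "provean",
                               idx_classes, provean_threshold, sift_threshold)
  sift <- deleterious_fraction(annotated, .as_scores(scores), "sift",
                               idx_classes, provean_threshold, sift_threshold)
  indices <- data.frame(
    species = species, specimen = specimen,
    pd = if (exclude_paralogs) NA_real_ else pd_row$pd,
    syn_per_kb = snv_idx$syn_per_kb,
    nonsyn_fraction = snv_idx$nonsyn_fraction,
    nonsense_fraction = snv_idx$nonsense_fraction,
    provean_fraction = prov$specimen_mean,
    sift_fraction = sift$specimen_mean,
    n_genes = pd_row$n_duplicated + pd_row$n_singleton,
    n_transcripts_with_snv = snv_idx$n_with_snv,
    paralog_excluded = exclude_paralogs,
    stringsAsFactors = FALSE)
  list(indices = indices, classes = classes, regions = regions,
       summaries = summaries, annotated = annotated,
       deleterious = list(provean = prov, sift = sift))
}

#' Compare species from a specimen-level index table
#'
#' Aggregates specimen rows to species values, forms all congeneric
#' EIE-vs-NE comparisons, and computes per-index cross-genus exact
#' binomial summaries.  When per-gene value distributions are supplied,
#' Welch t-test p-values are attached to each pair.
#'
#' @param specimen_table data.frame with `species`, `genus`, `category`,
#'   `specimen` and index columns.
#' @param gene_values optional nested list
#'   `gene_values[[species]][[index]]` of per-gene (or per-transcript)
#'   numeric vectors pooled over the species' specimens, used for the
#'   t tests.
#' @return list with `species_table`, `comparisons` (with `t_test_p` when
#'   computable), `binomial`.
#' @export
compare_species <- function(specimen_table, gene_values = NULL) {
  species_table <- species_index_table(specimen_table)
  comparisons <- build_comparisons(species_table)
  if (!is.null(gene_values)) {
    comparisons$t_test_p <- vapply(seq_len(nrow(comparisons)), function(i) {
      ev <- gene_values[[comparisons$eie_species[i]]][[comparisons$index[i]]]
      nv <- gene_values[[comparisons$ne_species[i]]][[comparisons$index[i]]]
      if (is.null(ev) || is.null(nv)) return(NA_real_)
      pairwise_ttest(ev, nv)
    }, numeric(1))
  }
  list(species_table = species_table, comparisons = comparisons,
       binomial = binomial_summary(comparisons))
}

#' Simulate and analyze a multi-genus study
#'
#' Builds `n_genera` congeneric pairs (one EIE-like and one NE-like
#' species each) from two simulation configs, runs the per-specimen
#' pipeline on every simulated specimen, and returns the specimen index
#' table together with the comparison layer.  Specimens of a species share
#' one simulated transcriptome (as in pooled-assembly practice) but get
#' independent variant draws.
#'
#' @param config_eie,config_ne [sim_config()]s for the two categories.
#' @param n_genera number of congeneric pairs.
#' @param seed master seed; per-species seeds are derived from it.
#' @return list with `specimen_table`, `species_table`, `comparisons`,
#'   `binomial`.
#' @export
simulate_study <- function(config_eie, config_ne, n_genera = 10L,
                           seed = 1L) {
  rows <- list()
  for (g in seq_len(n_genera)) {
    for (side in c("EIE", "NE")) {
      cfg <- if (side == "EIE") config_eie else config_ne
      base <- seed + 1000L * g + ifelse(side == "EIE", 0L, 500L)
      label <- sprintf("%s%02d", side, g)
      sim <- simulate_transcriptome(cfg, species_label = label, seed = base)
      self_hits <- simulate_self_hits(sim)
      plant_hits <- simulate_plant_hits(sim)
      for (sp in seq_len(cfg$n_specimens)) {
        variants <- simulate_variants(sim, cfg, seed = base + 10L * sp + 1L)
        scores <- simulate_scores(variants, cfg, seed = base + 10L * sp + 2L)
        res <- analyze_specimen(sim$seqs, variants$vcf, self_hits,
                                plant_hits, scores$scores,
                                species = label,
                                specimen = sprintf("spec%d", sp))
        row <- res$indices
        row$genus <- sprintf("Genus%02d", g)
        row$category <- side
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  specimen_table <- do.call(rbind, rows)
  cmp <- compare_species(specimen_table)
  c(list(specimen_table = specimen_table), cmp)
}

#' Run the interspecies substitution analysis on a species pair
#'
#' Ingests each species' integrated reference (FASTA + pooled VCF), pairs
#' orthologs by reciprocal best hits, finds species-specific homozygous
#' substitutions, and computes deleterious-substitution fractions by both
#' methods with each species used as the query.
#'
#' @param fasta_a,fasta_b integrated FASTAs (paths or `DNAStringSet`s).
#' @param vcf_a,vcf_b pooled VCFs (paths or record data.frames).
#' @param hits_ab,hits_ba direction-specific homology tables.
#' @param scores_a,scores_b direction-specific effect-score tables
#'   (query = that species).
#' @param min_identity ortholog identity threshold, strict `>`
#'   (default 80).
#' @param provean_denominator see
#'   [deleterious_substitution_fraction()].
#' @param gap_guard codon columns dropped around alignment gaps.
#' @return list with `pairs`, `sites`, and `fractions` — a data.frame
#'   with one row per (query, method): `query`, `method`, `n_genes`,
#'   `mean_fraction`.
#' @export
analyze_species_pair <- function(fasta_a, fasta_b, vcf_a, vcf_b,
                                 hits_ab, hits_ba, scores_a, scores_b,
                                 min_identity = 80,
                                 provean_denominator = "negative_scores",
                                 gap_guard = 2L) {
  as_mask_snvs <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.character(v)) return(read_vcf_snvs(v, mq_threshold = -Inf))
    if ("zygosity" %in% names(v)) v else filter_snvs(v, mq_threshold = -Inf)
  }
  ref_a <- build_integrated_reference(.as_seqs(fasta_a), as_mask_snvs(vcf_a))
  ref_b <- build_integrated_reference(.as_seqs(fasta_b), as_mask_snvs(vcf_b))
  pairs <- pair_orthologs(.as_hits(hits_ab), .as_hits(hits_ba), min_identity)
  sites <- ortholog_substitutions(pairs, ref_a, ref_b, gap_guard)
  runs <- expand.grid(query = c("a", "b"), method = c("provean", "sift"),
                      stringsAsFactors = FALSE)
  fr <- lapply(seq_len(nrow(runs)), function(i) {
    sc <- if (runs$query[i] == "a") .as_scores(scores_a) else
      .as_scores(scores_b)
    res <- deleterious_substitution_fraction(
      sites, sc, query = runs$query[i], method = runs$method[i],
      provean_denominator = provean_denominator)
    data.frame(query = runs$query[i], method = runs$method[i],
               n_genes = res$n_genes, mean_fraction = res$species_mean,
               stringsAsFactors = FALSE)
  })
  list(pairs = pairs, sites = sites, fractions = do.call(rbind, fr))
}
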