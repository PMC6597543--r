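# Duplicated-gene classification from protein homology tables, and P_D.
#
# A gene is a candidate duplicate when it hits another gene of the same
# transcriptome at E < 1e-4 with query coverage > 30% (coverage on protein
# lengths); candidate singletons have no such hit.  Genes without any
# plant-protein-database hit at E < 1e-4 are dropped from the gene universe
# entirely.  P_D = duplicated / (duplicated + singleton).

#' Read a BLAST tabular homology file
#'
#' Expects the standard 12-column `outfmt 6` layout with query length
#' (`qlen`) appended as a 13th column.  Lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`,
#'   `query_length`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bitscore", "query_length")
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) != 13L) {
    stop("expected 13 columns (outfmt 6 + qlen), got ", ncol(x))
  }
  names(x) <- cols
  x
}

.check_hits <- function(hits, what) {
  need <- c("query_id", "subject_id", "alignment_length", "evalue",
            "query_length")
  miss <- setdiff(need, names(hits))
  if (length(miss)) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(hits$query_length)) {
    stop(what, " table has missing query_length; coverage is incomputable")
  }
  invisible(hits)
}

#' Classify genes as duplicated, singleton, or excluded
#'
#' Within-transcriptome hits with `query != subject`, E-value below
#' `max_evalue` and query coverage (100 * alignment_length / query_length)
#' strictly above `min_coverage` mark a gene as a candidate duplicate; all
#' other genes are candidate singletons.  Candidates become final
#' `duplicated` / `singleton` labels only when the gene also has a
#' plant-database hit below `max_evalue` (no coverage requirement on that
#' search); genes without plant homology are labelled
#' `excluded_no_plant_homology` and do not enter P_D.
#'
#' Classification is directional: a gene's label depends only on its own
#' query rows, never on being someone else's subject.
#'
#' @param self_hits data.frame of within-set protein hits (see
#'   [read_blast_tab()]).
#' @param plantdb_hits data.frame of hits against the plant protein
#'   database.
#' @param gene_ids character vector: the full gene universe (genes with a
#'   retained coding region).
#' @param max_evalue E-value threshold, strict `<` (default `1e-4`).
#' @param min_coverage query-coverage threshold in percent, strict `>`
#'   (default `30`).
#' @return data.frame with columns `gene_id`,
#'   `label` (`duplicated` / `singleton` / `excluded_no_plant_homology`).
#' @export
classify_duplication <- function(self_hits, plantdb_hits, gene_ids,
                                 max_evalue = 1e-4, min_coverage = 30) {
  gene_ids <- unique(as.character(gene_ids))
  .check_hits(self_hits, "self-hit")
  if (!all(c("query_id", "evalue") %in% names(plantdb_hits))) {
    stop("plant-DB table lacks query_id/evalue columns")
  }
  unknown <- setdiff(unique(c(self_hits$query_id, self_hits$subject_id,
                              plantdb_hits$query_id)), gene_ids)
  if (length(unknown)) {
    stop("homology hit(s) reference unknown gene(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  coverage <- 100 * self_hits$alignment_length / self_hits$query_length
  qual <- self_hits$query_id != self_hits$subject_id &
    self_hits$evalue < max_evalue & coverage > min_coverage
  dup_genes <- unique(self_hits$query_id[qual])
  plant_genes <- unique(plantdb_hits$query_id[plantdb_hits$evalue < max_evalue])
  label <- ifelse(!(gene_ids %in% plant_genes), "excluded_no_plant_homology",
                  ifelse(gene_ids %in% dup_genes, "duplicated", "singleton"))
  data.frame(gene_id = gene_ids, label = label, stringsAsFactors = FALSE)
}

#' Proportion of duplicated genes (P_D)
#'
#' P_D = n_duplicated / (n_duplicated + n_singleton); genes excluded for
#' lack of plant homology are not counted in either term.
#'
#' @param classes data.frame from [classify_duplication()].
#' @return one-row data.frame: `n_duplicated`, `n_singleton`, `n_excluded`,
#'   `pd`.
#' @export
compute_pd <- function(classes) {
  n_dup <- sum(classes$label == "duplicated")
  n_single <- sum(classes$label == "singleton")
  n_excl <- sum(classes$label == "excluded_no_plant_homology")
  if (n_dup + n_single == 0L) {
    stop("no genes with plant homology; P_D is undefined")
  }
  data.frame(n_duplicated = n_dup, n_singleton = n_single,
             n_excluded = n_excl, pd = n_dup / (n_dup + n_single))
}
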