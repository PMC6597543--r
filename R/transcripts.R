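# Transcript models: Trinity-style ID parsing, longest-isoform selection,
# reading-frame identification (edge-tolerant longest ORF over six frames)
# and the 50-amino-acid retention filter.

#' Parse Trinity-style transcript identifiers
#'
#' IDs follow the cluster/gene/isoform hierarchy, e.g.
#' `SPP_c12_g3_i1` or `TRINITY_DN1000_c0_g1_i2`.  Gene identity is the ID
#' with the trailing `_i<k>` isoform suffix removed: contigs sharing
#' cluster and gene fields are isoforms of one gene.
#'
#' @param ids character vector of transcript IDs.
#' @return data.frame with columns `transcript_id`, `gene_id`, `cluster`,
#'   `gene`, `isoform`.
#' @export
parse_trinity_id <- function(ids) {
  ids <- as.character(ids)
  pat <- "^(.*)_c([0-9]+)_g([0-9]+)_i([0-9]+)$"
  bad <- !grepl(pat, ids)
  if (any(bad)) {
    stop("unparseable transcript ID(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  data.frame(
    transcript_id = ids,
    gene_id = sub("_i[0-9]+$", "", ids),
    cluster = as.integer(sub(pat, "\\2", ids)),
    gene = as.integer(sub(pat, "\\3", ids)),
    isoform = as.integer(sub(pat, "\\4", ids)),
    stringsAsFactors = FALSE
  )
}

#' Select the longest isoform per gene
#'
#' Keeps, for every gene (same cluster and gene ID fields), the isoform
#' with the greatest nucleotide length.  Length ties are broken by the
#' lexicographically smallest transcript ID, so selection is deterministic.
#'
#' @param seqs a named `Biostrings::DNAStringSet` (or named character
#'   vector) of transcript sequences; names must parse with
#'   [parse_trinity_id()].
#' @return `DNAStringSet` with exactly one transcript per gene, ordered by
#'   gene ID.
#' @export
select_longest_isoform <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (is.null(names(seqs))) stop("sequences must be named by transcript ID")
  ids <- parse_trinity_id(names(seqs))
  len <- Biostrings::width(seqs)
  ord <- order(ids$gene_id, -len, names(seqs))
  keep <- ord[!duplicated(ids$gene_id[ord])]
  seqs[sort(keep)]
}

# Maximal stop-free codon runs for one frame of one strand.
# Returns a data.frame of candidate ORFs (codon-run coordinates).
.frame_runs <- function(aas) {
  n <- length(aas)
  if (n == 0L) return(NULL)
  is_stop <- aas == "*"
  bounds <- c(0L, which(is_stop), n + 1L)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1] - 1L
  keep <- ends >= starts
  data.frame(start_cod = starts[keep], end_cod = ends[keep],
             has_stop = (ends[keep] + 1L) <= n)
}

#' Identify the reading frame of a transcript
#'
#' Finds the longest open reading frame over all six frames (both strands,
#' three offsets).  The rule is edge tolerant: an ORF is a maximal stop-free
#' stretch of codons, with no ATG requirement and the terminal stop optional
#' at a contig edge, which suits fragmentary de novo assemblies.  Ties on
#' protein length are broken by strand (`+` first) and then by the smallest
#' start position on the transcript.  Codons containing `N` translate to
#' `'X'` and do not interrupt an ORF.
#'
#' @param seq a single DNA sequence (character or `DNAString`); alphabet
#'   must be within `A/C/G/T/N` (case-insensitive).
#' @param min_protein_len minimum protein length to retain an ORF;
#'   default 50 amino acids (shorter predicted proteins are discarded).
#' @return one-row data.frame with columns `strand`, `start`, `end`
#'   (0-based half-open transcript coordinates of the CDS, terminal stop
#'   included when present), `cds`, `protein`, `protein_len`; or `NULL`
#'   when no ORF reaches `min_protein_len`.
#' @export
find_orf <- function(seq, min_protein_len = 50L) {
  s <- toupper(as.character(seq))
  if (length(s) != 1L) stop("find_orf() takes a single sequence")
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-IUPAC-DNA characters")
  n <- nchar(s)
  best <- NULL
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else revcomp(s)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 1L) next
      idx <- off + 1L + 3L * (seq_len(ncod) - 1L)
      aas <- translate_codons(substring(ss, idx, idx + 2L))
      runs <- .frame_runs(aas)
      if (is.null(runs)) next
      for (r in which(runs$end_cod - runs$start_cod + 1L >= min_protein_len)) {
        plen <- runs$end_cod[r] - runs$start_cod[r] + 1L
        cds_start <- off + 3L * (runs$start_cod[r] - 1L)
        cds_end <- off + 3L * (runs$end_cod[r] + as.integer(runs$has_stop[r]))
        # map back to original transcript coordinates (0-based half-open)
        if (strand == "+") {
          start <- cds_start; end <- cds_end
        } else {
          start <- n - cds_end; end <- n - cds_start
        }
        cand <- list(strand = strand, start = start, end = end, plen = plen,
                     ss = ss, cds_start = cds_start, cds_end = cds_end)
        if (is.null(best) ||
            plen > best$plen ||
            (plen == best$plen && best$strand == "-" && strand == "+") ||
            (plen == best$plen && strand == best$strand && start < best$start)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  cds <- substring(best$ss, best$cds_start + 1L, best$cds_end)
  protein <- substr(translate_cds(cds), 1L, best$plen)
  data.frame(strand = best$strand, start = best$start, end = best$end,
             cds = cds, protein = protein, protein_len = best$plen,
             stringsAsFactors = FALSE)
}

#' Find coding regions for a transcript set
#'
#' Applies [find_orf()] to every transcript (usually the longest isoform of
#' each gene) and drops those whose best ORF encodes fewer than
#' `min_protein_len` amino acids.
#'
#' @param seqs named `DNAStringSet` or character vector.
#' @inheritParams find_orf
#' @return data.frame with one row per retained transcript:
#'   `transcript_id`, `gene_id`, `tx_len`, `strand`, `start`, `end`
#'   (0-based half-open), `cds`, `protein`, `protein_len`.
#' @export
find_coding_regions <- function(seqs, min_protein_len = 50L) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named by transcript ID")
  rows <- lapply(seq_along(seqs), function(i) {
    orf <- find_orf(as.character(seqs[[i]]), min_protein_len)
    if (is.null(orf)) return(NULL)
    cbind(data.frame(transcript_id = names(seqs)[i],
                     tx_len = Biostrings::width(seqs)[i],
                     stringsAsFactors = FALSE), orf)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(transcript_id = character(0), tx_len = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), cds = character(0),
                      protein = character(0), protein_len = integer(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  out$gene_id <- parse_trinity_id(out$transcript_id)$gene_id
  rownames(out) <- NULL
  out
}

#' Write coding-region coordinates and proteins
#'
#' Emits a coordinate TSV (1-based inclusive coordinates, as in standard
#' tabular genomics formats) and optionally a protein FASTA.
#'
#' @param regions data.frame from [find_coding_regions()].
#' @param tsv path for the coordinate TSV.
#' @param protein_fasta optional path for a protein FASTA.
#' @return `tsv`, invisibly.
#' @export
write_coding_regions <- function(regions, tsv, protein_fasta = NULL) {
  out <- data.frame(transcript_id = regions$transcript_id,
                    strand = regions$strand,
                    start_1based = regions$start + 1L,
                    end_1based = regions$end,
                    protein_len = regions$protein_len)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(protein_fasta)) {
    aa <- Biostrings::AAStringSet(regions$protein)
    names(aa) <- regions$transcript_id
    Biostrings::writeXStringSet(aa, protein_fasta)
  }
  invisible(tsv)
}
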