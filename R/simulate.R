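# Deterministic synthetic-data generator.
#
# Emits self-contained inputs (transcript FASTA with Trinity-style IDs,
# VCF, homology TSVs, effect-score TSVs) whose statistical structure
# matches what the analysis assumes: gene families with a controllable
# duplicated fraction, heterozygous SNVs with controllable density and
# synonymous/nonsense composition, effect scores with controllable
# deleterious fractions, and diverged ortholog pairs with homozygous
# substitutions.  Every generated quantity is recorded in truth ledgers so
# pipeline estimates can be checked by parameter recovery.  All functions
# seed the RNG themselves; the same config and seed give byte-identical
# output.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates:
#' transcriptomes of a few hundred expressed genes with ~70% duplicated
#' genes, coding heterozygosity of about 2 SNVs/kb, a small nonsense share
#' among nonsynonymous SNVs, PROVEAN/SIFT deleterious fractions around
#' 0.25-0.35, and ~2% coding divergence between congeneric species.
#'
#' @param n_genes number of genes per transcriptome.
#' @param duplicated_fraction fraction of genes belonging to multi-gene
#'   families (size-2 families).
#' @param mean_cds_len_bp mean coding length in bp (multiple of 3,
#'   >= 150 so proteins pass the 50-aa filter).
#' @param het_snv_rate expected heterozygous SNVs per coding bp.
#' @param nonsyn_target_fraction probability a generated SNV is
#'   nonsynonymous.
#' @param nonsense_given_nonsyn probability a nonsynonymous SNV is
#'   nonsense.
#' @param deleterious_fraction_provean,deleterious_fraction_sift
#'   probability a missense variant is scored deleterious by each method.
#' @param sift_missing_rate probability a SIFT score is missing.
#' @param interspecies_divergence substitutions per coding site between
#'   the two species of a pair.
#' @param n_specimens specimens per species.
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, duplicated_fraction = 0.7,
                       mean_cds_len_bp = 900L, het_snv_rate = 0.002,
                       nonsyn_target_fraction = 0.55,
                       nonsense_given_nonsyn = 0.04,
                       deleterious_fraction_provean = 0.35,
                       deleterious_fraction_sift = 0.25,
                       sift_missing_rate = 0.1,
                       interspecies_divergence = 0.02,
                       n_specimens = 3L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              duplicated_fraction = duplicated_fraction,
              mean_cds_len_bp = as.integer(mean_cds_len_bp),
              het_snv_rate = het_snv_rate,
              nonsyn_target_fraction = nonsyn_target_fraction,
              nonsense_given_nonsyn = nonsense_given_nonsyn,
              deleterious_fraction_provean = deleterious_fraction_provean,
              deleterious_fraction_sift = deleterious_fraction_sift,
              sift_missing_rate = sift_missing_rate,
              interspecies_divergence = interspecies_divergence,
              n_specimens = as.integer(n_specimens),
              seed = as.integer(seed))
  probs <- c("duplicated_fraction", "nonsyn_target_fraction",
             "nonsense_given_nonsyn", "deleterious_fraction_provean",
             "deleterious_fraction_sift", "sift_missing_rate")
  for (p in probs) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be a probability in [0, 1]")
    }
  }
  if (cfg$het_snv_rate < 0 || cfg$interspecies_divergence < 0) {
    stop("rates must be non-negative")
  }
  if (cfg$mean_cds_len_bp < 150L || cfg$mean_cds_len_bp %% 3L != 0L) {
    stop("mean_cds_len_bp must be a multiple of 3 and at least 150")
  }
  if (cfg$n_genes < 1L || cfg$n_specimens < 1L) {
    stop("n_genes and n_specimens must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Study-condition presets for the two comparison categories
#'
#' Contrast presets whose directions and magnitudes mirror the published
#' EIE-vs-NE contrasts: an endangered-island-endemic-like species has a
#' lower duplicated-gene fraction and heterozygosity but higher
#' nonsynonymous, nonsense and deleterious fractions than a
#' non-endangered-like congener.
#'
#' @param n_genes,n_specimens,seed see [sim_config()].
#' @return a [sim_config()].
#' @export
eie_like_config <- function(n_genes = 200L, n_specimens = 1L, seed = 1L) {
  sim_config(n_genes = n_genes, duplicated_fraction = 0.60,
             mean_cds_len_bp = 900L, het_snv_rate = 0.002,
             nonsyn_target_fraction = 0.70, nonsense_given_nonsyn = 0.12,
             deleterious_fraction_provean = 0.45,
             deleterious_fraction_sift = 0.35, sift_missing_rate = 0.1,
             interspecies_divergence = 0.02, n_specimens = n_specimens,
             seed = seed)
}

#' @rdname eie_like_config
#' @export
ne_like_config <- function(n_genes = 200L, n_specimens = 1L, seed = 2L) {
  sim_config(n_genes = n_genes, duplicated_fraction = 0.85,
             mean_cds_len_bp = 900L, het_snv_rate = 0.005,
             nonsyn_target_fraction = 0.45, nonsense_given_nonsyn = 0.01,
             deleterious_fraction_provean = 0.25,
             deleterious_fraction_sift = 0.18, sift_missing_rate = 0.1,
             interspecies_divergence = 0.02, n_specimens = n_specimens,
             seed = seed)
}

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.rand_cds_codons <- function(ncod) {
  c("ATG", sample(.sense_codons(), ncod - 1L, replace = TRUE))
}

# longest stop-free codon run over all six frames: generator-internal
# scanner used to reject transcripts where a spurious frame rivals the
# planted CDS (so the planted frame is always the unique longest ORF)
.six_frame_max_runs <- function(s) {
  n <- nchar(s)
  lens <- integer(0)
  for (ss in c(s, revcomp(s))) {
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 1L) next
      idx <- off + 1L + 3L * (seq_len(ncod) - 1L)
      aas <- translate_codons(substring(ss, idx, idx + 2L))
      runs <- .frame_runs(aas)
      if (!is.null(runs) && nrow(runs)) {
        lens <- c(lens, runs$end_cod - runs$start_cod + 1L)
      }
    }
  }
  lens
}

# assemble one gene's transcript set around a CDS codon vector; retries
# UTRs until the planted CDS is the unique six-frame maximum.  Returns
# NULL when no UTR draw works (a competing stop-free run can sit inside
# the CDS itself, in another frame); callers then regenerate the CDS.
.build_gene_transcripts <- function(codons, id_prefix, n_isoforms,
                                    max_attempts = 25L) {
  ncod <- length(codons)
  cds <- paste(c(codons, sample(.STOP_CODONS, 1L)), collapse = "")
  for (attempt in seq_len(max_attempts)) {
    m5 <- sample(15:60, 1L)
    m3 <- sample(10:50, 1L)
    tx <- paste0(.rand_dna(m5 - 3L), "TAA", cds, .rand_dna(m3))
    runs <- .six_frame_max_runs(tx)
    if (sum(runs >= ncod) == 1L) {
      # isoforms: the full transcript plus strictly shorter 3' truncations;
      # isoform numbers are shuffled so "longest" is not always _i1
      n_iso <- n_isoforms
      lens <- nchar(tx)
      if (n_iso > 1L) {
        cuts <- sort(sample(30:max(31L, nchar(tx) %/% 3L), n_iso - 1L))
        lens <- c(nchar(tx), nchar(tx) - cuts)
      }
      iso_idx <- sample(seq_len(n_iso))
      ids <- paste0(id_prefix, "_i", iso_idx)
      seqs <- substring(tx, 1L, lens)
      names(seqs) <- ids
      return(list(seqs = seqs, longest_id = ids[1L], cds_start = m5,
                  cds_end = m5 + 3L * (ncod + 1L), protein_len = ncod,
                  cds = cds, tx = tx))
    }
  }
  NULL
}

# mutate a codon vector at `k` random codons with non-stop-creating
# single-base changes (used to derive a duplicate family member)
.mutate_codons <- function(codons, k) {
  tab <- codon_change_table()
  usable <- tab[tab$effect %in% c("synonymous", "missense"), , drop = FALSE]
  # never touch the ATG start codon
  pick <- sample(2:length(codons), min(k, length(codons) - 1L))
  for (ci in pick) {
    opts <- usable[usable$codon == codons[ci], , drop = FALSE]
    if (!nrow(opts)) next
    codons[ci] <- opts$alt_codon[sample(nrow(opts), 1L)]
  }
  codons
}

#' Simulate a transcriptome with gene families
#'
#' Generates `n_genes` genes; a `duplicated_fraction` of them belong to
#' size-2 families created by duplicating a CDS with low (~1.5%)
#' divergence.  Every gene has 1-3 isoforms (strictly shorter 3'
#' truncations of the full transcript).  Each CDS starts with ATG, ends
#' with a stop codon and has no internal stop; an in-frame upstream stop
#' bounds the open reading frame so the planted CDS is the unique longest
#' ORF of its transcript.
#'
#' @param config a [sim_config()].
#' @param species_label prefix for transcript IDs
#'   (`<label>_c<cluster>_g<gene>_i<isoform>`).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with `seqs` (named `DNAStringSet` of all isoforms) and
#'   `truth` (data.frame, one row per gene: `gene_id`, `transcript_id` of
#'   the longest isoform, `cluster`, `gene`, `n_isoforms`, `cds_start`,
#'   `cds_end` 0-based half-open, `protein_len`, `duplicated`).
#' @export
simulate_transcriptome <- function(config, species_label = "SYN",
                                   seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_pairs <- round(config$n_genes * config$duplicated_fraction / 2)
  n_dup <- 2L * n_pairs
  n_single <- config$n_genes - n_dup
  mean_cod <- config$mean_cds_len_bp %/% 3L
  sd_cod <- max(4L, mean_cod %/% 12L)
  draw_len <- function() max(55L, round(rnorm(1L, mean_cod, sd_cod)))

  all_seqs <- character(0)
  rows <- list()
  add_gene <- function(gt, cluster, gene, duplicated) {
    all_seqs <<- c(all_seqs, gt$seqs)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = sub("_i[0-9]+$", "", gt$longest_id),
      transcript_id = gt$longest_id,
      cluster = cluster, gene = gene,
      n_isoforms = length(gt$seqs), cds_start = gt$cds_start,
      cds_end = gt$cds_end, protein_len = gt$protein_len,
      cds = gt$cds, duplicated = duplicated, stringsAsFactors = FALSE)
  }
  cluster <- 0L
  for (f in seq_len(n_pairs)) {
    cluster <- cluster + 1L
    repeat {  # regenerate the whole family when either member's CDS
              # harbours a competing frame
      base <- .rand_cds_codons(draw_len())
      g1 <- .build_gene_transcripts(
        base, sprintf("%s_c%d_g1", species_label, cluster), sample(1:3, 1L))
      if (is.null(g1)) next
      g2 <- .build_gene_transcripts(
        .mutate_codons(base, max(1L, round(0.015 * length(base)))),
        sprintf("%s_c%d_g2", species_label, cluster), sample(1:3, 1L))
      if (is.null(g2)) next
      add_gene(g1, cluster, 1L, TRUE)
      add_gene(g2, cluster, 2L, TRUE)
      break
    }
  }
  for (s in seq_len(n_single)) {
    cluster <- cluster + 1L
    repeat {
      gt <- .build_gene_transcripts(
        .rand_cds_codons(draw_len()),
        sprintf("%s_c%d_g1", species_label, cluster), sample(1:3, 1L))
      if (!is.null(gt)) { add_gene(gt, cluster, 1L, FALSE); break }
    }
  }
  seqs <- Biostrings::DNAStringSet(all_seqs)
  truth <- do.call(rbind, rows)
  list(seqs = seqs, truth = truth, species_label = species_label,
       config = config)
}

#' Within-set homology table implied by the simulated gene families
#'
#' Builds the BLAST-tabular self-hit table the analysis consumes: one
#' reciprocal pair of rows per gene family (high identity, tiny E-value,
#' full-coverage alignment) plus trivial self-hits, written in terms of
#' gene IDs (longest-isoform proteins).
#'
#' @param sim output of [simulate_transcriptome()].
#' @return data.frame in [read_blast_tab()] layout.
#' @export
simulate_self_hits <- function(sim) {
  tr <- sim$truth
  mk_row <- function(q, s, plq, pls, ident) {
    data.frame(query_id = q, subject_id = s, percent_identity = ident,
               alignment_length = plq, mismatches = round((100 - ident) / 100 * plq),
               gap_opens = 0L, q_start = 1L, q_end = plq, s_start = 1L,
               s_end = pls, evalue = if (q == s) 0 else 1e-50,
               bitscore = 2 * plq, query_length = plq,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    mk_row(tr$gene_id[i], tr$gene_id[i], tr$protein_len[i],
           tr$protein_len[i], 100)
  })
  fams <- split(seq_len(nrow(tr)), tr$cluster)
  for (f in fams) {
    if (length(f) < 2L) next
    for (i in f) for (j in setdiff(f, i)) {
      rows[[length(rows) + 1L]] <- mk_row(tr$gene_id[i], tr$gene_id[j],
                                          tr$protein_len[i],
                                          tr$protein_len[j], 98)
    }
  }
  do.call(rbind, rows)
}

#' Plant-database homology table for a simulated transcriptome
#'
#' Every gene receives one qualifying plant-protein hit by default; lower
#' `plant_homology_rate` to exercise the plant-retention filter.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param plant_homology_rate probability a gene has plant homology.
#' @param seed RNG seed (only used when `plant_homology_rate < 1`).
#' @return data.frame in [read_blast_tab()] layout.
#' @export
simulate_plant_hits <- function(sim, plant_homology_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- sim$truth
  keep <- if (plant_homology_rate >= 1) rep(TRUE, nrow(tr)) else
    runif(nrow(tr)) < plant_homology_rate
  tr <- tr[keep, , drop = FALSE]
  if (!nrow(tr)) return(simulate_self_hits(sim)[0, ])
  data.frame(query_id = tr$gene_id,
             subject_id = sprintf("PLANTDB_%05d", seq_len(nrow(tr))),
             percent_identity = 85, alignment_length = tr$protein_len,
             mismatches = round(0.15 * tr$protein_len), gap_opens = 0L,
             q_start = 1L, q_end = tr$protein_len, s_start = 1L,
             s_end = tr$protein_len, evalue = 1e-30,
             bitscore = 1.8 * tr$protein_len, query_length = tr$protein_len,
             stringsAsFactors = FALSE)
}

# sample one single-base change of a target effect class on a codon
# vector; returns NULL when no unused codon offers that class
.sample_change <- function(codons, cls, used) {
  tab <- codon_change_table()
  for (try in 1:200) {
    ci <- sample(length(codons), 1L)
    if (ci %in% used) next
    opts <- tab[tab$codon == codons[ci] & tab$effect == cls, , drop = FALSE]
    if (!nrow(opts)) next
    o <- opts[sample(nrow(opts), 1L), , drop = FALSE]
    return(cbind(data.frame(codon_index = ci - 1L), o))
  }
  NULL
}

#' Simulate heterozygous SNVs on a transcriptome
#'
#' Places heterozygous SNVs on the coding positions of each gene's longest
#' isoform at `het_snv_rate` per coding bp.  Each SNV's effect class is
#' drawn to hit the configured synonymous/missense/nonsense composition in
#' expectation, then a compatible (codon, position, alternate base) is
#' sampled; at most one SNV per codon.  A `low_mq_fraction` of records get
#' RMS mapping quality <= 30 (to exercise the MQ filter), and a small
#' fraction of extra homozygous records is added (assembly-vs-individual
#' differences that must not enter the heterozygosity indices).
#'
#' @param sim output of [simulate_transcriptome()].
#' @param config a [sim_config()].
#' @param low_mq_fraction fraction of records with MQ in (10, 30].
#' @param hom_fraction homozygous records as a fraction of `het_snv_rate`.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list with `vcf` (records data.frame for [filter_snvs()] /
#'   [write_vcf()]) and `truth` (one row per record: placement, effect
#'   class, zygosity, `low_mq` flag).
#' @export
simulate_variants <- function(sim, config, low_mq_fraction = 0.1,
                              hom_fraction = 0.05,
                              seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  classes <- c("synonymous", "missense", "nonsense")
  f <- config$nonsyn_target_fraction
  g <- config$nonsense_given_nonsyn
  p_cls <- c(1 - f, f * (1 - g), f * g)
  rows <- list()
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    plen <- tr$protein_len[i]
    codons <- substring(tr$cds[i], 3L * (seq_len(plen) - 1L) + 1L,
                        3L * seq_len(plen))
    n_het <- rbinom(1L, 3L * plen, config$het_snv_rate)
    n_hom <- rbinom(1L, 3L * plen, config$het_snv_rate * hom_fraction)
    used <- integer(0)
    for (k in seq_len(n_het + n_hom)) {
      cls <- sample(classes, 1L, prob = p_cls)
      ch <- .sample_change(codons, cls, used)
      if (is.null(ch)) next
      used <- c(used, ch$codon_index + 1L)
      low <- runif(1L) < low_mq_fraction
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tr$transcript_id[i],
        pos = tr$cds_start[i] + 3L * ch$codon_index + ch$codon_pos + 1L,
        ref = ch$ref, alt = ch$alt,
        mq = if (low) round(runif(1L, 10, 30), 1) else round(runif(1L, 31, 60), 1),
        gt = if (k <= n_het) "0/1" else "1/1",
        class = ch$effect, codon_index = ch$codon_index,
        codon_pos = ch$codon_pos, ref_aa = ch$ref_aa, alt_aa = ch$alt_aa,
        low_mq = low, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    truth <- data.frame(transcript_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        mq = numeric(0), gt = character(0),
                        class = character(0), codon_index = integer(0),
                        codon_pos = integer(0), ref_aa = character(0),
                        alt_aa = character(0), low_mq = logical(0),
                        stringsAsFactors = FALSE)
  }
  ord <- order(truth$transcript_id, truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  list(vcf = truth[, c("transcript_id", "pos", "ref", "alt", "mq", "gt")],
       truth = truth)
}

#' Simulate PROVEAN/SIFT effect scores
#'
#' Assigns scores to the heterozygous missense variants of a simulated
#' variant set: a `deleterious_fraction_provean` of rows get PROVEAN
#' scores <= -2.5 (others above -2.5), a `deleterious_fraction_sift` get
#' SIFT scores < 0.05 (others >= 0.05), and a `sift_missing_rate` of rows
#' have the SIFT score missing.  Nonsense variants are not scored (the
#' predictors score amino-acid substitutions, not premature stops).
#'
#' @param variants output of [simulate_variants()].
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 2`.
#' @return list with `scores` (table for [deleterious_fraction()]) and
#'   `truth` (per-row deleterious/missing flags).
#' @export
simulate_scores <- function(variants, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  v <- variants$truth
  # predictors are run on the variants that survive calling-side filters,
  # so low-MQ records never reach the score table
  v <- v[v$gt == "0/1" & v$class == "missense" & !v$low_mq, , drop = FALSE]
  n <- nrow(v)
  prov_del <- runif(n) < config$deleterious_fraction_provean
  sift_del <- runif(n) < config$deleterious_fraction_sift
  sift_missing <- runif(n) < config$sift_missing_rate
  provean <- ifelse(prov_del, runif(n, -8, -2.5), runif(n, -2.4, 3))
  sift <- ifelse(sift_del, runif(n, 0, 0.049), runif(n, 0.05, 1))
  sift[sift_missing] <- NA_real_
  scores <- data.frame(transcript_id = v$transcript_id,
                       pos_1based = v$codon_index + 1L,
                       ref_aa = v$ref_aa, alt_aa = v$alt_aa,
                       provean_score = round(provean, 3),
                       sift_score = round(sift, 4),
                       stringsAsFactors = FALSE)
  truth <- cbind(v[, c("transcript_id", "codon_index", "ref_aa", "alt_aa")],
                 provean_deleterious = prov_del,
                 sift_deleterious = sift_del,
                 sift_missing = sift_missing)
  rownames(truth) <- NULL
  list(scores = scores, truth = truth)
}

#' Simulate a diverged congeneric species pair
#'
#' Generates orthologous single-isoform gene sets for two species from a
#' common ancestor, introduces homozygous substitutions at
#' `divergence` per coding site (single-base, non-stop-creating, at most
#' one per codon, assigned to either species), and records every
#' introduced site with its true effect class in a ledger.  A
#' `mask_fraction` of substitution sites are additionally marked
#' heterozygous in the carrier species' pooled VCF — those sites must be
#' excluded by the analysis.  Direction-specific effect-score tables for
#' the unmasked nonsynonymous sites are generated with the configured
#' deleterious fractions.
#'
#' @param config a [sim_config()].
#' @param species_a,species_b ID prefixes for the two species.
#' @param divergence substitutions per coding site; defaults to
#'   `config$interspecies_divergence`.
#' @param mask_fraction fraction of substitution sites masked as
#'   heterozygous.
#' @param seed RNG seed; defaults to `config$seed + 3`.
#' @return list with `seqs_a`, `seqs_b` (DNAStringSets), `vcf_a`, `vcf_b`
#'   (pooled het records), `hits_ab`, `hits_ba` (homology tables on gene
#'   IDs, identity computed from the final proteins), `scores_a`,
#'   `scores_b` (per-query-direction score tables), `ledger`
#'   (all introduced substitutions: positions in both species, effect,
#'   `masked` flag, per-direction deleterious truth).
#' @export
simulate_species_pair <- function(config, species_a = "EIA",
                                  species_b = "NEB",
                                  divergence = config$interspecies_divergence,
                                  mask_fraction = 0.1,
                                  seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  mean_cod <- config$mean_cds_len_bp %/% 3L
  sd_cod <- max(4L, mean_cod %/% 12L)
  tab <- codon_change_table()
  seqs_a <- character(0); seqs_b <- character(0)
  meta <- list(); ledger <- list()
  vcf_a <- list(); vcf_b <- list()
  for (i in seq_len(config$n_genes)) {
    gid_a <- sprintf("%s_c%d_g1", species_a, i)
    gid_b <- sprintf("%s_c%d_g1", species_b, i)
    repeat {  # regenerate gene + substitutions if either transcript's
              # planted frame is not the unique longest ORF
      ncod <- max(55L, round(rnorm(1L, mean_cod, sd_cod)))
      codons <- .rand_cds_codons(ncod)
      cod_a <- codons; cod_b <- codons
      n_sub <- rbinom(1L, 3L * ncod, divergence)
      used <- 1L  # keep the start codon intact in both species
      gene_ledger <- list()
      for (k in seq_len(n_sub)) {
        cls <- sample(c("synonymous", "missense"), 1L,
                      prob = c(0.35, 0.65))
        ch <- .sample_change(codons, cls, used)
        if (is.null(ch)) next
        used <- c(used, ch$codon_index + 1L)
        carrier <- sample(c("a", "b"), 1L)
        if (carrier == "a") {
          cod_a[ch$codon_index + 1L] <- ch$alt_codon
        } else {
          cod_b[ch$codon_index + 1L] <- ch$alt_codon
        }
        gene_ledger[[length(gene_ledger) + 1L]] <- data.frame(
          gene_a = gid_a, gene_b = gid_b, codon_index = ch$codon_index,
          protein_pos = ch$codon_index + 1L, carrier = carrier,
          codon_pos = ch$codon_pos, ref = ch$ref, alt = ch$alt,
          effect = ifelse(ch$effect == "synonymous", "synonymous",
                          "nonsynonymous"),
          aa_ancestral = ch$ref_aa, aa_derived = ch$alt_aa,
          masked = runif(1L) < mask_fraction, stringsAsFactors = FALSE)
      }
      ga <- .build_gene_transcripts(cod_a, gid_a, 1L)
      if (is.null(ga)) next
      gb <- .build_gene_transcripts(cod_b, gid_b, 1L)
      if (is.null(gb)) next
      break
    }
    ledger <- c(ledger, gene_ledger)
    seqs_a <- c(seqs_a, ga$seqs)
    seqs_b <- c(seqs_b, gb$seqs)
    meta[[i]] <- data.frame(
      gene_a = gid_a, gene_b = gid_b,
      transcript_a = ga$longest_id, transcript_b = gb$longest_id,
      cds_start_a = ga$cds_start, cds_start_b = gb$cds_start,
      protein_len = ncod,
      protein_a = substr(translate_cds(ga$cds), 1L, ncod),
      protein_b = substr(translate_cds(gb$cds), 1L, ncod),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(gene_a = character(0), gene_b = character(0),
               codon_index = integer(0), protein_pos = integer(0),
               carrier = character(0), codon_pos = integer(0),
               ref = character(0), alt = character(0), effect = character(0),
               aa_ancestral = character(0), aa_derived = character(0),
               masked = logical(0), stringsAsFactors = FALSE)
  # transcript positions of each ledger site in both species
  m <- match(ledger$gene_a, meta$gene_a)
  ledger$transcript_a <- meta$transcript_a[m]
  ledger$transcript_b <- meta$transcript_b[m]
  ledger$pos_a <- meta$cds_start_a[m] + 3L * ledger$codon_index +
    ledger$codon_pos + 1L
  ledger$pos_b <- meta$cds_start_b[m] + 3L * ledger$codon_index +
    ledger$codon_pos + 1L
  # pooled het records for masked sites (het in the carrier species)
  mk_vcf <- function(side) {
    sub <- ledger[ledger$masked & ledger$carrier == side, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(transcript_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        mq = numeric(0), gt = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(transcript_id = if (side == "a") sub$transcript_a else
                 sub$transcript_b,
               pos = if (side == "a") sub$pos_a else sub$pos_b,
               ref = sub$alt, alt = sub$ref, mq = 45, gt = "0/1",
               stringsAsFactors = FALSE)
  }
  # per-direction scores on unmasked nonsynonymous sites
  mk_scores <- function(side) {
    sub <- ledger[!ledger$masked & ledger$effect == "nonsynonymous", ,
                  drop = FALSE]
    n <- nrow(sub)
    prov_del <- runif(n) < config$deleterious_fraction_provean
    sift_del <- runif(n) < config$deleterious_fraction_sift
    sift_missing <- runif(n) < config$sift_missing_rate
    provean <- ifelse(prov_del, runif(n, -8, -2.5), runif(n, -2.4, 3))
    sift <- ifelse(sift_del, runif(n, 0, 0.049), runif(n, 0.05, 1))
    sift[sift_missing] <- NA_real_
    # amino acids as seen from the query side: a query-A row carries A's
    # residue as ref and B's as alt
    a_is_carrier <- sub$carrier == "a"
    aa_carrier <- sub$aa_derived
    aa_other <- sub$aa_ancestral
    ref_aa <- if (side == "a") ifelse(a_is_carrier, aa_carrier, aa_other)
              else ifelse(a_is_carrier, aa_other, aa_carrier)
    alt_aa <- if (side == "a") ifelse(a_is_carrier, aa_other, aa_carrier)
              else ifelse(a_is_carrier, aa_carrier, aa_other)
    list(scores = data.frame(
           transcript_id = if (side == "a") sub$transcript_a else
             sub$transcript_b,
           pos_1based = sub$protein_pos, ref_aa = ref_aa, alt_aa = alt_aa,
           provean_score = round(provean, 3), sift_score = round(sift, 4),
           stringsAsFactors = FALSE),
         truth = data.frame(gene_a = sub$gene_a, protein_pos = sub$protein_pos,
                            provean_deleterious = prov_del,
                            sift_deleterious = sift_del,
                            sift_missing = sift_missing,
                            stringsAsFactors = FALSE))
  }
  # homology tables with identity computed from the final proteins
  ident <- vapply(seq_len(nrow(meta)), function(i) {
    a <- strsplit(meta$protein_a[i], "")[[1]]
    b <- strsplit(meta$protein_b[i], "")[[1]]
    100 * mean(a == b)
  }, numeric(1))
  mk_hits <- function(q, s) {
    data.frame(query_id = q, subject_id = s, percent_identity = ident,
               alignment_length = meta$protein_len, mismatches =
                 round((100 - ident) / 100 * meta$protein_len),
               gap_opens = 0L, q_start = 1L, q_end = meta$protein_len,
               s_start = 1L, s_end = meta$protein_len, evalue = 1e-80,
               bitscore = 2 * meta$protein_len,
               query_length = meta$protein_len, stringsAsFactors = FALSE)
  }
  sc_a <- mk_scores("a")
  sc_b <- mk_scores("b")
  list(seqs_a = Biostrings::DNAStringSet(seqs_a),
       seqs_b = Biostrings::DNAStringSet(seqs_b),
       vcf_a = mk_vcf("a"), vcf_b = mk_vcf("b"),
       hits_ab = mk_hits(meta$gene_a, meta$gene_b),
       hits_ba = mk_hits(meta$gene_b, meta$gene_a),
       scores_a = sc_a$scores, scores_b = sc_b$scores,
       score_truth_a = sc_a$truth, score_truth_b = sc_b$truth,
       ledger = ledger, meta = meta, config = config)
}

#' Write variant records as VCFv4.2
#'
#' Heterozygous genotypes are written `0/1`, homozygous `1/1`; RMS mapping
#' quality goes in the `MQ` INFO key.
#'
#' @param records data.frame with `transcript_id`, `pos`, `ref`, `alt`,
#'   `mq`, `gt`.
#' @param path output path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "specimen1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  ord <- order(records$transcript_id, records$pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tMQ=%s\tGT\t%s",
                  records$transcript_id[ord], records$pos[ord],
                  records$ref[ord], records$alt[ord],
                  format(records$mq[ord], trim = TRUE),
                  records$gt[ord])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated specimen to disk
#'
#' Emits the FASTA (60-column wrap), VCF, homology TSVs, score TSV and
#' truth-ledger TSVs for one simulated specimen.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param variants output of [simulate_variants()].
#' @param scores output of [simulate_scores()].
#' @param outdir output directory (created if missing).
#' @param self_hits,plant_hits homology tables; defaults regenerate them
#'   from `sim`.
#' @return named character vector of written paths, invisibly.
#' @export
write_specimen <- function(sim, variants, scores, outdir,
                           self_hits = simulate_self_hits(sim),
                           plant_hits = simulate_plant_hits(sim)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- c(fasta = file.path(outdir, "transcripts.fasta"),
         vcf = file.path(outdir, "variants.vcf"),
         self_hits = file.path(outdir, "self_hits.tsv"),
         plant_hits = file.path(outdir, "plant_hits.tsv"),
         scores = file.path(outdir, "effect_scores.tsv"),
         gene_truth = file.path(outdir, "truth_genes.tsv"),
         variant_truth = file.path(outdir, "truth_variants.tsv"))
  Biostrings::writeXStringSet(sim$seqs, p[["fasta"]], width = 60L)
  write_vcf(variants$vcf, p[["vcf"]])
  wt <- function(x, f, col.names = TRUE) {
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = col.names)
  }
  wt(self_hits, p[["self_hits"]], col.names = FALSE)
  wt(plant_hits, p[["plant_hits"]], col.names = FALSE)
  wt(scores$scores, p[["scores"]])
  wt(sim$truth[, setdiff(names(sim$truth), "cds")], p[["gene_truth"]])
  wt(variants$truth, p[["variant_truth"]])
  invisible(p)
}
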