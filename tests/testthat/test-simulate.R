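test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(duplicated_fraction = 1.2), "probability")
  expect_error(sim_config(het_snv_rate = -0.1), "non-negative")
  expect_error(sim_config(mean_cds_len_bp = 120), "at least 150")
  expect_error(sim_config(mean_cds_len_bp = 301), "multiple of 3")
})

test_that("duplicated_fraction edge cases: none and all", {
  cfg0 <- sim_config(n_genes = 10L, duplicated_fraction = 0,
                     mean_cds_len_bp = 300L, seed = 3L)
  s0 <- simulate_transcriptome(cfg0)
  expect_equal(nrow(s0$truth), 10L)
  expect_false(any(s0$truth$duplicated))
  expect_equal(max(table(s0$truth$cluster)), 1L)
  cfg1 <- sim_config(n_genes = 10L, duplicated_fraction = 1,
                     mean_cds_len_bp = 300L, seed = 3L)
  s1 <- simulate_transcriptome(cfg1)
  expect_true(all(s1$truth$duplicated))
  expect_true(all(table(s1$truth$cluster) == 2L))
})

test_that("generated CDSs are well formed and planted frames recoverable", {
  fx <- small_sim()
  tr <- fx$sim$truth
  expect_true(all(substr(tr$cds, 1, 3) == "ATG"))
  prot <- translate_cds(tr$cds)
  expect_true(all(substr(prot, nchar(prot), nchar(prot)) == "*"))
  # no internal stops
  expect_false(any(grepl("\\*", substr(prot, 1, nchar(prot) - 1L))))
  # 1-3 isoforms, and the recorded longest really is the longest
  expect_true(all(tr$n_isoforms %in% 1:3))
  w <- Biostrings::width(fx$sim$seqs)
  ids <- parse_trinity_id(names(fx$sim$seqs))
  for (g in tr$gene_id[1:5]) {
    iso_w <- w[ids$gene_id == g]
    expect_equal(max(iso_w),
                 w[names(fx$sim$seqs) == tr$transcript_id[tr$gene_id == g]])
  }
})

test_that("same seed and config give byte-identical outputs", {
  cfg <- sim_config(n_genes = 8L, mean_cds_len_bp = 300L, seed = 9L)
  a <- simulate_transcriptome(cfg); b <- simulate_transcriptome(cfg)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  va <- simulate_variants(a, cfg); vb <- simulate_variants(b, cfg)
  expect_identical(va, vb)
  expect_identical(simulate_scores(va, cfg), simulate_scores(vb, cfg))
  d <- withr::local_tempdir()
  p1 <- write_specimen(a, va, simulate_scores(va, cfg), file.path(d, "r1"))
  p2 <- write_specimen(b, vb, simulate_scores(vb, cfg), file.path(d, "r2"))
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), info = f)
  }
})

test_that("zero variant rate yields a header-only VCF", {
  cfg <- sim_config(n_genes = 5L, het_snv_rate = 0, mean_cds_len_bp = 300L,
                    seed = 4L)
  sim <- simulate_transcriptome(cfg)
  v <- simulate_variants(sim, cfg)
  expect_equal(nrow(v$vcf), 0L)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v$vcf, f)
  expect_true(all(startsWith(readLines(f), "#")))
})

test_that("pure-missense composition annotates as 100% missense", {
  cfg <- sim_config(n_genes = 10L, mean_cds_len_bp = 300L,
                    het_snv_rate = 0.01, nonsyn_target_fraction = 1,
                    nonsense_given_nonsyn = 0, seed = 6L)
  sim <- simulate_transcriptome(cfg)
  v <- simulate_variants(sim, cfg, low_mq_fraction = 0, hom_fraction = 0)
  regions <- find_coding_regions(select_longest_isoform(sim$seqs))
  ann <- annotate_snvs(filter_snvs(v$vcf), regions)
  expect_gt(nrow(ann), 0L)
  expect_true(all(ann$effect == "missense"))
})

test_that("generated files parse with strict standard parsers", {
  fx <- small_sim()
  d <- withr::local_tempdir()
  p <- write_specimen(fx$sim, fx$variants, fx$scores, d)
  fa <- Biostrings::readDNAStringSet(p[["fasta"]])
  expect_identical(as.character(fa), as.character(fx$sim$seqs))
  snvs <- read_vcf_snvs(p[["vcf"]], mq_threshold = -Inf)
  expect_equal(nrow(snvs), nrow(fx$variants$vcf))
  hits <- read_blast_tab(p[["self_hits"]])
  expect_equal(nrow(hits), nrow(fx$self_hits))
  sc <- read_score_table(p[["scores"]])
  expect_equal(nrow(sc), nrow(fx$scores$scores))
  expect_equal(sum(is.na(sc$sift_score)), sum(is.na(fx$scores$scores$sift_score)))
})

test_that("score generator hits the configured deleterious fractions", {
  cfg <- sim_config(n_genes = 60L, mean_cds_len_bp = 600L,
                    het_snv_rate = 0.01, nonsyn_target_fraction = 0.8,
                    deleterious_fraction_provean = 0.4,
                    deleterious_fraction_sift = 0.3,
                    sift_missing_rate = 0.2, seed = 13L)
  sim <- simulate_transcriptome(cfg)
  v <- simulate_variants(sim, cfg)
  sc <- simulate_scores(v, cfg)
  n <- nrow(sc$scores)
  prop_del <- mean(sc$scores$provean_score <= -2.5)
  expect_lt(abs(prop_del - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  miss <- mean(is.na(sc$scores$sift_score))
  expect_lt(abs(miss - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  ev <- sc$scores$sift_score[!is.na(sc$scores$sift_score)]
  expect_lt(abs(mean(ev < 0.05) - 0.3), 3 * sqrt(0.3 * 0.7 / length(ev)))
})

test_that("zero divergence gives identical orthologs and no ledger", {
  cfg <- sim_config(n_genes = 5L, mean_cds_len_bp = 300L,
                    interspecies_divergence = 0, seed = 21L)
  p <- simulate_species_pair(cfg)
  expect_equal(nrow(p$ledger), 0L)
  res <- analyze_species_pair(p$seqs_a, p$seqs_b, p$vcf_a, p$vcf_b,
                              p$hits_ab, p$hits_ba, p$scores_a, p$scores_b)
  expect_equal(nrow(res$sites), 0L)
  expect_equal(nrow(res$pairs), 5L)
})
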