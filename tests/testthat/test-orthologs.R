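mk_ohit <- function(q, s, ident = 95, evalue = 1e-50, alen = 200,
                    qlen = 200) {
  data.frame(query_id = q, subject_id = s, percent_identity = ident,
             alignment_length = alen, mismatches = 5L, gap_opens = 0L,
             q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
             evalue = evalue, bitscore = 400, query_length = qlen,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits pair at > 80% identity, strict boundary", {
  ab <- rbind(mk_ohit("A1", "B1", 95), mk_ohit("A2", "B2", 80))
  ba <- rbind(mk_ohit("B1", "A1", 95), mk_ohit("B2", "A2", 80))
  pairs <- pair_orthologs(ab, ba)
  expect_equal(pairs$gene_a, "A1")   # 80.0 exactly is excluded
  # non-reciprocal best: B1's best is A9, so A1-B1 dissolves
  ba2 <- rbind(mk_ohit("B1", "A9", 99, evalue = 1e-80), mk_ohit("B1", "A1", 95))
  expect_equal(nrow(pair_orthologs(ab, ba2)), 0L)
})

test_that("identical CDSs yield no substitution sites", {
  reg <- region_row(paste(c("ATG", rep(c("TAC", "CTG", "AAA"), 20)),
                          collapse = ""))
  sites <- find_substitutions(reg, reg)
  expect_equal(nrow(sites), 0L)
})

test_that("a single third-position difference is one synonymous site", {
  codons <- c("ATG", rep(c("TAC", "CTG", "AAA"), 20))
  reg_a <- region_row(paste(codons, collapse = ""))
  codons_b <- codons
  codons_b[6] <- "CTA"  # CTG -> CTA, Leu/Leu
  reg_b <- region_row(paste(codons_b, collapse = ""), id = "T_c2_g1_i1")
  sites <- find_substitutions(reg_a, reg_b)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos_a, 6L)
  expect_equal(sites$effect, "synonymous")
})

test_that("heterozygous masks suppress sites in either species", {
  codons <- c("ATG", rep(c("TAC", "CTG", "AAA"), 20))
  codons_b <- codons
  codons_b[5] <- "CTA"; codons_b[10] <- "TAT"
  reg_a <- region_row(paste(codons, collapse = ""))
  reg_b <- region_row(paste(codons_b, collapse = ""), id = "T_c2_g1_i1")
  # mask the codon-5 change via species A transcript coordinates
  mask_a <- reg_a$start + 3L * 4L + 3L  # third base of codon 5, 1-based
  sites <- find_substitutions(reg_a, reg_b, mask_a = mask_a)
  expect_equal(sites$pos_a, 10L)
  expect_equal(attr(sites, "n_masked"), 1L)
  # mask the other via species B
  mask_b <- reg_b$start + 3L * 9L + 3L
  sites2 <- find_substitutions(reg_a, reg_b, mask_b = mask_b)
  expect_equal(sites2$pos_a, 5L)
})

test_that("site discovery is direction symmetric", {
  fx <- small_pair()
  p <- fx$pair
  ref_a <- build_integrated_reference(p$seqs_a, p$vcf_a)
  ref_b <- build_integrated_reference(p$seqs_b, p$vcf_b)
  pairs <- pair_orthologs(p$hits_ab, p$hits_ba)
  fwd <- ortholog_substitutions(pairs, ref_a, ref_b)
  rev_pairs <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                          stringsAsFactors = FALSE)
  rev <- ortholog_substitutions(rev_pairs, ref_b, ref_a)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(fwd$transcript_a, fwd$pos_a, fwd$codon_a),
                  paste(rev$transcript_b, rev$pos_b, rev$codon_b))
})

test_that("substitution discovery matches the generator ledger exactly", {
  fx <- small_pair()
  p <- fx$pair
  res <- analyze_species_pair(p$seqs_a, p$seqs_b, p$vcf_a, p$vcf_b,
                              p$hits_ab, p$hits_ba, p$scores_a, p$scores_b)
  led <- p$ledger[!p$ledger$masked, ]
  key_led <- paste(led$gene_a, led$protein_pos)
  key_found <- paste(res$sites$gene_a, res$sites$pos_a)
  expect_setequal(key_found, key_led)          # recall and precision 100%
  m <- match(key_found, key_led)
  expect_equal(res$sites$effect, led$effect[m])
  # masked sites are never reported
  masked <- paste(p$ledger$gene_a[p$ledger$masked],
                  p$ledger$protein_pos[p$ledger$masked])
  expect_length(intersect(masked, key_found), 0L)
  # the het mask equals an independent recount of pooled het genotypes
  ref_a <- build_integrated_reference(p$seqs_a, p$vcf_a)
  expect_setequal(paste(ref_a$mask$transcript_id, ref_a$mask$pos),
                  paste(p$vcf_a$transcript_id, p$vcf_a$pos))
})

test_that("high divergence pushes pairs below the 80% identity cliff", {
  cfg <- sim_config(n_genes = 8L, mean_cds_len_bp = 300L,
                    interspecies_divergence = 0.35, seed = 77L)
  p <- simulate_species_pair(cfg, mask_fraction = 0)
  # recompute identity independently from the sequences
  ident <- vapply(seq_len(nrow(p$meta)), function(i) {
    a <- strsplit(p$meta$protein_a[i], "")[[1]]
    b <- strsplit(p$meta$protein_b[i], "")[[1]]
    100 * mean(a == b)
  }, numeric(1))
  pairs <- pair_orthologs(p$hits_ab, p$hits_ba)
  expect_setequal(pairs$gene_a, p$meta$gene_a[ident > 80])
})

test_that("deleterious substitution fractions follow the literal rules", {
  sites <- data.frame(gene_a = "GA", gene_b = "GB",
                      transcript_a = "GA_i1", transcript_b = "GB_i1",
                      pos_a = 1:3, pos_b = 1:3,
                      codon_a = "TAC", codon_b = "GAC",
                      aa_a = "Y", aa_b = "D", effect = "nonsynonymous",
                      stringsAsFactors = FALSE)
  scores <- data.frame(transcript_id = "GA_i1", pos_1based = 1:3,
                       ref_aa = "Y", alt_aa = "D",
                       provean_score = c(-3.0, -1.0, 2.0),
                       sift_score = c(0.01, NA, 0.5),
                       stringsAsFactors = FALSE)
  prov <- deleterious_substitution_fraction(sites, scores, "a", "provean")
  expect_equal(prov$per_gene$fraction, 1 / 2)  # denominator: scores < 0
  prov_all <- deleterious_substitution_fraction(
    sites, scores, "a", "provean", provean_denominator = "all_nonsyn")
  expect_equal(prov_all$per_gene$fraction, 1 / 3)
  sift <- deleterious_substitution_fraction(sites, scores, "a", "sift")
  expect_equal(sift$per_gene$n_denominator, 2L)  # NA excluded
  expect_equal(sift$per_gene$fraction, 1 / 2)
})
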