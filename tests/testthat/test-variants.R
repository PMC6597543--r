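mk_rec <- function(id = "T_c1_g1_i1", pos = 11L, ref = "A", alt = "G",
                   mq = 50, gt = "0/1") {
  data.frame(transcript_id = id, pos = pos, ref = ref, alt = alt, mq = mq,
             gt = gt, stringsAsFactors = FALSE)
}

test_that("MQ filter is strictly greater-than 30", {
  recs <- rbind(mk_rec(mq = 30), mk_rec(pos = 12L, mq = 30.01),
                mk_rec(pos = 13L, mq = 31))
  out <- filter_snvs(recs)
  expect_equal(out$pos, c(12L, 13L))
  expect_equal(attr(out, "counts")$n_low_mq, 1L)
})

test_that("indels, multiallelics and uncalled genotypes are dropped", {
  recs <- rbind(mk_rec(ref = "AT", alt = "A"),        # indel
                mk_rec(pos = 12L, alt = "G,T"),       # multiallelic
                mk_rec(pos = 13L, gt = "./1"),        # half call
                mk_rec(pos = 14L, gt = "0/0"),        # not a variant
                mk_rec(pos = 15L, gt = "0|1"),        # phased het
                mk_rec(pos = 16L, gt = "1/1"))        # hom
  out <- filter_snvs(recs)
  expect_equal(out$pos, c(15L, 16L))
  expect_equal(out$zygosity, c("het", "hom"))
  cnt <- attr(out, "counts")
  expect_equal(cnt$n_not_snv, 2L)
  expect_equal(cnt$n_missing_gt, 1L)
  expect_equal(cnt$n_ref_only, 1L)
})

test_that("annotation classifies codon changes and positions correctly", {
  # CDS at offset 10 on a plus-strand transcript: ATG TAC CTG AAA
  reg <- region_row("ATGTACCTGAAA")
  # TAC -> TAA (codon 2, pos 3): nonsense
  a <- annotate_snvs(mk_rec(pos = 10L + 6L, ref = "C", alt = "A"), reg)
  expect_equal(a$effect, "nonsense")
  expect_equal(a$codon_index, 1L)
  expect_equal(a$codon_pos, 2L)
  # CTG -> CTA: synonymous (Leu)
  b <- annotate_snvs(mk_rec(pos = 10L + 9L, ref = "G", alt = "A"), reg)
  expect_equal(b$effect, "synonymous")
  # outside the CDS -> noncoding
  d <- annotate_snvs(mk_rec(pos = 3L, ref = "A", alt = "G"), reg)
  expect_equal(d$effect, "noncoding")
})

test_that("annotation is strand aware", {
  cds <- "ATGTACCTGAAA"
  tx_plus <- paste0(rand_dna(10, seed = 9), cds, rand_dna(8))
  tx_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tx_plus)))
  reg_minus <- region_row(cds, tx_len = nchar(tx_minus), strand = "-",
                          start = 8L)
  # the plus-strand TAC->TAA change sits mirrored on the minus strand
  # with complemented alleles
  pos_plus <- 10L + 6L
  pos_minus <- nchar(tx_plus) - pos_plus + 1L
  a <- annotate_snvs(mk_rec(pos = pos_minus, ref = "G", alt = "T"),
                     reg_minus)
  expect_equal(a$effect, "nonsense")
  expect_equal(a$codon_index, 1L)
})

test_that("annotate agrees with the 576-change enumeration through a CDS", {
  oracle <- oracle_codon_changes()
  oracle <- oracle[oracle$ref_aa != "*", ]  # stop codons never sit in a CDS
  set.seed(31)
  pick <- oracle[sample(nrow(oracle), 120), ]
  for (i in seq_len(nrow(pick))) {
    cds <- paste0("ATG", pick$codon[i], "CTGAAA")
    reg <- region_row(cds, start = 5L)
    rec <- mk_rec(pos = 5L + 3L + pick$codon_pos[i] + 1L,
                  ref = substr(pick$codon[i], pick$codon_pos[i] + 1L,
                               pick$codon_pos[i] + 1L),
                  alt = pick$alt[i])
    a <- annotate_snvs(rec, reg)
    expect_equal(a$effect, pick$effect[i])
  }
})

test_that("reference-allele mismatches are flagged unassessable", {
  reg <- region_row("ATGTACCTGAAA")
  expect_warning(
    a <- annotate_snvs(mk_rec(pos = 10L + 6L, ref = "G", alt = "A"), reg),
    "disagrees")
  expect_equal(a$effect, "unassessable")
})

test_that("positions beyond the transcript and unknown IDs error", {
  reg <- region_row("ATGTACCTGAAA")
  expect_error(annotate_snvs(mk_rec(pos = 1000L), reg), "beyond")
  expect_error(annotate_snvs(mk_rec(id = "GHOST_c1_g1_i1"), reg,
                             known_ids = reg$transcript_id), "absent")
})

test_that("per-transcript summaries: arithmetic and conservation", {
  fx <- small_sim()
  regions <- find_coding_regions(select_longest_isoform(fx$sim$seqs))
  snvs <- filter_snvs(fx$variants$vcf)
  ann <- annotate_snvs(snvs, regions, known_ids = names(fx$sim$seqs))
  summ <- summarize_transcripts(ann, regions)
  # conservation: class counts add up to the coding het total
  het_coding <- ann[ann$zygosity == "het" &
                      ann$effect %in% c("synonymous", "missense", "nonsense"), ]
  expect_equal(sum(summ$n_total), nrow(het_coding))
  # classes recovered exactly from the generator ledger (passing records)
  truth <- fx$variants$truth
  truth <- truth[!truth$low_mq & truth$gt == "0/1", ]
  expect_equal(sum(summ$n_syn), sum(truth$class == "synonymous"))
  expect_equal(sum(summ$n_nonsense), sum(truth$class == "nonsense"))
  # spot arithmetic
  i <- which(summ$n_total > 0)[1]
  expect_equal(summ$syn_per_kb[i], 1000 * summ$n_syn[i] / summ$cds_len_bp[i])
})

test_that("specimen indices: worked example and universe restriction", {
  reg <- rbind(region_row(paste(rep("ATGTACCTGAAA", 125), collapse = ""),
                          tx_len = 1520L, id = "T_c1_g1_i1"),
               region_row(paste(rep("ATGTACCTGAAA", 125), collapse = ""),
                          tx_len = 1520L, id = "T_c2_g1_i1"))
  # 3 syn on a 1500-bp CDS -> 2.0/kb; 2 syn + 2 missense + 1 nonsense
  recs <- rbind(
    mk_rec(pos = 10L + 9L, ref = "G", alt = "A"),             # syn
    mk_rec(pos = 10L + 21L, ref = "G", alt = "T"),            # syn CTG->CTT
    mk_rec(pos = 10L + 33L, ref = "G", alt = "C"),            # syn
    mk_rec(id = "T_c2_g1_i1", pos = 10L + 9L, ref = "G", alt = "A"),   # syn
    mk_rec(id = "T_c2_g1_i1", pos = 10L + 21L, ref = "G", alt = "C"),  # syn
    mk_rec(id = "T_c2_g1_i1", pos = 10L + 4L, ref = "T", alt = "G"),   # missense
    mk_rec(id = "T_c2_g1_i1", pos = 10L + 16L, ref = "T", alt = "G"),  # missense
    mk_rec(id = "T_c2_g1_i1", pos = 10L + 30L, ref = "C", alt = "A"))  # nonsense
  ann <- annotate_snvs(filter_snvs(recs), reg)
  summ <- summarize_transcripts(ann, reg)
  t1 <- summ[summ$transcript_id == "T_c1_g1_i1", ]
  expect_equal(t1$syn_per_kb, 2.0)
  # 2 syn + 2 missense + 1 nonsense
  t2 <- summ[summ$transcript_id == "T_c2_g1_i1", ]
  expect_equal(t2$n_total, 5L)
  expect_equal(t2$nonsyn_fraction, 0.6)
  expect_equal(t2$nonsense_fraction, 1 / 3)
  idx <- specimen_indices(summ)
  expect_equal(idx$syn_per_kb, mean(summ$syn_per_kb))
  # restricting the universe drops excluded genes
  cls <- data.frame(gene_id = c("T_c1_g1", "T_c2_g1"),
                    label = c("singleton", "excluded_no_plant_homology"))
  idx2 <- specimen_indices(summ, cls)
  expect_equal(idx2$n_transcripts, 1L)
  expect_equal(idx2$syn_per_kb, t1$syn_per_kb)
})
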