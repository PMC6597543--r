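mk_hit <- function(q, s, evalue = 1e-10, alen = 100, qlen = 150,
                   ident = 90) {
  data.frame(query_id = q, subject_id = s, percent_identity = ident,
             alignment_length = alen, mismatches = 5L, gap_opens = 0L,
             q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
             evalue = evalue, bitscore = 200, query_length = qlen,
             stringsAsFactors = FALSE)
}
plant_hit <- function(q, evalue = 1e-10) mk_hit(q, "PLANT_1", evalue)

test_that("duplication rule applies E-value and coverage thresholds", {
  genes <- c("G1", "G2", "G3", "G4")
  self <- rbind(
    mk_hit("G1", "G2", evalue = 1e-10, alen = 75, qlen = 150),  # cov 50%
    mk_hit("G2", "G1", evalue = 1e-10, alen = 30, qlen = 120),  # cov 25%
    mk_hit("G3", "G3"))                                         # self-hit
  plants <- rbind(plant_hit("G1"), plant_hit("G2"), plant_hit("G3"))
  cl <- classify_duplication(self, plants, genes)
  lab <- setNames(cl$label, cl$gene_id)
  expect_equal(lab[["G1"]], "duplicated")
  expect_equal(lab[["G2"]], "singleton")       # coverage below 30%
  expect_equal(lab[["G3"]], "singleton")       # self-hit ignored
  expect_equal(lab[["G4"]], "excluded_no_plant_homology")
})

test_that("thresholds are strict as printed", {
  genes <- c("G1", "G2")
  plants <- rbind(plant_hit("G1"), plant_hit("G2"))
  # coverage exactly 30% does not qualify
  cl <- classify_duplication(mk_hit("G1", "G2", alen = 45, qlen = 150),
                             plants, genes)
  expect_equal(cl$label[cl$gene_id == "G1"], "singleton")
  # E-value exactly 1e-4 does not qualify
  cl <- classify_duplication(mk_hit("G1", "G2", evalue = 1e-4),
                             plants, genes)
  expect_equal(cl$label[cl$gene_id == "G1"], "singleton")
  # plant retention also strict on E
  cl <- classify_duplication(mk_hit("G1", "G2"),
                             rbind(plant_hit("G1"), plant_hit("G2", 1e-4)),
                             genes)
  expect_equal(cl$label[cl$gene_id == "G2"], "excluded_no_plant_homology")
})

test_that("genes without plant homology are excluded regardless of hits", {
  cl <- classify_duplication(mk_hit("G1", "G2"), plant_hit("G2"),
                             c("G1", "G2"))
  expect_equal(cl$label[cl$gene_id == "G1"], "excluded_no_plant_homology")
})

test_that("classification is directional and ignores reciprocal absence", {
  # A hits B above thresholds, B has no qualifying row of its own
  cl <- classify_duplication(mk_hit("A", "B"),
                             rbind(plant_hit("A"), plant_hit("B")),
                             c("A", "B"))
  expect_equal(cl$label[cl$gene_id == "A"], "duplicated")
  expect_equal(cl$label[cl$gene_id == "B"], "singleton")
})

test_that("P_D arithmetic and invariance to hit order/duplication", {
  genes <- sprintf("G%d", 1:10)
  self <- do.call(rbind, lapply(1:7, function(i)
    mk_hit(genes[i], genes[11 - i])))
  plants <- do.call(rbind, lapply(genes, plant_hit))
  cl <- classify_duplication(self, plants, genes)
  expect_equal(compute_pd(cl)$pd, 0.7)
  # shuffled and duplicated hit rows change nothing
  set.seed(3)
  messy <- rbind(self, self)[sample(14), ]
  expect_equal(classify_duplication(messy, plants, genes), cl)
  # zero duplicated
  cl0 <- classify_duplication(mk_hit("G1", "G1"), plants, genes)
  expect_equal(compute_pd(cl0)$pd, 0)
})

test_that("error cases: unknown genes, missing qlen, empty universe", {
  expect_error(classify_duplication(mk_hit("GX", "G1"), plant_hit("G1"),
                                    "G1"), "unknown gene")
  bad <- mk_hit("G1", "G1"); bad$query_length <- NA
  expect_error(classify_duplication(bad, plant_hit("G1"), "G1"),
               "query_length")
  cl <- classify_duplication(mk_hit("G1", "G1"), plant_hit("G1")[0, ],
                             c("G1"))
  expect_error(compute_pd(cl), "undefined")
})

test_that("P_D recovery on the simulated transcriptome is exact", {
  fx <- small_sim()
  regions <- find_coding_regions(select_longest_isoform(fx$sim$seqs))
  cl <- classify_duplication(fx$self_hits, fx$plant_hits, regions$gene_id)
  expect_equal(compute_pd(cl)$pd, mean(fx$sim$truth$duplicated))
})
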