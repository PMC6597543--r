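# Small shared simulated fixtures, built once per test run.

.fixtures <- new.env()

small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(n_genes = 40L, duplicated_fraction = 0.5,
                      mean_cds_len_bp = 600L, het_snv_rate = 0.004,
                      nonsyn_target_fraction = 0.55,
                      nonsense_given_nonsyn = 0.06, seed = 101L)
    sim <- simulate_transcriptome(cfg, "FIX")
    variants <- simulate_variants(sim, cfg)
    scores <- simulate_scores(variants, cfg)
    .fixtures$sim <- list(cfg = cfg, sim = sim, variants = variants,
                          scores = scores,
                          self_hits = simulate_self_hits(sim),
                          plant_hits = simulate_plant_hits(sim))
  }
  .fixtures$sim
}

small_pair <- function() {
  if (is.null(.fixtures$pair)) {
    cfg <- sim_config(n_genes = 25L, mean_cds_len_bp = 600L,
                      interspecies_divergence = 0.02, seed = 202L)
    .fixtures$pair <- list(cfg = cfg,
                           pair = simulate_species_pair(cfg,
                                                        mask_fraction = 0.15))
  }
  .fixtures$pair
}

# hand-built coding region row for annotation tests
region_row <- function(cds, tx_len = nchar(cds) + 20L, strand = "+",
                       start = 10L, id = "T_c1_g1_i1") {
  plen <- nchar(cds) / 3L
  data.frame(transcript_id = id, tx_len = tx_len, strand = strand,
             start = start, end = start + nchar(cds),
             cds = cds, protein = substr(translate_cds(cds), 1, plen),
             protein_len = plen, gene_id = sub("_i[0-9]+$", "", id),
             stringsAsFactors = FALSE)
}
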