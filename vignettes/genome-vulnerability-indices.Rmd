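---
title: "Genome-vulnerability indices: models, thresholds and design choices"
author: "genomevuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-vulnerability indices: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomevuln)
```

## The comparative model

`genomevuln` compares congeneric plant species — endangered island
endemics (EIE) against non-endangered widespread relatives (NE) — on six
transcriptome-derived indices of genomic vulnerability. The underlying
population-genetic expectations are:

* **Synonymous heterozygosity (syn/kb)** is approximately neutral and
  tracks effective population size; bottlenecked island populations
  should show less of it.
* **The nonsynonymous fraction of heterozygous SNVs** rises when
  purifying selection is inefficient (small *N*e); most nonsynonymous
  mutations are deleterious or neutral, and beneficial ones are
  negligible at small population size, so a higher fraction indicates
  relaxed selection rather than adaptation.
* **The nonsense fraction** (premature stop codons among nonsynonymous
  SNVs) is the extreme of that signal: loss-of-function variation.
* **PROVEAN / SIFT deleterious fractions** quantify the predicted impact
  of the segregating amino-acid variants.
* **The duplicated-gene proportion (*P*D)** correlates with the
  environmental breadth a species experiences; range-restricted island
  endemics are expected to retain fewer duplicates.
* **Deleterious substitution fractions** between species (homozygous
  differences at orthologous codons) reflect the *long-term* efficacy of
  selection since the lineages split, complementing the within-species
  (heterozygous) indices that reflect recent history.

All per-specimen analysis happens on the longest transcript per gene
(Trinity-style cluster/gene/isoform IDs collapse to a gene by dropping
the isoform suffix), restricted to predicted proteins of at least 50
amino acids with homology to a plant protein database.

## Thresholds

Every threshold has the analysis-standard value as its default and is
overridable as a function argument:

| parameter | default | comparison | where |
|---|---|---|---|
| RMS mapping quality | 30 | strictly `>` | `filter_snvs()` |
| homology E-value | 1e-4 | strictly `<` | `classify_duplication()`, `pair_orthologs()` |
| query coverage (duplication) | 30% | strictly `>` | `classify_duplication()` |
| ortholog protein identity | 80% | strictly `>` | `pair_orthologs()` |
| PROVEAN deleterious | −2.5 | `<=` (boundary inclusive) | `classify_provean()` |
| SIFT deleterious | 0.05 | strictly `<` | `classify_sift()` |
| minimum protein length | 50 aa | `>=` | `find_coding_regions()` |

Strictness follows the printed form of each rule; the PROVEAN boundary is
inclusive because the predictor's own convention is "deleterious at or
below −2.5". Query coverage is computed on protein lengths
(`100 · alignment_length / query_length`), which is the natural unit for
BLASTP tables; the plant-database retention filter applies only the
E-value, with no coverage requirement.

## Reading-frame identification

No ORF-finding tool is prescribed by the analysis, so the package uses a
deterministic, oracle-checkable rule: the coding region of a transcript
is the longest stop-free codon stretch over all six frames, edge
tolerant — no ATG requirement and no terminal-stop requirement, because
de novo assemblies are frequently 5′- or 3′-incomplete. Ties are broken
by strand (`+` first) and then smallest start coordinate, making
selection reproducible. Codons containing `N` translate to `X` and do
not interrupt an open reading frame; SNVs falling in such codons are
classified `unassessable` and excluded from all counts, as are SNVs
whose VCF reference allele disagrees with the assembly base (logged with
a warning). Coordinates are 0-based half-open internally and 1-based in
everything written to or read from TSV/VCF.

## Variant annotation and index denominators

Only biallelic single-nucleotide records with a called diploid genotype
enter the analysis; the heterozygous/homozygous distinction comes solely
from the genotype field (`0/1`-like heterozygous, `1/1` homozygous;
half-calls are skipped and counted). Homozygous SNVs are
assembly-vs-individual differences and are excluded from the
heterozygosity indices. Each SNV is substituted into its reference codon
(alleles complemented for minus-strand coding regions) and the two
translations compared. Multiple SNVs in one codon are annotated
independently against the reference codon; phase is unknowable here and
such codons are rare at observed densities. A SNV in the terminal stop
codon is outside the protein-coding span and classified `noncoding`.

Denominator choices, which the source analysis leaves partly open, are
fixed as follows and applied uniformly:

* The transcript universe for **all** six indices is the set of genes
  with a retained coding region *and* plant-database homology, so the
  indices are internally consistent (the deleterious fractions are only
  defined on that universe anyway).
* `syn_per_kb` is the unweighted mean over every universe transcript
  (zero-SNV transcripts contribute 0), per kb of coding sequence
  (terminal stop excluded).
* The nonsynonymous and nonsense fractions are unweighted means over
  transcripts with at least one coding heterozygous SNV (at least one
  nonsynonymous SNV for the nonsense fraction); mean-of-transcripts is
  used rather than pooled counts because species are compared on mean
  values of per-transcript distributions.
* Deleterious fractions are per-gene proportions among *evaluated*
  nonsynonymous SNVs, averaged over genes with at least one evaluated
  SNV. SIFT-unevaluated variants leave both numerator and denominator;
  an all-unevaluated result is reported as no-data (`NA`), distinct
  from 0. Only the reference→alternate direction is scored: with two
  heterozygous alleles the ancestral state is unknown, but a |score|
  beyond threshold flags a large functional difference between the
  alleles in either direction.

## The interspecies substitution layer

Orthologs are reciprocal best BLASTP hits above 80% identity, one
longest-CDS transcript per gene per species ("same gene ID" is
within-assembly isoform collapsing — cross-species IDs cannot match by
construction). Coordinate matching between the two coding sequences uses
a global protein alignment (BLOSUM62, affine gaps: opening 10, extension
0.5) back-projected to codons; with protein-level gaps, frameshifts
cannot arise in the projected CDS alignment. A substitution site is a
gap-free aligned codon pair that differs, provided no base of either
codon is heterozygous in the corresponding species' pooled calls. The
heterozygosity mask uses *every* heterozygous record in the pooled VCF,
without a mapping-quality filter — the mask is an exclusion list, and
masking conservatively is the safer direction. Codons within 2 alignment
columns of a gap are also excluded (alignment-uncertainty guard); both
exclusion counts are reported as attributes.

For PROVEAN-based substitution fractions the denominator is, by default,
nonsynonymous substitutions with a *negative* query-direction score
(`provean_denominator = "negative_scores"`): a positive score marks an
amino acid better supported in the database species than in the query,
i.e. the impact sits on the other lineage. Because the alternative
reading (all scored nonsynonymous substitutions) is defensible, it is
available as `provean_denominator = "all_nonsyn"`. Everything is
computed twice, with each species as the query.

## The statistical layer

Species values are arithmetic means of specimen values (a single
specimen passes through). Within a genus every EIE×NE species pair is
compared: Welch *t* tests (unequal variances; the Student variant via
`var_equal = TRUE`) on per-gene value distributions pooled over
specimens, two-sided throughout. Across genera the trend of each index
is tested with a two-sided exact binomial test on the number of
concordant pairs, p = min(1, 2·tail) under Binomial(n, ½); ties abort
with an error rather than being silently dropped. Two-sidedness is
verifiable from the reproduced values: 10/10 concordant gives 0.00195
(printed 0.002), not the one-sided 0.001. No multiple-testing correction
is applied, matching the original analysis; reported values round to 3
decimals but all comparisons use unrounded values.

The bundled `ogasawara_indices()` table carries the published
per-specimen values at 3-decimal precision. The published species
averages were computed from unrounded specimen values, so a mean of the
printed specimen rows can differ from the printed average by one unit in
the third decimal; the package's tests therefore check aggregation to
within 0.001.

`analyze_specimen(..., exclude_paralogs = TRUE)` recomputes every
SNV-based index on singleton genes only, the control for heterozygosity
artifacts caused by reads mis-mapped across paralogs. *P*D is reported
as `NA` in that mode (it is undefined on a set that excludes duplicates
by construction).

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates. The
defaults describe a mid-sized expressed-gene sample with the magnitudes
seen in the real study system: 500 genes of mean CDS 900 bp, 70% of
genes in size-2 duplicate families, 2 heterozygous SNVs per kb of coding
sequence, 55% of SNVs nonsynonymous with 4% of those nonsense, PROVEAN
and SIFT deleterious fractions of 0.35 and 0.25 with 10% of SIFT scores
missing, and 2% coding-site divergence between congeneric species.
`eie_like_config()` / `ne_like_config()` are contrast presets whose
differences mirror the direction and rough magnitude of the published
EIE-vs-NE contrasts (e.g. *P*D 0.60 vs 0.85, het rate 0.002 vs 0.005 per
bp, nonsynonymous share 0.70 vs 0.45).

What the generator emulates: Trinity-like ID structure with 1–3 isoforms
per gene (strictly shorter 3′ truncations); ATG-initiated, stop-terminated
CDSs with uniform codon usage and an in-frame upstream stop bounding the
reading frame; gene families as low-divergence duplicates whose homology
table rows carry full-coverage, tiny-E-value hits; class-targeted SNV
placement (at most one SNV per codon) with a controllable low-MQ share
and a small homozygous admixture; effect scores drawn on the correct
side of each threshold; and diverged ortholog pairs with per-site truth
ledgers and heterozygosity masks. Because a random transcript can, by
chance, contain a stop-free run in another frame that rivals the planted
CDS, the generator verifies each transcript with an internal six-frame
scanner and regenerates the gene until the planted frame is the unique
longest ORF — at the default CDS length this rejects well under 1% of
draws.

What it does **not** emulate: read-level error, expression variation and
coverage-dependent genotype confidence, assembly chimerism or
fragmentation, codon-usage bias, linkage between variants, and indel
divergence between orthologs (the alignment path is exercised, but gap
placement is not stress-tested by the generator). Passing the recovery
suite therefore validates the estimators and their denominators, not
robustness to upstream assembly artifacts.

Determinism: every generator function seeds the RNG itself (offsets +1,
+2, +3 from `config$seed` for variants, scores and species pairs, so the
streams differ), and identical config + seed gives byte-identical output
files.

## Problem sizes used in the checks

The test and acceptance runs use sizes chosen to make sampling error
small relative to the effects being recovered while keeping runs quick:
a 500-gene specimen for parameter recovery (3-standard-error bands,
computed from the realized per-transcript/per-gene spread); ten
simulated genera at 150 genes per species for the cross-genus sign test
(the preset contrasts are ≳4 standard errors per pair, so full
concordance is the expected outcome, not a coin flip); and a 60-gene
species pair at 2% divergence with 15% of substitution sites
heterozygosity-masked for the substitution-ledger check, where recall
and precision are exact requirements, not approximations.

## Known limitations

* The effect classifier assumes the standard genetic code and ignores
  phase between SNVs in one codon.
* The heterozygosity indices inherit whatever ascertainment the upstream
  caller imposes; the package only enforces the MQ > 30 and biallelic
  filters.
* *P*D from RNA-seq depends on what was expressed in the sampled tissue;
  multiple specimens per species are advisable, and the specimen→species
  aggregation treats specimens as exchangeable.
* The substitution layer does not polarize changes against an outgroup
  (no ancestral-state inference) and does not estimate dN/dS; its
  deleterious fractions are conditional on the reciprocal-best-hit
  ortholog set at > 80% identity.
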