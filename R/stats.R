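# Statistical comparison layer: specimen -> species aggregation, per-genus
# Welch t tests on per-gene value distributions, and cross-genus two-sided
# exact binomial (sign) tests on the direction of each EIE-vs-NE
# comparison.

# The six indices and the direction theory predicts for an endangered
# island endemic relative to its widespread congener.
.INDEX_COLS <- c("pd", "syn_per_kb", "nonsyn_fraction", "nonsense_fraction",
                 "provean_fraction", "sift_fraction")
.EXPECTED_DIRECTION <- c(
  pd = "eie_lower", syn_per_kb = "eie_lower",
  nonsyn_fraction = "eie_higher", nonsense_fraction = "eie_higher",
  provean_fraction = "eie_higher", sift_fraction = "eie_higher")

#' Expected EIE-vs-NE direction per index
#'
#' Lower duplicated-gene proportion and synonymous diversity, higher
#' nonsynonymous, nonsense and deleterious fractions are the directions
#' expected for endangered island endemics.
#'
#' @return named character vector over the six indices.
#' @export
index_directions <- function() .EXPECTED_DIRECTION

#' Aggregate specimen values to a species value
#'
#' The species value is the arithmetic mean of per-specimen values; a
#' single specimen's value passes through unchanged.
#'
#' @param x numeric vector of per-specimen index values.
#' @return numeric scalar.
#' @export
species_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' Welch t test on per-gene value distributions
#'
#' Two-sided two-sample t test, unequal variances by default (set
#' `var_equal = TRUE` for the Student variant).  Returns `NA` when either
#' side has fewer than two values; when both sides are constant with equal
#' means the p-value is 1 by convention (with a warning).
#'
#' @param x,y numeric vectors (per-gene or per-transcript values for the
#'   two species; `NA`s dropped).
#' @param var_equal assume equal variances (default `FALSE`, Welch).
#' @return p-value, or `NA_real_`.
#' @export
pairwise_ttest <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
           error = function(e) {
             if (isTRUE(all.equal(mean(x), mean(y)))) {
               warning("both sides constant with equal means; p = 1")
               1
             } else {
               warning("t test failed: ", conditionMessage(e))
               NA_real_
             }
           })
}

#' Two-sided exact binomial (sign) test
#'
#' Probability under p = 0.5 of a direction split at least as extreme as
#' observed: p = min(1, 2 * tail), where the tail is the upper tail of
#' Binomial(n, 1/2) at `k` when `k >= n/2` and the lower tail otherwise.
#'
#' @param k number of concordant comparisons.
#' @param n total number of comparisons.
#' @return p-value.
#' @export
#' @examples
#' exact_binomial(10, 10)  # 2 / 1024 = 0.00195...
#' exact_binomial(9, 10)   # 22 / 1024 = 0.0215...
exact_binomial <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, k <= n, n >= 1)
  tail <- if (k >= n / 2) {
    stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  } else {
    stats::pbinom(k, n, 0.5)
  }
  min(1, 2 * tail)
}

#' Build all congeneric EIE-vs-NE comparisons
#'
#' Forms the full bipartite product of EIE and NE species within each
#' genus and records, for every index, which side has the higher species
#' value.
#'
#' @param species_table data.frame with columns `species`, `genus`,
#'   `category` (`"EIE"` / `"NE"`) and the index columns (any subset of
#'   `pd`, `syn_per_kb`, `nonsyn_fraction`, `nonsense_fraction`,
#'   `provean_fraction`, `sift_fraction`).
#' @param indices which index columns to compare; defaults to those
#'   present.
#' @return data.frame with one row per (pair, index): `genus`,
#'   `eie_species`, `ne_species`, `index`, `eie_value`, `ne_value`,
#'   `direction` (`eie_lower` / `eie_higher` / `tie`).
#' @export
build_comparisons <- function(species_table,
                              indices = intersect(.INDEX_COLS,
                                                  names(species_table))) {
  stopifnot(all(c("species", "genus", "category") %in% names(species_table)),
            all(species_table$category %in% c("EIE", "NE")),
            length(indices) > 0L)
  rows <- list()
  for (g in unique(species_table$genus)) {
    sub <- species_table[species_table$genus == g, , drop = FALSE]
    eie <- sub[sub$category == "EIE", , drop = FALSE]
    ne <- sub[sub$category == "NE", , drop = FALSE]
    for (i in seq_len(nrow(eie))) for (j in seq_len(nrow(ne))) {
      for (idx in indices) {
        ev <- eie[[idx]][i]
        nv <- ne[[idx]][j]
        rows[[length(rows) + 1L]] <- data.frame(
          genus = g, eie_species = eie$species[i], ne_species = ne$species[j],
          index = idx, eie_value = ev, ne_value = nv,
          direction = if (is.na(ev) || is.na(nv)) NA_character_
                      else if (ev < nv) "eie_lower"
                      else if (ev > nv) "eie_higher" else "tie",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-genus concordance summary per index
#'
#' Counts, for each index, how many congeneric pairs go in the
#' theoretically expected direction and computes the two-sided exact
#' binomial p-value.  Ties abort with an error (none occur in the study
#' data).
#'
#' @param comparisons data.frame from [build_comparisons()].
#' @param expected named character vector of expected directions; defaults
#'   to [index_directions()].
#' @return data.frame with one row per index: `index`,
#'   `expected_direction`, `n_pairs`, `n_concordant`, `p_two_sided`.
#' @export
binomial_summary <- function(comparisons, expected = index_directions()) {
  out <- lapply(unique(comparisons$index), function(idx) {
    sub <- comparisons[comparisons$index == idx & !is.na(comparisons$direction),
                       , drop = FALSE]
    if (any(sub$direction == "tie")) {
      stop("tied species values for index ", idx,
           "; the sign test is undefined on ties")
    }
    exp_dir <- expected[[idx]]
    if (is.null(exp_dir)) stop("no expected direction for index ", idx)
    k <- sum(sub$direction == exp_dir)
    n <- nrow(sub)
    data.frame(index = idx, expected_direction = exp_dir, n_pairs = n,
               n_concordant = k,
               p_two_sided = if (n > 0) exact_binomial(k, n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate a specimen index table to species values
#'
#' @param specimen_table data.frame with `species`, `genus`, `category`,
#'   `specimen` and index columns.
#' @return data.frame with one row per species (specimen means per index).
#' @export
species_index_table <- function(specimen_table) {
  idx <- intersect(.INDEX_COLS, names(specimen_table))
  sp <- unique(specimen_table[, c("species", "genus", "category")])
  if (anyDuplicated(sp$species)) {
    stop("species assigned to more than one genus/category")
  }
  for (col in idx) {
    agg <- tapply(specimen_table[[col]], specimen_table$species, species_value)
    sp[[col]] <- as.numeric(agg[sp$species])
  }
  rownames(sp) <- NULL
  sp
}

#' Published per-specimen vulnerability indices for the Ogasawara study
#' system
#'
#' The six indices for 35 RNA-seq specimens of 12 plant species (six
#' endangered Ogasawara endemics and six widespread congeners in the
#' genera *Ajuga*, *Crepidiastrum*, *Calanthe* and *Melastoma*), as
#' published, at 3-decimal precision.  With `level = "species"` the
#' published species-average rows are returned instead (also 3 d.p.;
#' computed by the original authors from unrounded specimen values, so a
#' recomputed mean of the printed specimen rows can differ by one unit in
#' the last digit).
#'
#' @param level `"specimen"` (default) or `"species"`.
#' @return data.frame with `genus`, `species`, `category` (+ `specimen`
#'   at specimen level) and the six index columns.
#' @export
ogasawara_indices <- function(level = c("specimen", "species")) {
  level <- match.arg(level)
  f <- system.file("extdata",
                   if (level == "specimen") "ogasawara_specimen_indices.tsv"
                   else "ogasawara_species_averages.tsv",
                   package = "genomevuln", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}
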