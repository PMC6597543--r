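# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths.

# genetic code straight from Biostrings, N-containing codons -> "X"
oracle_translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) "X" else aa
}

# exhaustive enumeration of all 576 single-base codon changes with an
# independently written classification rule
oracle_codon_changes <- function() {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (c1 in bases) for (c2 in bases) for (c3 in bases) {
    codon <- paste0(c1, c2, c3)
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(codon, pos, pos))) {
        alt_codon <- codon
        substr(alt_codon, pos, pos) <- alt
        a1 <- oracle_translate_codon(codon)
        a2 <- oracle_translate_codon(alt_codon)
        eff <- if (a1 == "*") "unassessable"
        else if (a2 == "*") "nonsense"
        else if (a1 == a2) "synonymous"
        else "missense"
        out[[length(out) + 1L]] <- data.frame(
          codon = codon, codon_pos = pos - 1L, alt = alt,
          ref_aa = a1, alt_aa = a2, effect = eff, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# brute-force six-frame scan for the longest stop-free codon stretch;
# returns the best protein length and (one of) the best proteins
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  best_len <- 0L
  best_prot <- character(0)
  for (ss in c(s, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))) {
    n <- nchar(ss)
    for (off in 0:2) {
      i <- off + 1L
      run <- character(0)
      while (i + 2L <= n) {
        aa <- oracle_translate_codon(substr(ss, i, i + 2L))
        if (aa == "*") {
          if (length(run) > best_len) {
            best_len <- length(run)
            best_prot <- paste(run, collapse = "")
          } else if (length(run) == best_len && best_len > 0L) {
            best_prot <- c(best_prot, paste(run, collapse = ""))
          }
          run <- character(0)
        } else {
          run <- c(run, aa)
        }
        i <- i + 3L
      }
      if (length(run) > best_len) {
        best_len <- length(run)
        best_prot <- paste(run, collapse = "")
      } else if (length(run) == best_len && best_len > 0L) {
        best_prot <- c(best_prot, paste(run, collapse = ""))
      }
    }
  }
  list(len = best_len, proteins = unique(best_prot))
}

# Welch two-sample t test from the textbook formulas
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# two-sided sign-test p by explicit enumeration of all 2^n outcome vectors
oracle_binom_p <- function(k, n) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  s <- rowSums(grid)
  tail <- if (k >= n / 2) mean(s >= k) else mean(s <= k)
  min(1, 2 * tail)
}

# deterministic random DNA for property tests
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
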