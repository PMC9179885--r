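# Fixtures and independent oracles used across the test files.

make_snps <- function(ids, counted = "A", other = "G") {
  n <- length(ids)
  data.frame(snp_id = ids, rs_id = rep(NA_character_, n),
             chromosome = as.character(rep_len(1:18, n)),
             position = seq_len(n) * 100L,
             counted_allele = rep_len(counted, n),
             other_allele = rep_len(other, n),
             stringsAsFactors = FALSE)
}

make_dataset <- function(dosage, populations, snp_ids = NULL,
                         sample_ids = NULL, counted = "A", other = "G") {
  dosage <- as.matrix(dosage)
  snp_ids <- snp_ids %||% sprintf("s%d", seq_len(ncol(dosage)))
  sample_ids <- sample_ids %||% sprintf("ind%d", seq_len(nrow(dosage)))
  genotype_dataset(dosage, make_snps(snp_ids, counted, other),
                   data.frame(sample_id = sample_ids,
                              population = populations,
                              stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_aft <- function(freq, pops = NULL, snp_ids = NULL) {
  freq <- as.matrix(freq)
  rownames(freq) <- pops %||% rownames(freq) %||%
    sprintf("P%d", seq_len(nrow(freq)))
  colnames(freq) <- snp_ids %||% colnames(freq) %||%
    sprintf("s%d", seq_len(ncol(freq)))
  allele_freq_table(freq)
}

# --- Oracle: Hardy-Weinberg exact p-value by direct enumeration.
# Probability of each heterozygote count from the log-factorial closed form
# P(het | n, rare) = n! / (hom_r! het! hom_c!) * 2^het * rare! (2n-rare)! / (2n)!
# summed over configurations no more probable than the observed one.
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# --- Oracle: shared-covariance Gaussian posteriors by direct dense algebra.
bayes_posterior_oracle <- function(X, means, W, priors) {
  Wi <- solve(W)
  n <- nrow(X)
  cls <- rownames(means)
  dens <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  for (k in seq_along(cls)) {
    for (i in seq_len(n)) {
      d <- X[i, ] - means[k, ]
      dens[i, k] <- priors[k] * exp(-0.5 * drop(t(d) %*% Wi %*% d))
    }
  }
  dens / rowSums(dens)
}

# --- Oracle: exhaustive sort-and-pick panel selection with dedup.
selection_oracle <- function(freq, scheme_df) {
  chosen <- character(0)
  for (r in seq_len(nrow(scheme_df))) {
    d <- abs(freq[scheme_df$pop_i[r], ] - freq[scheme_df$pop_j[r], ])
    ord <- order(-d, colnames(freq))
    ids <- colnames(freq)[ord]
    ids <- ids[!ids %in% chosen]
    chosen <- c(chosen, ids[seq_len(scheme_df$count[r])])
  }
  chosen
}

expect_dosage_equal <- function(a, b) {
  expect_equal(unname(a$dosage), unname(b$dosage))
}
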