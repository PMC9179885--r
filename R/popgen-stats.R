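# Population-genetic summaries: per-population allele frequencies, the
# delta marker-informativeness statistic, mean identity-by-state, and
# classical multidimensional scaling of the IBS distance.

#' Allele frequency table
#'
#' Construct a per-population, per-SNP table of counted-allele frequencies.
#' Usually built from data via [allele_frequencies()]; the constructor is
#' exported so that frequency tables can also be specified directly (e.g.
#' for panel design on published frequencies, or for simulation).
#'
#' @param freq numeric matrix, populations in rows (rownames = labels) and
#'   SNPs in columns (colnames = snp_ids), entries in `[0, 1]` (`NaN` where
#'   undefined).
#' @param n_obs integer matrix of the same shape: number of non-missing
#'   genotypes behind each frequency. Defaults to 1 everywhere.
#' @param snps optional SNP metadata data.frame (as in [genotype_dataset()]),
#'   carried along so simulated cohorts keep marker annotation.
#' @return An object of class `allele_freq_table`.
#' @export
allele_freq_table <- function(freq, n_obs = NULL, snps = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq)) || is.null(colnames(freq))) {
    stop_("freq must have population rownames and snp_id colnames")
  }
  if (is.null(n_obs)) {
    n_obs <- matrix(1L, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  }
  n_obs <- as.matrix(n_obs)
  ok <- is.nan(freq) | (freq >= 0 & freq <= 1)
  if (!all(ok, na.rm = TRUE)) stop_("frequencies must lie in [0, 1]")
  if (is.null(snps)) {
    snps <- data.frame(snp_id = colnames(freq), rs_id = NA_character_,
                       chromosome = NA_character_, position = NA_integer_,
                       counted_allele = "A", other_allele = "G",
                       stringsAsFactors = FALSE)
  }
  structure(list(freq = freq, n_obs = n_obs,
                 populations = rownames(freq), snps = snps),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("<allele_freq_table> ", length(x$populations), " populations x ",
      ncol(x$freq), " SNPs\n", sep = "")
  invisible(x)
}

#' Per-population allele frequencies
#'
#' For each population and SNP, the frequency of the counted allele is the
#' dosage sum over non-missing samples divided by twice the number of
#' non-missing samples. Missing calls are excluded from both numerator and
#' denominator; a (population, SNP) cell with no observations is flagged as
#' `NaN` rather than silently set to 0.
#'
#' @param ds a [genotype_dataset()].
#' @param by optional vector of population labels, one per sample; defaults
#'   to the dataset's `population` column. No label may be missing.
#' @return An [allele_freq_table()].
#' @export
allele_frequencies <- function(ds, by = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  by <- by %||% ds$samples$population
  if (length(by) != nrow(ds$samples) || anyNA(by) || any(!nzchar(by))) {
    stop_("every sample needs a non-missing population label")
  }
  pops <- sort(unique(by))
  m <- nrow(ds$snps)
  freq <- matrix(NaN, length(pops), m, dimnames = list(pops, ds$snps$snp_id))
  nobs <- matrix(0L, length(pops), m, dimnames = list(pops, ds$snps$snp_id))
  for (k in seq_along(pops)) {
    g <- ds$dosage[by == pops[k], , drop = FALSE]
    n <- colSums(!is.na(g))
    s <- colSums(g, na.rm = TRUE)
    nobs[k, ] <- n
    freq[k, ] <- ifelse(n > 0, s / (2 * n), NaN)
  }
  allele_freq_table(freq, nobs, snps = ds$snps)
}

#' Delta statistic table for a pair of populations
#'
#' The delta statistic of a SNP for populations i and j is the absolute
#' difference of the counted allele's frequencies, `|p_i - p_j|`. It is
#' invariant to which allele is counted and ranges from 0 (uninformative) to
#' 1 (a fixed difference). SNPs with an undefined frequency in either
#' population are excluded.
#'
#' @param aft an [allele_freq_table()].
#' @param pop_i,pop_j distinct population labels present in `aft`.
#' @return A data.frame of class `delta_table` with columns `snp_id`,
#'   `delta`, `freq_i`, `freq_j`, sorted by `delta` descending with ties
#'   broken by `snp_id` ascending; attribute `pair` records the two labels.
#' @export
delta_table <- function(aft, pop_i, pop_j) {
  stopifnot(inherits(aft, "allele_freq_table"))
  if (identical(pop_i, pop_j)) stop_("pop_i and pop_j must differ")
  for (p in c(pop_i, pop_j)) {
    if (!p %in% aft$populations) stop_("unknown population: ", p)
  }
  fi <- aft$freq[pop_i, ]
  fj <- aft$freq[pop_j, ]
  ok <- !is.nan(fi) & !is.nan(fj)
  d <- abs(fi[ok] - fj[ok])
  ids <- colnames(aft$freq)[ok]
  ord <- order(-d, ids)
  out <- data.frame(snp_id = ids[ord], delta = unname(d[ord]),
                    freq_i = unname(fi[ok][ord]), freq_j = unname(fj[ok][ord]),
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- c(pop_i, pop_j)
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Mean identity-by-state matrix
#'
#' For each pair of samples, over the SNPs where both are genotyped, the
#' mean of `(2 - |g_a - g_b|) / 2`: 1 for identical genotypes, 0.5 when the
#' genotypes differ by one allele, 0 for opposite homozygotes. Pairs sharing
#' no genotyped SNP are `NaN`.
#'
#' @param ds a [genotype_dataset()] with at least two samples.
#' @return A list of class `ibs_matrix`: `ibs` (n x n symmetric similarity
#'   matrix with unit diagonal for fully genotyped samples) and `n_shared`
#'   (SNPs compared per pair).
#' @export
ibs_matrix <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$samples)
  if (n < 2L) stop_("IBS needs at least two samples")
  G <- ds$dosage
  A <- lapply(0:2, function(v) {
    m <- (G == v); m[is.na(m)] <- FALSE; m * 1
  })
  M <- (!is.na(G)) * 1
  shared <- M %*% t(M)
  # sum over shared SNPs of |g_a - g_b|
  d1 <- A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[1]]) +
        A[[2]] %*% t(A[[3]]) + A[[3]] %*% t(A[[2]])
  d2 <- A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]])
  dsum <- d1 + 2 * d2
  ibs <- ifelse(shared > 0, 1 - dsum / (2 * shared), NaN)
  dimnames(ibs) <- list(ds$samples$sample_id, ds$samples$sample_id)
  structure(list(ibs = ibs, n_shared = shared,
                 populations = ds$samples$population),
            class = "ibs_matrix")
}

#' Classical multidimensional scaling of an IBS matrix
#'
#' Embeds samples in k dimensions from the distance `D = 1 - IBS` by
#' classical (Torgerson) scaling: double-centering of squared distances and
#' eigendecomposition, with coordinates scaled by the square roots of the
#' eigenvalues. Negative eigenvalues contribute nothing; if fewer than `k`
#' positive eigenvalues exist, fewer columns are returned with a warning.
#'
#' @param ibs an [ibs_matrix()] defined for all pairs.
#' @param k number of dimensions, `1 <= k <= n - 1`.
#' @return A list of class `mds_result`: `coordinates` (n x k', row names =
#'   sample ids), `eigenvalues` (first k, non-increasing), and the sample
#'   `populations`.
#' @export
classical_mds <- function(ibs, k = 2) {
  stopifnot(inherits(ibs, "ibs_matrix"))
  n <- nrow(ibs$ibs)
  if (anyNA(ibs$ibs) || any(is.nan(ibs$ibs))) {
    stop_("IBS must be defined for every pair before scaling")
  }
  if (k < 1 || k > n - 1) stop_("k must be between 1 and n - 1")
  D <- 1 - ibs$ibs
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  coords <- as.matrix(fit$points)
  if (ncol(coords) < k) {
    warning("only ", ncol(coords), " positive eigenvalue(s); returning ",
            ncol(coords), " dimension(s)")
  }
  rownames(coords) <- rownames(ibs$ibs)
  structure(list(coordinates = coords,
                 eigenvalues = fit$eig[seq_len(min(k, length(fit$eig)))],
                 populations = ibs$populations),
            class = "mds_result")
}

#' Write MDS coordinates as TSV
#'
#' @param mds an [classical_mds()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mds_coordinates <- function(mds, path) {
  stopifnot(inherits(mds, "mds_result"))
  co <- mds$coordinates
  out <- data.frame(sample_id = rownames(co),
                    population = mds$populations %||% NA_character_,
                    co, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("dim", seq_len(ncol(co)))
  write_tsv(out, path)
}

#' Write an allele-frequency table as TSV
#'
#' Long format: population, snp_id, freq, n_obs.
#'
#' @param aft an [allele_freq_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(aft, path) {
  stopifnot(inherits(aft, "allele_freq_table"))
  out <- data.frame(
    population = rep(rownames(aft$freq), times = ncol(aft$freq)),
    snp_id = rep(colnames(aft$freq), each = nrow(aft$freq)),
    freq = as.vector(aft$freq),
    n_obs = as.vector(aft$n_obs), stringsAsFactors = FALSE)
  write_tsv(out, path)
}
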