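# Genotype quality control: call-rate filters and the Hardy-Weinberg
# exact test with Bonferroni correction.

#' QC thresholds
#'
#' @param min_sample_call_rate minimum fraction of non-missing genotypes a
#'   sample must have to be retained (default 0.95).
#' @param min_snp_call_rate minimum fraction of non-missing genotypes a SNP
#'   must have to be retained (default 0.95).
#' @param hwe_alpha significance level for the Hardy-Weinberg exact test,
#'   Bonferroni-corrected across the SNPs actually tested (default 0.01).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.95,
                          min_snp_call_rate = 0.95,
                          hwe_alpha = 0.01) {
  for (v in c(min_sample_call_rate, min_snp_call_rate, hwe_alpha)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop_("qc thresholds must be single fractions in [0, 1]")
    }
  }
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 hwe_alpha = hwe_alpha),
            class = "qc_thresholds")
}

#' Call rates per sample or per SNP
#'
#' @param ds a [genotype_dataset()].
#' @param axis `"samples"` for per-sample rates (fraction of SNPs called) or
#'   `"snps"` for per-SNP rates (fraction of samples called).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
call_rates <- function(ds, axis = c("samples", "snps")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  axis <- match.arg(axis)
  if (nrow(ds$samples) == 0L || nrow(ds$snps) == 0L) {
    stop_("cannot compute call rates on an empty dataset")
  }
  obs <- !is.na(ds$dosage)
  if (axis == "samples") rowMeans(obs) else colMeans(obs)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on the heterozygote count conditional on the allele
#' counts: the p-value is the sum of the probabilities of all heterozygote
#' configurations whose conditional probability does not exceed that of the
#' observed configuration. Probabilities are accumulated by the standard
#' outward recurrence from the modal heterozygote count; no mid-p adjustment
#' is applied. Monomorphic samples return `p = 1`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in `[0, 1]`. The result is invariant to swapping the two
#'   homozygote classes.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_("at least one genotype is required")
  rare <- 2L * min(n_AA, n_aa) + n_Aa        # copies of the rarer allele
  if (rare == 0L) return(1)

  probs <- numeric(rare + 1L)                # index k+1 = P(het = k)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  probs[mid + 1L] <- 1
  het <- mid
  hom_r <- (rare - mid) / 2                  # rare-allele homozygotes
  hom_c <- n - het - hom_r                   # common-allele homozygotes
  while (het >= 2L) {
    probs[het - 1L] <- probs[het + 1L] * het * (het - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    het <- het - 2L; hom_r <- hom_r + 1; hom_c <- hom_c + 1
  }
  het <- mid
  hom_r <- (rare - mid) / 2
  hom_c <- n - het - hom_r
  while (het <= rare - 2L) {
    probs[het + 3L] <- probs[het + 1L] * 4 * hom_r * hom_c /
      ((het + 2) * (het + 1))
    het <- het + 2L; hom_r <- hom_r - 1; hom_c <- hom_c - 1
  }
  probs <- probs / sum(probs)
  p_obs <- probs[n_Aa + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test against expected proportions
#' `p^2 : 2pq : q^2`; offered as a large-sample alternative to
#' [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return p-value in `[0, 1]`.
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_("at least one genotype is required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

hwe_counts <- function(dosage_col) {
  c(n_AA = sum(dosage_col == 2, na.rm = TRUE),
    n_Aa = sum(dosage_col == 1, na.rm = TRUE),
    n_aa = sum(dosage_col == 0, na.rm = TRUE))
}

#' Apply call-rate and Hardy-Weinberg quality control
#'
#' Filters are applied in a fixed order: (1) samples below the sample
#' call-rate threshold are dropped; (2) SNP call rates are recomputed on the
#' retained samples and failing SNPs dropped; (3) the surviving SNPs are
#' tested for Hardy-Weinberg equilibrium (within `hwe_population`'s samples
#' if given, otherwise across all samples) and SNPs with
#' `p < hwe_alpha / n_tested` (Bonferroni) are dropped. No minor-allele
#' frequency filter is applied: rare alleles can be breed-diagnostic and are
#' deliberately retained.
#'
#' @param ds a [genotype_dataset()].
#' @param thr a [qc_thresholds()] object.
#' @param hwe_population optional population label restricting the samples
#'   used for the HWE test (e.g. the focal breed).
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return A list with elements `dataset` (the filtered
#'   [genotype_dataset()]) and `report` (class `qc_report`: removed samples
#'   and SNPs with the statistic that removed them, the number of HWE tests,
#'   and the effective Bonferroni threshold).
#' @export
apply_qc <- function(ds, thr = qc_thresholds(), hwe_population = NULL,
                     hwe_test = c("exact", "chisq")) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(thr, "qc_thresholds"))
  hwe_test <- match.arg(hwe_test)
  if (nrow(ds$samples) == 0L || nrow(ds$snps) == 0L) {
    stop_("cannot run QC on an empty dataset")
  }

  cr_s <- call_rates(ds, "samples")
  drop_s <- cr_s < thr$min_sample_call_rate
  removed_samples <- data.frame(sample_id = ds$samples$sample_id[drop_s],
                                call_rate = unname(cr_s[drop_s]),
                                stringsAsFactors = FALSE)
  if (all(drop_s)) stop_("all samples removed by the sample call-rate filter")
  ds <- subset_genotypes(ds, sample_ids = ds$samples$sample_id[!drop_s])

  cr_m <- call_rates(ds, "snps")
  drop_m <- cr_m < thr$min_snp_call_rate
  removed_snps <- data.frame(snp_id = ds$snps$snp_id[drop_m],
                             reason = rep("call_rate", sum(drop_m)),
                             value = unname(cr_m[drop_m]),
                             stringsAsFactors = FALSE)
  ds <- subset_genotypes(ds, snp_ids = ds$snps$snp_id[!drop_m])

  if (is.null(hwe_population)) {
    hw <- ds$dosage
  } else {
    in_pop <- ds$samples$population == hwe_population
    if (!any(in_pop)) stop_("unknown hwe_population: ", hwe_population)
    hw <- ds$dosage[in_pop, , drop = FALSE]
  }
  n_tests <- ncol(hw)
  test_fun <- if (hwe_test == "exact") hwe_exact_test else hwe_chisq_test
  pvals <- apply(hw, 2, function(col) {
    cnt <- hwe_counts(col)
    if (sum(cnt) == 0) return(1)
    test_fun(cnt[1], cnt[2], cnt[3])
  })
  threshold <- thr$hwe_alpha / max(n_tests, 1L)
  drop_h <- pvals < threshold
  removed_snps <- rbind(removed_snps,
                        data.frame(snp_id = ds$snps$snp_id[drop_h],
                                   reason = rep("hwe", sum(drop_h)),
                                   value = unname(pvals[drop_h]),
                                   stringsAsFactors = FALSE))
  ds <- subset_genotypes(ds, snp_ids = ds$snps$snp_id[!drop_h])

  report <- structure(list(removed_samples = removed_samples,
                           removed_snps = removed_snps,
                           n_tests_hwe = n_tests,
                           hwe_threshold_effective = threshold,
                           filter_order = c("sample_call_rate",
                                            "snp_call_rate", "hwe")),
                      class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  samples removed (call rate):", nrow(x$removed_samples), "\n")
  cat("  SNPs removed (call rate):   ",
      sum(x$removed_snps$reason == "call_rate"), "\n")
  cat("  SNPs removed (HWE):         ",
      sum(x$removed_snps$reason == "hwe"),
      sprintf(" [%d tests, threshold %.3g]\n", x$n_tests_hwe,
              x$hwe_threshold_effective))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  rs <- report$removed_samples
  rm_ <- report$removed_snps
  out <- rbind(
    if (nrow(rs)) data.frame(id = rs$sample_id, kind = "sample",
                             reason = "call_rate", value = rs$call_rate),
    if (nrow(rm_)) data.frame(id = rm_$snp_id, kind = "snp",
                              reason = rm_$reason, value = rm_$value))
  if (is.null(out)) out <- data.frame(id = character(0), kind = character(0),
                                      reason = character(0), value = numeric(0))
  write_tsv(out, path)
}

#' Drop samples with missing panel genotypes
#'
#' Retains exactly the samples with zero missing calls across the panel's
#' SNPs, as done before fitting the discriminant model.
#'
#' @param ds a [genotype_dataset()] containing all panel SNPs.
#' @param panel a [select_panel()] result or a character vector of SNP ids.
#' @return A `genotype_dataset` restricted to the panel SNPs and to the
#'   fully genotyped samples.
#' @export
drop_incomplete_samples <- function(ds, panel) {
  ids <- if (inherits(panel, "snp_panel")) panel$snp_id else as.character(panel)
  ds <- subset_genotypes(ds, snp_ids = ids)
  keep <- rowSums(is.na(ds$dosage)) == 0L
  subset_genotypes(ds, sample_ids = ds$samples$sample_id[keep])
}
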