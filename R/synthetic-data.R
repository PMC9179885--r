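# Synthetic multi-population SNP studies under the Balding-Nichols model:
# population allele frequencies are Beta-distributed around an ancestral
# frequency with variance F * p * (1 - p), genotypes follow Hardy-Weinberg
# and linkage equilibrium within populations, and missing calls are
# injected completely at random.

#' Configuration of a synthetic SNP study
#'
#' Defaults emulate a five-population pig design: cohort sizes
#' NS 93, LW 44, LR 37, DU 44, WB 88; 5,000 biallelic SNPs; differentiation
#' F = 0.2 for every population; ancestral frequencies uniform on
#' `[0.05, 0.95]`; 1.5% missing calls (a 98.5% mean call rate).
#'
#' @param population_sizes named integer vector (label -> cohort size,
#'   each >= 2).
#' @param n_snps number of biallelic SNPs.
#' @param fst differentiation parameter in `[0, 1)`: a single value or a
#'   named per-population vector (0 = no divergence from the ancestral
#'   frequency).
#' @param ancestral_freq_range interval within `(0, 1)` for the uniform
#'   ancestral frequency draw.
#' @param missing_rate fraction of genotype calls set missing, completely
#'   at random.
#' @param seed master seed; all draws derive from it.
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(population_sizes = c(NS = 93L, LW = 44L,
                                                        LR = 37L, DU = 44L,
                                                        WB = 88L),
                                   n_snps = 5000L,
                                   fst = 0.2,
                                   ancestral_freq_range = c(0.05, 0.95),
                                   missing_rate = 0.015,
                                   seed = 1L) {
  if (is.null(names(population_sizes)) || any(!nzchar(names(population_sizes)))) {
    stop_("population_sizes must be a named vector")
  }
  if (any(population_sizes < 2)) stop_("each population needs >= 2 individuals")
  if (n_snps < 1) stop_("n_snps must be >= 1")
  pops <- names(population_sizes)
  if (length(fst) == 1L && is.null(names(fst))) {
    fst <- stats::setNames(rep(fst, length(pops)), pops)
  }
  if (!all(pops %in% names(fst))) stop_("fst must cover every population")
  fst <- fst[pops]
  if (any(fst < 0 | fst >= 1)) stop_("fst values must lie in [0, 1)")
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      diff(ancestral_freq_range) < 0) {
    stop_("ancestral_freq_range must be an interval within (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_("missing_rate must lie in [0, 1)")
  }
  structure(list(population_sizes = population_sizes, n_snps = as.integer(n_snps),
                 fst = fst, ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Draw true population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequency `p ~ Uniform(range)` per SNP; each population's
#' frequency is Beta-distributed with shape `p(1-F)/F, (1-p)(1-F)/F`, giving
#' mean `p` and variance `F p (1-p)`. `F = 0` is handled as the degenerate
#' limit (the population frequency equals the ancestral one exactly).
#'
#' @param config a [synthetic_study_config()].
#' @return An object of class `truth_record`: `ancestral` (per-SNP vector),
#'   `pop_freq` (populations x SNPs matrix), `snp_ids`.
#' @export
draw_population_frequencies <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  m <- config$n_snps
  pops <- names(config$population_sizes)
  snp_ids <- sprintf("SNP%06d", seq_len(m))
  with_seed(derive_seed(config$seed, 1L), {
    p <- stats::runif(m, config$ancestral_freq_range[1],
                      config$ancestral_freq_range[2])
    pf <- matrix(NA_real_, length(pops), m, dimnames = list(pops, snp_ids))
    for (k in seq_along(pops)) {
      f <- config$fst[[k]]
      pf[k, ] <- if (f == 0) p else {
        stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      }
    }
    structure(list(ancestral = stats::setNames(p, snp_ids), pop_freq = pf,
                   snp_ids = snp_ids),
              class = "truth_record")
  })
}

#' Generate a synthetic multi-population genotype study
#'
#' Draws true frequencies via [draw_population_frequencies()], then
#' genotypes as Binomial(2, p_pop) independently per locus (Hardy-Weinberg
#' and linkage equilibrium within populations), and finally sets calls
#' missing completely at random at `missing_rate`. Identifiers, chromosome
#' assignments and allele labels are synthesized deterministically; the
#' whole study is a pure function of the config (fixed seed = identical
#' output, byte for byte, when exported).
#'
#' @param config a [synthetic_study_config()].
#' @return A list: `dataset` (a [genotype_dataset()]) and `truth` (the
#'   `truth_record` of generating frequencies).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  truth <- draw_population_frequencies(config)
  m <- config$n_snps
  pops <- names(config$population_sizes)
  n <- sum(config$population_sizes)

  allele_pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                           "C", "A", "G", "A", "C", "T", "G", "T"),
                         ncol = 2, byrow = TRUE)
  with_seed(derive_seed(config$seed, 2L), {
    pair_idx <- sample.int(nrow(allele_pairs), m, replace = TRUE)
    snps <- data.frame(
      snp_id = truth$snp_ids, rs_id = NA_character_,
      chromosome = as.character(rep_len(1:18, m)),
      position = as.integer(seq_len(m)) * 1000L,
      counted_allele = allele_pairs[pair_idx, 1],
      other_allele = allele_pairs[pair_idx, 2],
      stringsAsFactors = FALSE)

    dosage <- matrix(NA_real_, n, m)
    row0 <- 0L
    sample_id <- character(n); population <- character(n)
    for (k in seq_along(pops)) {
      nk <- config$population_sizes[[k]]
      idx <- row0 + seq_len(nk)
      dosage[idx, ] <- matrix(
        stats::rbinom(nk * m, 2L, rep(truth$pop_freq[k, ], each = nk)),
        nrow = nk)
      sample_id[idx] <- sprintf("%s_%03d", pops[k], seq_len(nk))
      population[idx] <- pops[k]
      row0 <- row0 + nk
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(n * m) < config$missing_rate
      dosage[drop] <- NA_real_
    }
    samples <- data.frame(sample_id = sample_id, population = population,
                          stringsAsFactors = FALSE)
    list(dataset = genotype_dataset(dosage, snps, samples), truth = truth)
  })
}

#' Write the generating truth of a synthetic study as TSV
#'
#' Columns: snp_id, ancestral_freq, then one true-frequency column per
#' population.
#'
#' @param truth a `truth_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  out <- data.frame(snp_id = truth$snp_ids,
                    ancestral_freq = unname(truth$ancestral),
                    t(truth$pop_freq), stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("freq_", rownames(truth$pop_freq))
  write_tsv(out, path)
}
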