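# Simulation of purebred and first-generation hybrid genotypes from
# population allele frequencies, and assembly of the four training /
# validation cohorts used to benchmark panel performance.

#' Crossing plan for training/validation cohorts
#'
#' Describes which F1 crossings to simulate and how many individuals each
#' cohort receives. Defaults reproduce the standard five-breed design: 10
#' crossings with 20 F1 individuals each for the hybrid training cohort and
#' 10 each for the hybrid validation cohort, plus 40 simulated purebreds per
#' breed for the purebred validation cohort.
#'
#' @param crossings list of 2-element character vectors (parental
#'   populations; the two must differ).
#' @param n_per_cross_training F1 individuals per crossing in the hybrid
#'   training cohort (default 20).
#' @param n_per_cross_validation F1 individuals per crossing in the hybrid
#'   validation cohort (default 10).
#' @param purebred_pops breeds to simulate purebreds for (default the union
#'   of the crossing parents).
#' @param n_per_purebred simulated purebreds per breed in the validation
#'   cohort (default 40).
#' @param seed master seed for all simulation randomness.
#' @return An object of class `crossing_plan`.
#' @export
crossing_plan <- function(crossings = default_crossings(),
                          n_per_cross_training = 20L,
                          n_per_cross_validation = 10L,
                          purebred_pops = NULL,
                          n_per_purebred = 40L,
                          seed = 1L) {
  crossings <- lapply(crossings, as.character)
  if (any(vapply(crossings, function(x) length(x) != 2L || x[1] == x[2],
                 logical(1)))) {
    stop_("each crossing must name two distinct populations")
  }
  if (n_per_cross_training < 0 || n_per_cross_validation < 0 ||
      n_per_purebred < 0) {
    stop_("cohort counts must be >= 0")
  }
  purebred_pops <- purebred_pops %||% sort(unique(unlist(crossings)))
  structure(list(crossings = crossings,
                 n_per_cross_training = as.integer(n_per_cross_training),
                 n_per_cross_validation = as.integer(n_per_cross_validation),
                 purebred_pops = purebred_pops,
                 n_per_purebred = as.integer(n_per_purebred),
                 seed = as.integer(seed)),
            class = "crossing_plan")
}

#' Default crossing set for the five-breed design
#'
#' @param focal focal breed (default NS).
#' @param wild wild population (default WB).
#' @param cosmopolitan cosmopolitan breeds (default DU, LR, LW).
#' @return List of 2-element character vectors: focal x each other breed,
#'   wild x each cosmopolitan, and all cosmopolitan pairs (10 crossings).
#' @export
default_crossings <- function(focal = "NS", wild = "WB",
                              cosmopolitan = c("DU", "LR", "LW")) {
  c(lapply(c(cosmopolitan, wild), function(b) c(focal, b)),
    lapply(cosmopolitan, function(b) c(wild, b)),
    list(c(cosmopolitan[1], cosmopolitan[2]),
         c(cosmopolitan[1], cosmopolitan[3]),
         c(cosmopolitan[2], cosmopolitan[3])))
}

sim_snp_subset <- function(aft, snp_ids) {
  if (is.null(snp_ids)) return(aft)
  j <- match(snp_ids, colnames(aft$freq))
  if (anyNA(j)) {
    stop_("frequency table lacks SNPs: ",
          paste(snp_ids[is.na(j)], collapse = ", "))
  }
  allele_freq_table(aft$freq[, j, drop = FALSE],
                    aft$n_obs[, j, drop = FALSE],
                    snps = aft$snps[match(snp_ids, aft$snps$snp_id), , drop = FALSE])
}

check_defined <- function(p, pop, ids) {
  bad <- is.nan(p) | is.na(p)
  if (any(bad)) {
    stop_("undefined allele frequency for population ", pop, " at SNP(s): ",
          paste(utils::head(ids[bad], 5), collapse = ", "))
  }
}

#' Simulate purebred genotypes from population frequencies
#'
#' Each individual's dosage at each SNP is drawn as Binomial(2, p), i.e.
#' Hardy-Weinberg proportions within the population and linkage equilibrium
#' across loci. Simulated data contain no missing calls.
#'
#' @param aft an [allele_freq_table()].
#' @param pop population label to simulate from.
#' @param n number of individuals.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param snp_ids optional SNP subset (default: all SNPs in `aft`).
#' @param id_prefix prefix for generated sample ids.
#' @return A [genotype_dataset()] whose samples carry `population = pop` and
#'   provenance columns `type = "purebred"`, `parent_a`, `parent_b`, `seed`.
#' @export
simulate_purebred <- function(aft, pop, n, seed = 1L, snp_ids = NULL,
                              id_prefix = paste0("SIM_", pop)) {
  stopifnot(inherits(aft, "allele_freq_table"))
  if (!pop %in% aft$populations) stop_("unknown population: ", pop)
  aft <- sim_snp_subset(aft, snp_ids)
  p <- aft$freq[pop, ]
  check_defined(p, pop, colnames(aft$freq))
  m <- length(p)
  dosage <- with_seed(seed, {
    matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  })
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", id_prefix, seq_len(max(n, 0))),
    population = rep(pop, n), type = rep("purebred", n),
    parent_a = rep(pop, n), parent_b = rep(pop, n),
    seed = rep(as.integer(seed), n), stringsAsFactors = FALSE)
  genotype_dataset(dosage, aft$snps, samples)
}

#' Simulate first-generation (F1) hybrid genotypes
#'
#' Each F1 individual receives, at each SNP independently, one allele drawn
#' from each parental gene pool: dosage = Bernoulli(p_A) + Bernoulli(p_B).
#' The truth label of simulated hybrids is `"HY"`, with the parental
#' populations recorded as provenance.
#'
#' @param aft an [allele_freq_table()].
#' @param pop_A,pop_B distinct parental population labels.
#' @param n number of F1 individuals.
#' @param seed integer seed.
#' @param snp_ids optional SNP subset.
#' @param hybrid_label truth label assigned to the hybrids (default "HY").
#' @param id_prefix prefix for generated sample ids.
#' @return A [genotype_dataset()]; samples carry `type = "F1"` and the
#'   parental labels.
#' @export
simulate_f1 <- function(aft, pop_A, pop_B, n, seed = 1L, snp_ids = NULL,
                        hybrid_label = "HY",
                        id_prefix = paste0("F1_", pop_A, "x", pop_B)) {
  stopifnot(inherits(aft, "allele_freq_table"))
  if (identical(pop_A, pop_B)) {
    stop_("pop_A and pop_B must differ; use simulate_purebred() for one population")
  }
  for (p in c(pop_A, pop_B)) {
    if (!p %in% aft$populations) stop_("unknown population: ", p)
  }
  aft <- sim_snp_subset(aft, snp_ids)
  pa <- aft$freq[pop_A, ]; pb <- aft$freq[pop_B, ]
  check_defined(pa, pop_A, colnames(aft$freq))
  check_defined(pb, pop_B, colnames(aft$freq))
  m <- length(pa)
  dosage <- with_seed(seed, {
    a1 <- matrix(stats::rbinom(n * m, 1L, rep(pa, each = n)), nrow = n)
    a2 <- matrix(stats::rbinom(n * m, 1L, rep(pb, each = n)), nrow = n)
    a1 + a2
  })
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", id_prefix, seq_len(max(n, 0))),
    population = rep(hybrid_label, n), type = rep("F1", n),
    parent_a = rep(pop_A, n), parent_b = rep(pop_B, n),
    seed = rep(as.integer(seed), n), stringsAsFactors = FALSE)
  genotype_dataset(dosage, aft$snps, samples)
}

#' Assemble the four training/validation study cohorts
#'
#' Builds, restricted to the panel SNPs:
#' * `PTP` — purebred training: the real samples with complete panel
#'   genotypes;
#' * `HTP` — hybrid training: PTP plus `n_per_cross_training` simulated F1s
#'   per crossing (truth label "HY");
#' * `PVP` — purebred validation: `n_per_purebred` simulated purebreds per
#'   breed;
#' * `HVP` — hybrid validation: PVP plus `n_per_cross_validation` simulated
#'   F1s per crossing.
#' Every simulated sub-cohort draws from its own seed derived from the
#' plan's master seed, so training and validation hybrids are independent.
#'
#' @param real a QC'd [genotype_dataset()] of real purebred individuals.
#' @param aft an [allele_freq_table()] providing parental frequencies.
#' @param plan a [crossing_plan()].
#' @param panel a `snp_panel` or character vector of panel SNP ids.
#' @return Named list of `genotype_dataset`s: `PTP`, `HTP`, `PVP`, `HVP`.
#' @export
build_study_populations <- function(real, aft, plan, panel) {
  stopifnot(inherits(real, "genotype_dataset"), inherits(plan, "crossing_plan"))
  ids <- if (inherits(panel, "snp_panel")) panel$snp_id else as.character(panel)

  ptp <- drop_incomplete_samples(real, ids)
  if (nrow(ptp$samples) == 0L) {
    stop_("no real samples with complete panel genotypes (empty PTP)")
  }

  sim_cross <- function(n, stream0, tag) {
    out <- NULL
    for (i in seq_along(plan$crossings)) {
      if (n == 0) next
      cr <- plan$crossings[[i]]
      coh <- simulate_f1(aft, cr[1], cr[2], n,
                         seed = derive_seed(plan$seed, stream0 + i),
                         snp_ids = ids,
                         id_prefix = paste0(tag, "_", cr[1], "x", cr[2]))
      out <- if (is.null(out)) coh else bind_samples(out, coh)
    }
    out
  }

  htp_hy <- sim_cross(plan$n_per_cross_training, 100L, "HT")
  htp <- if (is.null(htp_hy)) ptp else bind_samples(ptp, htp_hy)

  pvp <- NULL
  for (i in seq_along(plan$purebred_pops)) {
    if (plan$n_per_purebred == 0) next
    pop <- plan$purebred_pops[i]
    coh <- simulate_purebred(aft, pop, plan$n_per_purebred,
                             seed = derive_seed(plan$seed, 200L + i),
                             snp_ids = ids, id_prefix = paste0("PV_", pop))
    pvp <- if (is.null(pvp)) coh else bind_samples(pvp, coh)
  }
  if (is.null(pvp)) {
    pvp <- subset_genotypes(ptp, sample_ids = character(0))
  }

  hvp_hy <- sim_cross(plan$n_per_cross_validation, 300L, "HV")
  hvp <- if (is.null(hvp_hy)) pvp else if (nrow(pvp$samples) == 0) hvp_hy else
    bind_samples(pvp, hvp_hy)

  list(PTP = ptp, HTP = htp, PVP = pvp, HVP = hvp)
}
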