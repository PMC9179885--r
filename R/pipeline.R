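# End-to-end orchestration: QC -> allele frequencies -> delta ranking ->
# panel selection -> study-cohort assembly -> discriminant assignment ->
# thresholding -> summary tables, driven by a YAML config.

#' Run the full traceability pipeline
#'
#' Executes, in order: data acquisition (a synthetic study or PLINK files),
#' quality control, per-population allele frequencies, delta-ranked core
#' panel selection with MDS-guided additions, between-breed augmentation,
#' assembly of the purebred/hybrid training and validation cohorts,
#' discriminant fitting and prediction on all four cohorts for both the
#' core and the augmented panel, posterior thresholding, and summary
#' export. Every artifact is written under `out_dir`, together with a
#' `manifest.yaml` recording the config and seed.
#'
#' @param config a YAML file path or a list with (a subset of) sections:
#'   `synthetic` (fields of [synthetic_study_config()]) or `input`
#'   (`ped`/`map` or `bed`/`bim`/`fam` paths); `qc`
#'   (`min_sample_call_rate`, `min_snp_call_rate`, `hwe_alpha`,
#'   `hwe_population`); `selection` (`focal`, `cosmopolitan`, `wild`);
#'   `plan` (fields of [crossing_plan()]); `threshold` (`tau`,
#'   `fallback_class`); `priors`; `seed`.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a list with the panels, cohorts, per-cohort
#'   assignment summaries and the paths of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir = "snptrace_out", quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_syn <- !is.null(config$synthetic)
  has_real <- !is.null(config$input)
  if (has_syn == has_real) {
    stop_("config needs exactly one of: a `synthetic` section or an `input` section")
  }
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ds) {
    if (!quiet) message(sprintf("[%s] %d samples x %d SNPs", stage,
                                nrow(ds$samples), nrow(ds$snps)))
  }

  # -- data
  if (has_syn) {
    syn <- config$synthetic
    ps <- syn$population_sizes %||% c(NS = 93L, LW = 44L, LR = 37L,
                                      DU = 44L, WB = 88L)
    ps <- stats::setNames(as.integer(ps), names(ps))
    scfg <- synthetic_study_config(
      population_sizes = ps,
      n_snps = syn$n_snps %||% 5000L,
      fst = unlist(syn$fst %||% 0.2),
      ancestral_freq_range = unlist(syn$ancestral_freq_range %||% c(0.05, 0.95)),
      missing_rate = syn$missing_rate %||% 0.015,
      seed = syn$seed %||% seed)
    study <- generate_study(scfg)
    ds <- study$dataset
    write_truth_record(study$truth, file.path(out_dir, "truth.tsv"))
  } else {
    inp <- config$input
    ds <- if (!is.null(inp$bed)) {
      read_plink_binary(inp$bed, inp$bim, inp$fam)
    } else {
      read_plink_text(inp$ped, inp$map)
    }
  }
  say("input", ds)

  # -- qc
  qc_cfg <- config$qc %||% list()
  thr <- qc_thresholds(qc_cfg$min_sample_call_rate %||% 0.95,
                       qc_cfg$min_snp_call_rate %||% 0.95,
                       qc_cfg$hwe_alpha %||% 0.01)
  qc <- apply_qc(ds, thr, hwe_population = qc_cfg$hwe_population)
  ds <- qc$dataset
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  say("qc", ds)

  # -- frequencies and panels
  sel_cfg <- config$selection %||% list()
  schemes <- study_selection_schemes(
    focal = sel_cfg$focal %||% "NS",
    cosmopolitan = unlist(sel_cfg$cosmopolitan %||% c("LR", "LW", "DU")),
    wild = sel_cfg$wild %||% "WB")
  aft <- allele_frequencies(ds)
  write_frequency_table(aft, file.path(out_dir, "allele_frequencies.tsv"))

  core <- select_panel(aft, schemes$core)
  core <- mds_guided_slots(core, aft, schemes$mds_guided$pairs,
                           schemes$mds_guided$count)
  full <- augment_panel(core, aft, schemes$augmentation)
  write_panel(core, file.path(out_dir, "panel_core.tsv"))
  write_panel(full, file.path(out_dir, "panel_full.tsv"))
  if (!quiet) message(sprintf("[panel] core %d SNPs, augmented %d SNPs",
                              nrow(core), nrow(full)))

  # -- MDS of the panel genotypes (coordinates export)
  mds_ds <- drop_incomplete_samples(ds, full)
  if (nrow(mds_ds$samples) >= 3) {
    mds <- classical_mds(ibs_matrix(mds_ds), k = 2)
    write_mds_coordinates(mds, file.path(out_dir, "mds_coordinates.tsv"))
  }

  # -- cohorts and assignment, both panels
  plan_cfg <- config$plan %||% list()
  pops <- sort(unique(ds$samples$population))
  plan <- crossing_plan(
    crossings = plan_cfg$crossings %||%
      default_crossings(focal = sel_cfg$focal %||% "NS",
                        wild = sel_cfg$wild %||% "WB",
                        cosmopolitan = unlist(sel_cfg$cosmopolitan %||%
                                                c("DU", "LR", "LW"))),
    n_per_cross_training = plan_cfg$n_per_cross_training %||% 20L,
    n_per_cross_validation = plan_cfg$n_per_cross_validation %||% 10L,
    purebred_pops = plan_cfg$purebred_pops %||% pops,
    n_per_purebred = plan_cfg$n_per_purebred %||% 40L,
    seed = plan_cfg$seed %||% seed)
  rule <- threshold_rule(config$threshold$tau %||% 0.65,
                         config$threshold$fallback_class %||% "HY")
  priors <- config$priors %||% "proportional"

  summaries <- list()
  rates <- NULL
  for (panel_name in c("core", "full")) {
    panel <- if (panel_name == "core") core else full
    cohorts <- build_study_populations(ds, aft, plan, panel)
    fit_p <- fit_cda(cohorts$PTP, priors = priors)
    fit_h <- if (nrow(cohorts$HTP$samples) > nrow(cohorts$PTP$samples)) {
      fit_cda(cohorts$HTP, priors = priors)
    } else fit_p
    for (coh in c("PTP", "PVP", "HTP", "HVP")) {
      model <- if (coh %in% c("PTP", "PVP")) fit_p else fit_h
      res <- predict(model, cohorts[[coh]])
      res <- apply_threshold(res, rule)
      truth <- cohorts[[coh]]$samples$population
      sm <- assignment_summary(res, truth)
      key <- paste(panel_name, coh, sep = "_")
      summaries[[key]] <- sm
      write_assignment_report(
        res, file.path(out_dir, paste0("assignments_", key, ".tsv")),
        truth = truth)
      rates <- rbind(rates, data.frame(
        panel = panel_name, cohort = coh,
        n = sm$overall[["n_total"]],
        n_correct = sm$overall[["n_correct_cda"]],
        rate = sm$overall[["rate_cda"]],
        rate_thresholded = sm$overall[["rate_thresholded"]],
        stringsAsFactors = FALSE))
      if (!quiet) message(sprintf("[assign] %s %s: %.1f%% correct",
                                  panel_name, coh,
                                  100 * sm$overall[["rate_cda"]]))
    }
  }
  write_tsv(rates, file.path(out_dir, "assignment_rates.tsv"))

  manifest <- list(package = "snptrace",
                   version = as.character(utils::packageVersion("snptrace")),
                   seed = seed, config = config)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(panel_core = core, panel_full = full, rates = rates,
                 summaries = summaries, out_dir = out_dir))
}
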