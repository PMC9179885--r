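# Reduced-panel construction: per-breed-pair delta ranking with
# deduplication, plus the MDS-guided and between-breed augmentation stages.

#' Selection scheme for a delta-ranked panel
#'
#' An ordered list of breed pairs with the number of top-delta SNPs to take
#' from each pair's ranking.
#'
#' @param pop_i,pop_j character vectors (recycled to equal length) naming
#'   the populations of each comparison.
#' @param count positive integer vector: SNPs to select per comparison.
#' @return A data.frame of class `selection_scheme` with columns `pop_i`,
#'   `pop_j`, `count`.
#' @export
selection_scheme <- function(pop_i, pop_j, count) {
  df <- data.frame(pop_i = pop_i, pop_j = pop_j, count = as.integer(count),
                   stringsAsFactors = FALSE)
  if (any(df$count < 1L)) stop_("selection counts must be >= 1")
  if (any(df$pop_i == df$pop_j)) stop_("a comparison needs two distinct populations")
  class(df) <- c("selection_scheme", "data.frame")
  df
}

#' Study selection schemes for a five-breed design
#'
#' The per-comparison counts used to build the panels for a design with a
#' focal breed (default NS), three cosmopolitan breeds (LR, LW, DU) and wild
#' boar (WB): a focal-vs-other core (3 + 3 + 2 + 1 = 9 SNPs), 3 additional
#' SNPs for the near-clustering LR-LW pair identified by MDS (core panel of
#' 12), and 8 SNPs over the remaining between-breed pairs (final panel of
#' 20, weighted toward LR-LW, the hardest pair to separate).
#'
#' @param focal focal breed label (default `"NS"`).
#' @param cosmopolitan labels of the cosmopolitan breeds, in the order used
#'   for the 3/3/2/1 counts together with `wild`.
#' @param wild wild-population label (default `"WB"`).
#' @return A list with elements `core`, `mds_guided` (list: `pairs`,
#'   `count`), and `augmentation` [selection_scheme()]s.
#' @export
study_selection_schemes <- function(focal = "NS",
                                    cosmopolitan = c("LR", "LW", "DU"),
                                    wild = "WB") {
  lr <- cosmopolitan[1]; lw <- cosmopolitan[2]; du <- cosmopolitan[3]
  list(
    core = selection_scheme(pop_i = rep(focal, 4),
                            pop_j = c(lr, lw, wild, du),
                            count = c(3L, 3L, 2L, 1L)),
    mds_guided = list(pairs = list(c(lr, lw)), count = 3L),
    augmentation = selection_scheme(
      pop_i = c(lr, lr, lw, lr, lw, du),
      pop_j = c(lw, du, du, wild, wild, wild),
      count = c(3L, 1L, 1L, 1L, 1L, 1L))
  )
}

take_top <- function(aft, pop_i, pop_j, count, exclude, stage) {
  dt <- delta_table(aft, pop_i, pop_j)
  dt <- dt[!dt$snp_id %in% exclude, , drop = FALSE]
  if (nrow(dt) < count) {
    stop_("not enough distinct SNPs with a defined delta for the ",
          pop_i, "-", pop_j, " comparison (need ", count, ", have ",
          nrow(dt), ")")
  }
  dt <- dt[seq_len(count), , drop = FALSE]
  data.frame(snp_id = dt$snp_id, pop_i = pop_i, pop_j = pop_j,
             delta = dt$delta, stage = stage, stringsAsFactors = FALSE)
}

as_panel <- function(entries, aft) {
  rownames(entries) <- NULL
  meta <- aft$snps[match(entries$snp_id, aft$snps$snp_id), , drop = FALSE]
  entries$chromosome <- meta$chromosome
  entries$position <- meta$position
  class(entries) <- c("snp_panel", "data.frame")
  entries
}

#' Select a delta-ranked SNP panel
#'
#' Processes the scheme's comparisons in order; each comparison contributes
#' its `count` highest-delta SNPs not already selected (a SNP may fill only
#' one slot — a later pair whose top SNP is taken moves to its next-ranked
#' SNP, so the panel size always equals the scheme's count total). Ties in
#' delta are broken by `snp_id` ascending, making the selection fully
#' deterministic.
#'
#' @param aft an [allele_freq_table()].
#' @param scheme a [selection_scheme()].
#' @param stage provenance label recorded for the selected entries.
#' @return A data.frame of class `snp_panel` with columns `snp_id`, `pop_i`,
#'   `pop_j` (the source comparison), `delta` (at selection), `stage`,
#'   `chromosome`, `position`.
#' @export
select_panel <- function(aft, scheme, stage = "core") {
  stopifnot(inherits(aft, "allele_freq_table"),
            inherits(scheme, "selection_scheme"))
  entries <- NULL
  for (r in seq_len(nrow(scheme))) {
    sel <- take_top(aft, scheme$pop_i[r], scheme$pop_j[r], scheme$count[r],
                    exclude = entries$snp_id %||% character(0), stage = stage)
    entries <- rbind(entries, sel)
  }
  as_panel(entries, aft)
}

#' Augment a panel with additional between-breed SNPs
#'
#' Appends SNPs chosen exactly as in [select_panel()] but over a further set
#' of comparisons (typically the non-focal breed pairs), skipping SNPs
#' already in the panel.
#'
#' @param panel an existing `snp_panel`.
#' @param aft an [allele_freq_table()].
#' @param extra a [selection_scheme()] for the additional comparisons.
#' @param stage provenance label (default `"augmentation"`).
#' @return The grown `snp_panel`.
#' @export
augment_panel <- function(panel, aft, extra, stage = "augmentation") {
  stopifnot(inherits(panel, "snp_panel"), inherits(aft, "allele_freq_table"),
            inherits(extra, "selection_scheme"))
  entries <- as.data.frame(panel)[, c("snp_id", "pop_i", "pop_j", "delta", "stage")]
  for (r in seq_len(nrow(extra))) {
    sel <- take_top(aft, extra$pop_i[r], extra$pop_j[r], extra$count[r],
                    exclude = entries$snp_id, stage = stage)
    entries <- rbind(entries, sel)
  }
  as_panel(entries, aft)
}

#' MDS-guided panel slots
#'
#' Adds SNPs for pairs of populations that cluster closely in the MDS
#' embedding (e.g. LR-LW): for each such pair, the `count` highest-delta
#' SNPs not already selected are appended with stage `"mds_guided"`. This
#' operationalizes "improve the separation of near-clustering breeds" as
#' delta ranking restricted to those pairs.
#'
#' @param panel an existing `snp_panel`.
#' @param aft an [allele_freq_table()].
#' @param pair_list list of 2-element character vectors naming the
#'   near-clustering pairs (default `list(c("LR", "LW"))`).
#' @param count SNPs to add per pair; 0 leaves the panel unchanged.
#' @return The grown `snp_panel`.
#' @export
mds_guided_slots <- function(panel, aft, pair_list = list(c("LR", "LW")),
                             count = 3L) {
  stopifnot(inherits(panel, "snp_panel"), inherits(aft, "allele_freq_table"))
  if (count < 0) stop_("count must be >= 0")
  if (count == 0L) return(panel)
  entries <- as.data.frame(panel)[, c("snp_id", "pop_i", "pop_j", "delta", "stage")]
  for (pr in pair_list) {
    sel <- take_top(aft, pr[1], pr[2], count, exclude = entries$snp_id,
                    stage = "mds_guided")
    entries <- rbind(entries, sel)
  }
  as_panel(entries, aft)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", nrow(x), " SNPs (",
      paste(sprintf("%s: %d", names(table(x$stage)), as.integer(table(x$stage))),
            collapse = ", "), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a SNP panel as TSV
#'
#' Columns mirror a published panel table: snp_id, chromosome, position,
#' source comparison, delta at selection, and selection stage.
#'
#' @param panel a `snp_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  write_tsv(as.data.frame(panel), path)
}
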