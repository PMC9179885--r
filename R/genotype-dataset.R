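#' Genotype dataset container
#'
#' Holds diploid biallelic SNP genotypes as counted-allele dosages together
#' with per-SNP and per-sample metadata. The dosage entry for sample `i` and
#' SNP `j` is the number of copies (0, 1 or 2) of that SNP's counted allele
#' carried by the sample; missing calls are `NA`.
#'
#' @param dosage numeric matrix, samples in rows and SNPs in columns, with
#'   entries in `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `counted_allele`, `other_allele` and optionally `rs_id`. `snp_id` must be
#'   unique; alleles are single characters in `A/C/G/T`, or `"0"` for the
#'   unknown second allele of a monomorphic marker.
#' @param samples data.frame with columns `sample_id` (unique) and
#'   `population` (non-empty label). Extra columns (e.g. simulation
#'   provenance) are preserved.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosage`, `snps`, `samples`.
#' @export
genotype_dataset <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  req_snp <- c("snp_id", "chromosome", "position", "counted_allele", "other_allele")
  if (!all(req_snp %in% names(snps))) {
    stop_("snps metadata must have columns: ", paste(req_snp, collapse = ", "))
  }
  if (!"rs_id" %in% names(snps)) snps$rs_id <- NA_character_
  if (!all(c("sample_id", "population") %in% names(samples))) {
    stop_("samples metadata must have columns sample_id, population")
  }
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(snps)) {
    stop_("dosage dimensions (", nrow(dosage), " x ", ncol(dosage),
          ") do not match samples (", nrow(samples), ") x snps (", nrow(snps), ")")
  }
  if (anyDuplicated(snps$snp_id)) {
    stop_("duplicate snp_id: ",
          paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_("duplicate sample_id: ",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (any(!is.na(samples$population) & !nzchar(samples$population))) {
    stop_("population labels must be non-empty")
  }
  if (nrow(snps) > 0) {
    bad <- snps$counted_allele == snps$other_allele & snps$other_allele != "0"
    if (any(bad)) {
      stop_("counted and other allele identical for: ",
            paste(snps$snp_id[bad], collapse = ", "))
    }
    if (any(snps$position < 0, na.rm = TRUE)) stop_("SNP positions must be >= 0")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop_("dosage entries must be in {0, 1, 2, NA}")
  }
  dimnames(dosage) <- list(samples$sample_id, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$samples), " samples x ", nrow(x$snps),
      " SNPs\n", sep = "")
  if (nrow(x$samples)) {
    tab <- table(x$samples$population)
    cat("  populations:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  miss <- if (length(x$dosage)) mean(is.na(x$dosage)) else 0
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(nrow(x$samples), nrow(x$snps))

#' Subset a genotype dataset
#'
#' Restrict a dataset to named SNPs and/or samples, preserving the order of
#' the requested identifiers.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_ids,sample_ids character vectors of identifiers to keep, or
#'   `NULL` to keep all. Unknown identifiers are an error.
#' @return A `genotype_dataset`.
#' @export
subset_genotypes <- function(ds, snp_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- seq_len(nrow(ds$samples))
  sj <- seq_len(nrow(ds$snps))
  if (!is.null(snp_ids)) {
    sj <- match(snp_ids, ds$snps$snp_id)
    if (anyNA(sj)) {
      stop_("unknown snp_id(s): ", paste(snp_ids[is.na(sj)], collapse = ", "))
    }
  }
  if (!is.null(sample_ids)) {
    si <- match(sample_ids, ds$samples$sample_id)
    if (anyNA(si)) {
      stop_("unknown sample_id(s): ", paste(sample_ids[is.na(si)], collapse = ", "))
    }
  }
  genotype_dataset(ds$dosage[si, sj, drop = FALSE],
                   ds$snps[sj, , drop = FALSE],
                   ds$samples[si, , drop = FALSE])
}

#' Stack the samples of two datasets typed on the same SNPs
#'
#' @param a,b `genotype_dataset` objects with identical SNP metadata and
#'   disjoint sample identifiers.
#' @return A `genotype_dataset` with the samples of `a` followed by `b`.
#' @export
bind_samples <- function(a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  if (!identical(a$snps$snp_id, b$snps$snp_id)) {
    stop_("datasets are typed on different SNP sets")
  }
  if (any(b$samples$sample_id %in% a$samples$sample_id)) {
    stop_("sample_ids overlap between the two datasets")
  }
  cols <- union(names(a$samples), names(b$samples))
  fill <- function(df) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
    df[, cols, drop = FALSE]
  }
  genotype_dataset(rbind(a$dosage, b$dosage), a$snps,
                   rbind(fill(a$samples), fill(b$samples)))
}

# Ambiguous = the allele pair is its own reverse complement (A/T or C/G):
# strand cannot be inferred from the alleles alone.
is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Merge two genotype datasets on their common SNPs
#'
#' Keeps the SNPs present in both datasets, harmonizing allele coding: where
#' the second dataset records the counted/other alleles swapped relative to
#' the first, its dosages are recoded as `2 - g`. No strand flipping is
#' attempted; A/T and C/G strand-ambiguous SNPs whose allele pairs are not
#' recorded identically in both datasets are dropped, as are SNPs with
#' irreconcilable allele pairs. `"0"` (the unknown allele of a monomorphic
#' marker) matches any allele.
#'
#' @param a,b `genotype_dataset` objects with disjoint sample identifiers.
#' @return A `genotype_dataset` with the samples of `a` followed by those of
#'   `b`, restricted to the harmonized SNPs, with attribute `merge_report`: a
#'   data.frame (`snp_id`, `action` in kept/flipped/dropped, `reason`).
#' @export
merge_genotypes <- function(a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  if (any(b$samples$sample_id %in% a$samples$sample_id)) {
    stop_("sample_ids must be disjoint between the datasets being merged")
  }
  common <- intersect(a$snps$snp_id, b$snps$snp_id)
  if (length(common) == 0L) stop_("no SNPs in common between the two datasets")

  ia <- match(common, a$snps$snp_id)
  ib <- match(common, b$snps$snp_id)
  ca <- a$snps$counted_allele[ia]; oa <- a$snps$other_allele[ia]
  cb <- b$snps$counted_allele[ib]; ob <- b$snps$other_allele[ib]

  amatch <- function(x, y) x == y | x == "0" | y == "0"
  direct <- amatch(cb, ca) & amatch(ob, oa)
  swapped <- !direct & amatch(cb, oa) & amatch(ob, ca)
  ambig <- is_ambiguous_pair(ca, oa) | is_ambiguous_pair(cb, ob)
  # For ambiguous pairs a swap is indistinguishable from a strand flip:
  # keep only the literal match.
  action <- ifelse(direct & !(ambig & !(cb == ca & ob == oa)), "kept",
            ifelse(swapped & !ambig, "flipped", "dropped"))
  reason <- ifelse(action == "kept", "",
            ifelse(action == "flipped", "counted/other alleles swapped",
            ifelse(ambig, "strand_ambiguous", "irreconcilable_alleles")))

  report <- data.frame(snp_id = c(common,
                                  setdiff(a$snps$snp_id, common),
                                  setdiff(b$snps$snp_id, common)),
                       action = c(action,
                                  rep("dropped", nrow(a$snps) + nrow(b$snps) -
                                        2L * length(common))),
                       reason = c(reason,
                                  rep("not_in_both", nrow(a$snps) + nrow(b$snps) -
                                        2L * length(common))),
                       stringsAsFactors = FALSE)

  keep <- common[action != "dropped"]
  if (length(keep) == 0L) stop_("no SNPs in common after allele harmonization")
  flip <- common[action == "flipped"]

  da <- a$dosage[, match(keep, a$snps$snp_id), drop = FALSE]
  db <- b$dosage[, match(keep, b$snps$snp_id), drop = FALSE]
  if (length(flip)) {
    j <- match(flip, keep)
    db[, j] <- 2 - db[, j]
  }
  out <- genotype_dataset(rbind(da, db),
                          a$snps[match(keep, a$snps$snp_id), , drop = FALSE],
                          {
                            cols <- union(names(a$samples), names(b$samples))
                            fa <- a$samples; fb <- b$samples
                            for (cn in setdiff(cols, names(fa))) fa[[cn]] <- NA
                            for (cn in setdiff(cols, names(fb))) fb[[cn]] <- NA
                            rbind(fa[, cols, drop = FALSE], fb[, cols, drop = FALSE])
                          })
  attr(out, "merge_report") <- report
  out
}

#' Write a merge report as TSV
#'
#' @param ds a merged dataset carrying a `merge_report` attribute.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(ds, path) {
  rep <- attr(ds, "merge_report")
  if (is.null(rep)) stop_("dataset carries no merge_report attribute")
  write_tsv(rep, path)
}
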