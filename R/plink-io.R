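# PLINK text (PED/MAP) and binary (BED/BIM/FAM) genotype I/O.
# No installed package in this stack reads these formats, so the parsers are
# written against the PLINK 1.9 file-format description.

#' Read PLINK text genotypes (PED/MAP)
#'
#' The PED family-ID column becomes the population label and the
#' within-family ID the sample ID. The allele pair `0 0` (or any pair
#' containing `0`) is a missing call. Unless `allele_ref` is given, the
#' counted allele of each SNP is fixed as the first non-missing allele
#' encountered down the sample rows, and dosages count copies of it.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param allele_ref optional data.frame (`snp_id`, `counted_allele`,
#'   `other_allele`) fixing the allele coding, e.g. to make a text round-trip
#'   reproduce the original dosage matrix exactly.
#' @return A [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path, allele_ref = NULL) {
  if (!file.exists(ped_path)) stop_("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop_("MAP file not found: ", map_path)

  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) == 3L) map <- cbind(map[, 1:2], V3 = "0", map[, 3, drop = FALSE])
  if (ncol(map) != 4L) stop_("MAP file must have 3 or 4 columns")
  snps <- data.frame(snp_id = map[[2]], rs_id = NA_character_,
                     chromosome = map[[1]],
                     position = as.integer(map[[4]]),
                     counted_allele = "0", other_allele = "0",
                     stringsAsFactors = FALSE)
  if (anyDuplicated(snps$snp_id)) {
    stop_("duplicate marker in MAP: ",
          paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  m <- nrow(snps)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) {
    return(genotype_dataset(matrix(NA_real_, 0, m), snps,
                            data.frame(sample_id = character(0),
                                       population = character(0),
                                       stringsAsFactors = FALSE)))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  len <- lengths(toks)
  if (any(len != want)) {
    bad <- which(len != want)[1]
    stop_("malformed PED line ", bad, ": expected ", want, " fields, found ",
          len[bad])
  }
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- data.frame(sample_id = tok[, 2], population = tok[, 1],
                        stringsAsFactors = FALSE)
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA; a2[miss] <- NA

  if (is.null(allele_ref)) {
    counted <- other <- rep("0", m)
    for (j in seq_len(m)) {
      al <- c(rbind(a1[, j], a2[, j]))      # sample-major allele stream
      al <- al[!is.na(al)]
      if (length(al)) {
        counted[j] <- al[1]
        rest <- al[al != al[1]]
        if (length(rest)) other[j] <- rest[1]
      }
    }
  } else {
    k <- match(snps$snp_id, allele_ref$snp_id)
    if (anyNA(k)) {
      stop_("allele_ref missing SNPs: ",
            paste(snps$snp_id[is.na(k)], collapse = ", "))
    }
    counted <- allele_ref$counted_allele[k]
    other <- allele_ref$other_allele[k]
  }
  snps$counted_allele <- counted
  snps$other_allele <- other

  cnt <- matrix(rep(counted, each = n), nrow = n)
  dosage <- (a1 == cnt) + (a2 == cnt)
  dosage[miss] <- NA
  genotype_dataset(dosage, snps, samples)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param ds a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(ds, ped_path, map_path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  utils::write.table(
    data.frame(ds$snps$chromosome, ds$snps$snp_id, 0L, ds$snps$position),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  n <- nrow(ds$samples); m <- nrow(ds$snps)
  ca <- ds$snps$counted_allele; oa <- ds$snps$other_allele
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- ds$dosage[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, ca, oa))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, ca, oa))
    lines[i] <- paste(c(ds$samples$population[i], ds$samples$sample_id[i],
                        "0", "0", "0", "-9", c(rbind(a1, a2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

# 2-bit genotype codes of the PLINK .bed format, SNP-major:
# 00 = homozygous A1 (dosage 2 of the counted allele), 01 = missing,
# 10 = heterozygous, 11 = homozygous A2. Samples fill each byte from the
# low-order bit pair.
bed_code_to_dosage <- c(2, NA, 1, 0)

bed_byte_table <- function() {
  tab <- matrix(NA_real_, 256, 4)
  for (b in 0:255) {
    for (i in 0:3) tab[b + 1, i + 1] <- bed_code_to_dosage[bitwAnd(bitwShiftR(b, 2L * i), 3L) + 1L]
  }
  tab
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Requires SNP-major BED files (mode byte `0x01`), the only mode PLINK 1.9
#' writes. BIM allele 1 is taken as the counted allele.
#'
#' @param bed_path,bim_path,fam_path paths to the three files.
#' @return A [genotype_dataset()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop_("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(bim) != 6L) stop_("BIM file must have 6 columns")
  snps <- data.frame(snp_id = bim[[2]], rs_id = NA_character_,
                     chromosome = bim[[1]], position = as.integer(bim[[4]]),
                     counted_allele = bim[[5]], other_allele = bim[[6]],
                     stringsAsFactors = FALSE)
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  samples <- data.frame(sample_id = fam[[2]], population = fam[[1]],
                        stringsAsFactors = FALSE)
  n <- nrow(samples); m <- nrow(snps)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_("not a PLINK BED file (bad magic number): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) stop_("only SNP-major BED files are supported")
  bps <- ceiling(n / 4)                      # bytes per SNP block
  expected <- 3L + bps * m
  if (length(raw) != expected) {
    stop_("truncated or oversized BED file: expected ", expected,
          " bytes, found ", length(raw))
  }
  tab <- bed_byte_table()
  body <- as.integer(raw[-(1:3)])
  # rows of `tab` indexed by byte value give 4 sample dosages per byte
  dos <- matrix(t(tab[body + 1L, , drop = FALSE]), nrow = 4L * bps)
  dosage <- dos[seq_len(n), , drop = FALSE]
  genotype_dataset(dosage, snps, samples)
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' @param ds a [genotype_dataset()].
#' @param bed_path,bim_path,fam_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_plink_binary <- function(ds, bed_path, bim_path, fam_path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  utils::write.table(
    data.frame(ds$snps$chromosome, ds$snps$snp_id, 0L, ds$snps$position,
               ds$snps$counted_allele, ds$snps$other_allele),
    bim_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(ds$samples$population, ds$samples$sample_id, 0L, 0L, 0L, -9L),
    fam_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  n <- nrow(ds$samples); m <- nrow(ds$snps)
  bps <- ceiling(n / 4)
  # dosage -> 2-bit code (inverse of bed_code_to_dosage)
  code <- ds$dosage
  codes <- ifelse(is.na(code), 1L, ifelse(code == 2, 0L, ifelse(code == 1, 2L, 3L)))
  out <- raw(3L + bps * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pad <- matrix(0L, nrow = 4L * bps, ncol = m)
  if (n > 0 && m > 0) pad[seq_len(n), ] <- codes
  shifts <- rep(c(0L, 2L, 4L, 6L), bps)
  shifted <- pad * bitwShiftL(1L, shifts)    # value << shift per sample slot
  if (n > 0 && m > 0) {
    dim(shifted) <- c(4L, bps * m)           # column-major = BED byte order
    out[-(1:3)] <- as.raw(colSums(shifted))
  }
  writeBin(out, bed_path)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}
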