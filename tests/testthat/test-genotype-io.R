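# PLINK text/binary I/O, merging and subsetting.

write_lines <- function(lines, path) { writeLines(lines, path); path }

test_that("PED/MAP parsing encodes dosages against the first allele seen", {
  tmp <- withr::local_tempdir()
  ped <- write_lines(c("FAM1 ind1 0 0 0 -9 A A G G",
                       "FAM2 ind2 0 0 0 -9 A C 0 0"),
                     file.path(tmp, "toy.ped"))
  map <- write_lines(c("1\ts1\t0\t100", "1\ts2\t0\t200"),
                     file.path(tmp, "toy.map"))
  ds <- read_plink_text(ped, map)
  expect_equal(unname(ds$dosage), rbind(c(2, 2), c(1, NA)))
  expect_equal(ds$snps$counted_allele, c("A", "G"))
  expect_equal(ds$snps$other_allele, c("C", "0"))
  expect_equal(ds$samples$population, c("FAM1", "FAM2"))
})

test_that("an empty PED with a valid MAP yields zero samples", {
  tmp <- withr::local_tempdir()
  ped <- write_lines(character(0), file.path(tmp, "e.ped"))
  map <- write_lines(c("1\ts1\t0\t100", "2\ts2\t0\t200"),
                     file.path(tmp, "e.map"))
  ds <- read_plink_text(ped, map)
  expect_equal(dim(ds), c(0L, 2L))
})

test_that("malformed PED lines and duplicate markers are rejected by name", {
  tmp <- withr::local_tempdir()
  map <- write_lines(c("1\ts1\t0\t100", "1\ts2\t0\t200"),
                     file.path(tmp, "m.map"))
  bad <- write_lines("FAM1 ind1 0 0 0 -9 A A", file.path(tmp, "bad.ped"))
  expect_error(read_plink_text(bad, map), "line 1")
  dupmap <- write_lines(c("1\ts1\t0\t100", "1\ts1\t0\t200"),
                        file.path(tmp, "dup.map"))
  ok <- write_lines("FAM1 ind1 0 0 0 -9 A A G G", file.path(tmp, "ok.ped"))
  expect_error(read_plink_text(ok, dupmap), "duplicate")
})

test_that("text and binary round-trips reproduce the dataset", {
  set.seed(42)
  g <- matrix(sample(c(0, 1, 2, NA), 60, TRUE), nrow = 6)
  ds <- make_dataset(g, populations = rep(c("NS", "WB"), each = 3),
                     counted = "A", other = "C")
  tmp <- withr::local_tempdir()

  write_plink_text(ds, file.path(tmp, "x.ped"), file.path(tmp, "x.map"))
  back <- read_plink_text(file.path(tmp, "x.ped"), file.path(tmp, "x.map"),
                          allele_ref = ds$snps)
  expect_dosage_equal(ds, back)
  expect_equal(back$samples$population, ds$samples$population)
  expect_equal(back$snps$snp_id, ds$snps$snp_id)

  write_plink_binary(ds, file.path(tmp, "x.bed"), file.path(tmp, "x.bim"),
                     file.path(tmp, "x.fam"))
  bin <- read_plink_binary(file.path(tmp, "x.bed"), file.path(tmp, "x.bim"),
                           file.path(tmp, "x.fam"))
  expect_dosage_equal(ds, bin)
  expect_equal(bin$snps$counted_allele, ds$snps$counted_allele)

  # writing the re-read text dataset again must round-trip too
  write_plink_text(back, file.path(tmp, "y.ped"), file.path(tmp, "y.map"))
  again <- read_plink_text(file.path(tmp, "y.ped"), file.path(tmp, "y.map"),
                           allele_ref = back$snps)
  expect_dosage_equal(back, again)

  # and binary / text exports of the same dataset read back identically
  expect_dosage_equal(back, bin)
})

test_that("BED 2-bit codes decode per the binary format", {
  tmp <- withr::local_tempdir()
  # 4 samples, 2 SNPs: SNP1 byte 0x00 = four homozygous-A1 calls;
  # SNP2 codes (sample1..4) = 00, 10, 01, 11 -> byte 11 01 10 00 = 0xD8
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0xD8)), file.path(tmp, "t.bed"))
  writeLines(c("1\ts1\t0\t100\tA\tG", "1\ts2\t0\t200\tA\tG"),
             file.path(tmp, "t.bim"))
  writeLines(sprintf("P%d\tind%d\t0\t0\t0\t-9", 1:4, 1:4),
             file.path(tmp, "t.fam"))
  ds <- read_plink_binary(file.path(tmp, "t.bed"), file.path(tmp, "t.bim"),
                          file.path(tmp, "t.fam"))
  expect_equal(unname(ds$dosage[, 1]), c(2, 2, 2, 2))
  expect_equal(unname(ds$dosage[, 2]), c(2, 1, NA, 0))
})

test_that("bad magic bytes and truncated BED blocks are rejected", {
  tmp <- withr::local_tempdir()
  writeLines("1\ts1\t0\t100\tA\tG", file.path(tmp, "t.bim"))
  writeLines("P1\tind1\t0\t0\t0\t-9", file.path(tmp, "t.fam"))
  writeBin(as.raw(c(0xff, 0x1b, 0x01, 0x00)), file.path(tmp, "bad.bed"))
  expect_error(read_plink_binary(file.path(tmp, "bad.bed"),
                                 file.path(tmp, "t.bim"),
                                 file.path(tmp, "t.fam")), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(tmp, "trunc.bed"))
  expect_error(read_plink_binary(file.path(tmp, "trunc.bed"),
                                 file.path(tmp, "t.bim"),
                                 file.path(tmp, "t.fam")),
               "expected 4 bytes, found 3")
})

test_that("merging keeps common SNPs and recodes swapped alleles", {
  a <- make_dataset(rbind(c(2, 1, 0), c(1, 1, 2)), c("NS", "NS"),
                    snp_ids = c("s1", "s2", "s3"))
  bsnps <- make_snps(c("s2", "s3", "s4"))
  bsnps$counted_allele[1] <- "G"; bsnps$other_allele[1] <- "A"  # s2 swapped
  b <- genotype_dataset(rbind(c(0, 2, 1), c(2, 0, 1)), bsnps,
                        data.frame(sample_id = c("w1", "w2"),
                                   population = "WB"))
  m <- merge_genotypes(a, b)
  expect_setequal(m$snps$snp_id, c("s2", "s3"))
  # b's s2 dosage 0 under swapped coding -> 2 under a's coding
  expect_equal(unname(m$dosage[3:4, m$snps$snp_id == "s2"]), c(2, 0))
  rep <- attr(m, "merge_report")
  expect_equal(rep$action[rep$snp_id == "s2"], "flipped")
  expect_equal(rep$action[rep$snp_id == "s4"], "dropped")
})

test_that("merge SNP content is symmetric and ambiguous swaps are dropped", {
  asnps <- make_snps(c("s1", "s2"))
  asnps$counted_allele <- c("A", "A"); asnps$other_allele <- c("T", "G")
  a <- genotype_dataset(rbind(c(1, 2), c(0, 1)), asnps,
                        data.frame(sample_id = c("a1", "a2"), population = "NS"))
  bsnps <- make_snps(c("s1", "s2"))
  bsnps$counted_allele <- c("T", "A"); bsnps$other_allele <- c("A", "G")
  b <- genotype_dataset(rbind(c(1, 0), c(2, 2)), bsnps,
                        data.frame(sample_id = c("b1", "b2"), population = "WB"))
  m <- merge_genotypes(a, b)
  # s1 is A/T with swapped coding: indistinguishable from a strand flip
  expect_equal(m$snps$snp_id, "s2")
  rep <- attr(m, "merge_report")
  expect_equal(rep$reason[rep$snp_id == "s1"], "strand_ambiguous")
  m2 <- merge_genotypes(b, a)
  expect_setequal(m$snps$snp_id, m2$snps$snp_id)
})

test_that("self-merge under renamed samples preserves allele frequencies", {
  g <- rbind(c(2, 1), c(0, 1), c(1, 2))
  a <- make_dataset(g, rep("NS", 3))
  b <- make_dataset(g, rep("NS", 3), sample_ids = sprintf("dup%d", 1:3))
  m <- merge_genotypes(a, b)
  expect_equal(nrow(m$samples), 6L)
  expect_equal(unname(colMeans(m$dosage) / 2), unname(colMeans(g) / 2))
  c_ <- make_dataset(g[, 1, drop = FALSE], rep("NS", 3),
                     snp_ids = "zzz", sample_ids = sprintf("c%d", 1:3))
  expect_error(merge_genotypes(a, c_), "no SNPs in common")
  expect_error(merge_genotypes(a, a), "disjoint")
})

test_that("subsetting preserves order, composes, and rejects unknown ids", {
  set.seed(7)
  ds <- make_dataset(matrix(sample(0:2, 40, TRUE), 5), rep("NS", 5))
  expect_dosage_equal(subset_genotypes(ds, ds$snps$snp_id,
                                       ds$samples$sample_id), ds)
  one <- subset_genotypes(ds, snp_ids = "s3")
  expect_equal(unname(one$dosage), ds$dosage[, 3, drop = FALSE],
               ignore_attr = TRUE)
  aset <- c("s5", "s2", "s4")
  bset <- c("s4", "s2")
  expect_dosage_equal(subset_genotypes(subset_genotypes(ds, aset), bset),
                      subset_genotypes(ds, bset))
  expect_equal(subset_genotypes(ds, aset)$snps$snp_id, aset)
  expect_error(subset_genotypes(ds, snp_ids = "nope"), "nope")
})
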