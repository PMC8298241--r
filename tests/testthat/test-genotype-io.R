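# write a ped/map pair encoding the given dosage matrix (risk-allele counts)
write_ped_map <- function(dosage, panel, stem) {
  map <- data.frame(panel$chrom, panel$snp_id, 0, panel$pos)
  write.table(map, paste0(stem, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ped_rows <- lapply(seq_len(nrow(dosage)), function(i) {
    alleles <- unlist(lapply(seq_len(ncol(dosage)), function(j) {
      d <- dosage[i, j]
      if (is.na(d)) c("0", "0")
      else c(rep(panel$risk_allele[j], d), rep(panel$other_allele[j], 2 - d))
    }))
    c("FAM", rownames(dosage)[i], "0", "0", "1", "-9", alleles)
  })
  writeLines(vapply(ped_rows, paste, "", collapse = " "), paste0(stem, ".ped"))
  paste0(stem, ".ped")
}

test_that("the three genotype dialects produce identical matrices", {
  panel <- make_test_panel(3)
  set.seed(11)
  dos <- matrix(sample(c(0:2, NA), 15, TRUE), 5, 3,
                dimnames = list(sprintf("S%02d", 1:5), panel$snp_id))
  td <- withr::local_tempdir()
  write_genotype_vcf(dos, panel, file.path(td, "g.vcf"))
  write_dosage_tsv(dos, file.path(td, "g.tsv"))
  ped <- write_ped_map(dos, panel, file.path(td, "g"))

  g_vcf <- read_genotypes(file.path(td, "g.vcf"), "vcf", panel)
  g_tsv <- read_genotypes(file.path(td, "g.tsv"), "dosage_tsv", panel)
  g_ped <- read_genotypes(ped, "ped_map", panel)
  strip <- function(m) { attributes(m)[c("io_log", "n_ignored")] <- NULL; m }
  expect_identical(strip(g_vcf), strip(g_tsv))
  expect_identical(strip(g_vcf), strip(g_ped))
  expect_identical(unname(strip(g_vcf)), unname(dos))
})

test_that("dosage counts the risk allele whichever way the file orients it", {
  panel <- make_test_panel(1)   # risk A, other G
  td <- withr::local_tempdir()
  vcf <- file.path(td, "o.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"))
  # REF = risk allele: dosage must be 2 - ALT count
  writeLines(c(hdr, paste(c("1", "1000", "snp01", "A", "G", ".", "PASS", ".",
                            "GT", "0/0", "0/1", "1/1"), collapse = "\t")), vcf)
  g <- read_genotypes(vcf, "vcf", panel)
  expect_identical(unname(g[, 1]), c(2L, 1L, 0L))
  expect_identical(attr(g, "io_log")$status, "ok")
})

test_that("unambiguous strand flips are applied and logged", {
  panel <- make_test_panel(1)   # risk A, other G; file on the other strand: T/C
  td <- withr::local_tempdir()
  vcf <- file.path(td, "f.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"))
  writeLines(c(hdr, paste(c("1", "1000", "snp01", "C", "T", ".", "PASS", ".",
                            "GT", "0/1", "1/1"), collapse = "\t")), vcf)
  g <- read_genotypes(vcf, "vcf", panel)
  expect_identical(attr(g, "io_log")$status, "flipped")
  expect_identical(unname(g[, 1]), c(1L, 2L))
})

test_that("strand-ambiguous SNPs are flagged, not silently flipped", {
  panel <- make_test_panel(1)
  panel$risk_allele <- "A"; panel$other_allele <- "T"
  td <- withr::local_tempdir()
  vcf <- file.path(td, "a.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(hdr, paste(c("1", "1000", "snp01", "T", "A", ".", "PASS", ".",
                            "GT", "0/1"), collapse = "\t")), vcf)
  g <- read_genotypes(vcf, "vcf", panel)
  expect_identical(attr(g, "io_log")$status, "ambiguous")
  expect_true(all(is.na(g)))
  g2 <- read_genotypes(vcf, "vcf", panel, allow_ambiguous = TRUE)
  expect_identical(unname(g2[, 1]), 1L)
})

test_that("panel SNPs absent from the file become all-missing columns", {
  panel <- make_test_panel(3)
  set.seed(3)
  dos <- matrix(sample(0:2, 8, TRUE), 4, 2,
                dimnames = list(sprintf("S%d", 1:4), panel$snp_id[1:2]))
  td <- withr::local_tempdir()
  write_dosage_tsv(dos, file.path(td, "p.tsv"))
  g <- read_genotypes(file.path(td, "p.tsv"), "dosage_tsv", panel)
  expect_true(all(is.na(g[, 3])))
  expect_identical(attr(g, "io_log")$status, c("ok", "ok", "absent"))
})
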