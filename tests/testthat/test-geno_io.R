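test_that("PLINK write/read round-trips dosages, including missing calls", {
  sim <- small_sim(seed = 3, n = 30, m = 10)
  panel <- sim$panel
  panel$dosages[2, 5] <- NA  # one missing genotype
  panel <- dosage_panel(panel$dosages, panel$sample_ids, panel$variants)
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_identical(unname(back$dosages), unname(panel$dosages))
  expect_true(is.na(back$dosages[2, 5]))
  # freq computed over the 29 non-missing entries
  expect_equal(back$freq[5], mean(panel$dosages[-2, 5]) / 2)
  expect_equal(back$variants$pos, panel$variants$pos)
  expect_equal(back$variants$allele_effect, panel$variants$allele_effect)
})

test_that("truncated bed payload raises a format error", {
  sim <- small_sim(seed = 4, n = 12, m = 6)
  prefix <- file.path(withr::local_tempdir(), "trunc")
  write_plink(sim$panel, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "size mismatch")
})

test_that("VCF GT and DS fields are read as dosages", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT:DS\t0/1:1.37\t1/1:1.92",
    "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT:DS\t0/0:0.10\t./.:0.55"), vcf)
  gt <- read_vcf_dosages(vcf, field = "GT")
  expect_equal(unname(gt$dosages[, 1]), c(1, 2))
  expect_equal(unname(gt$dosages[1, 2]), 0)
  expect_true(is.na(gt$dosages[2, 2]))
  expect_equal(gt$variants$allele_effect, c("A", "C"))  # ALT is effect
  ds <- read_vcf_dosages(vcf, field = "DS")
  expect_equal(unname(ds$dosages[, 1]), c(1.37, 1.92))
})

test_that("multi-allelic VCF records are rejected", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta",
    "1\t100\trs1\tG\tA,C\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_vcf_dosages(vcf, "GT"), "multi-allelic")
})

test_that("summary tables log-transform OR, recompute p, drop se<=0", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "s.tsv")
  df <- data.frame(chr = c("1", "1", "2"), bp = c(10L, 20L, 30L),
                   ea = c("A", "C", "G"), oa = c("G", "T", "A"),
                   OR = c(1.38, 1.105, 0.9), SE = c(0.05, 0.05, 0),
                   EAF = c(0.3, 0.2, 0.1), N = 1000)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_message(
    ss <- read_summary_table(tsv, column_map = list(
      chrom = "chr", pos = "bp", allele_effect = "ea",
      allele_other = "oa", or = "OR", se = "SE", freq = "EAF",
      n = "N")),
    "dropping 1")
  expect_equal(nrow(ss), 2)
  expect_equal(ss$beta[1], log(1.38), tolerance = 1e-12)
  # beta/se = 2.0 -> two-sided normal p = 0.0455
  expect_equal(ss$z[2], log(1.105) / 0.05, tolerance = 1e-12)
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 1e-3)
  expect_equal(ss$p, 2 * pnorm(-abs(ss$z)))
})

test_that("harmonize flips swapped alleles, drops ambiguous, reports", {
  panel <- tiny_panel()  # effect alleles A (v1), C (v2)
  ws <- weight_set(variant_key(c("1", "1", "1"), c(100L, 200L, 300L),
                               c("G", "C", "A"), c("A", "T", "G")),
                   c(0.2, 0.5, 0.9))
  h <- harmonize(ws, panel)
  # v1 is allele-swapped: weight sign flips
  expect_equal(h$target$weight, c(-0.2, 0.5))
  expect_equal(h$target$allele_effect, c("A", "C"))
  expect_equal(h$report$n_flipped, 1)
  expect_equal(h$report$n_unmatched, 1)
  expect_equal(h$report$unmatched_keys, "1:300")
  # idempotence: harmonizing the aligned output changes nothing
  ws2 <- weight_set(h$target[, c("chrom", "pos", "allele_effect",
                                 "allele_other", "id")], h$target$weight)
  h2 <- harmonize(ws2, panel)
  expect_equal(h2$target$weight, h$target$weight)
  expect_equal(h2$report$n_flipped, 0)
})

test_that("strand-ambiguous variants are dropped only across datasets", {
  panel <- dosage_panel(rbind(c(1, 2), c(0, 1)), c("s1", "s2"),
                        variant_key(c("1", "1"), c(5L, 6L), c("A", "C"),
                                    c("T", "G")))
  ws <- weight_set(panel$variants, c(0.1, 0.2))
  h_drop <- harmonize(ws, panel, drop_ambiguous = TRUE)
  expect_equal(nrow(h_drop$target), 0)  # both A/T and C/G ambiguous
  expect_equal(h_drop$report$n_ambiguous_dropped, 2)
  h_keep <- harmonize(ws, panel, drop_ambiguous = FALSE)
  expect_equal(nrow(h_keep$target), 2)
})

test_that("weight files round-trip to 12 significant digits", {
  sim <- small_sim(seed = 5, n = 30, m = 100, block_size = 25)
  set.seed(9)
  ws <- weight_set(sim$panel$variants, rnorm(100) * exp(rnorm(100)))
  path <- file.path(withr::local_tempdir(), "w.tsv")
  write_weights(ws, path)
  back <- read_weights(path)
  expect_equal(back$weight, ws$weight, tolerance = 1e-11)
  expect_equal(back$pos, ws$pos)
  # duplicate row -> error
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_weights(path), "duplicate")
})

test_that("empty weight sets write a header-only file and read back", {
  vk <- variant_key(character(), integer(), character(), character())
  ws <- weight_set(vk, numeric())
  path <- file.path(withr::local_tempdir(), "empty.tsv")
  write_weights(ws, path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_weights(path)), 0)
})
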