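# PED/MAP input-output and the genotype container.

write_lines <- function(lines, path) { writeLines(lines, path); path }

test_that("PED allele pairs collapse to minor-allele counts and 0 0 is missing", {
  ped <- write_lines(c(
    "b1 s1 0 0 0 2 A A C C",
    "b1 s2 0 0 0 2 A G C C",
    "b2 s3 0 0 0 1 G G 0 0",
    "b2 s4 0 0 0 0 G G C T"),
    tempfile(fileext = ".ped"))
  map <- write_lines(c("chr1 snp1 0 100", "chr1 snp2 0 200"),
                     tempfile(fileext = ".map"))
  gd <- read_ped_map(ped, map)
  # snp1: A appears 3 times, G 5 times -> A minor
  expect_equal(unname(gd$calls[, 1]), c(2L, 1L, 0L, 0L))
  # snp2: T appears once -> minor; s3 missing
  expect_equal(unname(gd$calls[, 2]), c(0L, 0L, NA_integer_, 1L))
  expect_equal(gd$samples$status, c("case", "case", "control", NA))
  expect_equal(gd$samples$breed, c("b1", "b1", "b2", "b2"))
  expect_equal(gd$snps$position_bp, c(100L, 200L))
})

test_that("malformed PED/MAP inputs fail with informative errors", {
  map <- write_lines(c("chr1 snp1 0 100", "chr1 snp2 0 200"),
                     tempfile(fileext = ".map"))
  short <- write_lines("b1 s1 0 0 0 2 A A", tempfile(fileext = ".ped"))
  expect_error(read_ped_map(short, map), "row 1")
  tri <- write_lines(c("b1 s1 0 0 0 2 A A C C",
                       "b1 s2 0 0 0 1 G G C C",
                       "b1 s3 0 0 0 1 T T C C"),
                     tempfile(fileext = ".ped"))
  expect_error(read_ped_map(tri, map), "snp1")
  expect_error(read_ped_map("nope.ped", map), "not found")
})

test_that("write_ped_map followed by read_ped_map is the identity", {
  set.seed(41)
  for (rep in 1:20) {
    gd <- random_dataset(n_samples = sample(2:8, 1),
                         n_snps = sample(1:7, 1))
    ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
    write_ped_map(gd, ped, map)
    back <- read_ped_map(ped, map)
    expect_equal(back$calls, gd$calls)
    expect_equal(back$samples, gd$samples)
    expect_equal(back$snps, gd$snps)
  }
})

test_that("degenerate datasets round-trip: no samples, missing calls", {
  empty <- genotype_dataset(
    matrix(integer(0), 0, 2),
    samples = data.frame(sample_id = character(0), breed = character(0),
                         status = character(0)),
    snps = data.frame(snp_id = c("a", "b"), chromosome = "chr1",
                      position_bp = c(1L, 2L)))
  ped <- tempfile(); map <- tempfile()
  write_ped_map(empty, ped, map)
  expect_length(readLines(ped), 0)
  expect_length(readLines(map), 2)
  back <- read_ped_map(ped, map)
  expect_equal(dim(back), c(0L, 2L))
  expect_equal(back$snps$snp_id, c("a", "b"))

  onemiss <- genotype_dataset(
    matrix(c(1L, NA), 1, 2),
    samples = data.frame(sample_id = "s", breed = "b", status = "case"),
    snps = data.frame(snp_id = c("a", "b"), chromosome = "chr1",
                      position_bp = c(1L, 2L)))
  write_ped_map(onemiss, ped, map)
  expect_match(readLines(ped), "0 0$")
  expect_equal(read_ped_map(ped, map)$calls, onemiss$calls)
})

test_that("the container rejects inconsistent inputs", {
  smp <- data.frame(sample_id = "s1", breed = "b", status = "case")
  snp <- data.frame(snp_id = "a", chromosome = "chr1", position_bp = 1L)
  expect_error(genotype_dataset(matrix(3L, 1, 1), smp, snp), "0, 1, 2")
  expect_error(genotype_dataset(matrix(0L, 2, 1), smp, snp), "rows")
  snps2 <- data.frame(snp_id = c("a", "b"), chromosome = "chr1",
                      position_bp = c(5L, 2L))
  expect_error(genotype_dataset(matrix(0L, 1, 2), smp, snps2),
               "strictly increasing")
})

test_that("a SNP with MAF 0.04 is removed at maf_min 0.05", {
  calls <- cbind(c(1L, 1L, rep(0L, 23)), rep(c(0L, 1L, 2L), length.out = 25))
  gd <- genotype_dataset(
    calls,
    samples = data.frame(sample_id = paste0("s", 1:25), breed = "b",
                         status = rep(c("case", "control"), length.out = 25)),
    snps = data.frame(snp_id = c("rare", "common"), chromosome = "chr1",
                      position_bp = c(100L, 200L)))
  res <- apply_qc(gd, maf_min = 0.05, snp_callrate_min = 0,
                  sample_missing_max = 1)
  # rare: 2/50 = 0.04 -> removed; common stays
  expect_equal(res$dataset$snps$snp_id, "common")
  expect_equal(res$report$snps_removed_maf, 1)
})

test_that("QC removes monomorphic SNPs, poorly called samples, and reconciles", {
  # 10 samples x 4 SNPs: m1 monomorphic (MAF 0 -> removed by any
  # maf_min > 0), m2/m4 fine, m3 call rate 6/9 after sample filtering,
  # sample 10 has 3/4 missing (> 0.25 -> removed first)
  calls <- cbind(rep(0L, 10),
                 c(rep(1L, 5), rep(0L, 4), NA),
                 c(rep(NA, 3), rep(1L, 3), 0L, 0L, 1L, NA),
                 c(rep(c(0L, 1L, 2L), 3), NA))
  gd <- genotype_dataset(
    calls,
    samples = data.frame(sample_id = paste0("s", 1:10),
                         breed = "b",
                         status = rep(c("case", "control"), 5)),
    snps = data.frame(snp_id = paste0("m", 1:4), chromosome = "chr1",
                      position_bp = (1:4) * 100L))
  res <- apply_qc(gd, maf_min = 0.05, snp_callrate_min = 0.75,
                  sample_missing_max = 0.25)
  expect_equal(res$dataset$snps$snp_id, c("m2", "m4"))
  expect_equal(res$report$samples_removed_missingness, 1)
  expect_equal(res$report$snps_removed_callrate, 1)  # m3: 6/9 called
  expect_equal(res$report$snps_removed_maf, 1)       # m1
  expect_equal(res$report$samples_out, 9)
  # counts reconcile with shape deltas
  expect_equal(res$report$samples_in - res$report$samples_removed_missingness,
               nrow(res$dataset$calls))
  expect_equal(res$report$snps_in - res$report$snps_removed_callrate -
                 res$report$snps_removed_maf, ncol(res$dataset$calls))
})

test_that("QC with vacuous thresholds is the identity and QC is idempotent", {
  set.seed(7)
  gd <- random_dataset(n_samples = 12, n_snps = 10)
  res0 <- apply_qc(gd, maf_min = 0, snp_callrate_min = 0,
                   sample_missing_max = 1)
  expect_equal(res0$dataset$calls, gd$calls)

  res1 <- apply_qc(gd, 0.05, 0.75, 0.25)
  res2 <- apply_qc(res1$dataset, 0.05, 0.75, 0.25)
  expect_equal(res2$dataset$calls, res1$dataset$calls)
  expect_equal(res2$report$samples_removed_missingness, 0)
  expect_equal(res2$report$snps_removed_callrate +
                 res2$report$snps_removed_maf, 0)
})

test_that("QC failure modes raise hard errors", {
  gd <- genotype_dataset(
    matrix(c(NA, NA, 0L, 1L), 2, 2),
    samples = data.frame(sample_id = c("s1", "s2"), breed = "b",
                         status = c("case", "control")),
    snps = data.frame(snp_id = c("a", "b"), chromosome = "chr1",
                      position_bp = c(1L, 2L)))
  expect_error(apply_qc(gd, sample_missing_max = 0.1), "all samples")
  expect_error(apply_qc(gd, maf_min = 0.9, sample_missing_max = 1),
               "all SNPs")
  expect_error(apply_qc(gd, maf_min = 2), "fractions")
})
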