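# EM haplotype frequencies, four-gamete blocks, haplotype association.

test_that("EM equals direct gamete counting when phase is unambiguous", {
  # all homozygous: 3x BB/BB, 2x AA/AA at both SNPs
  g1 <- c(2, 2, 2, 0, 0); g2 <- c(2, 2, 2, 0, 0)
  f <- em_pair_frequencies(g1, g2)
  expect_equal(unname(f[c("AA", "BB")]), c(0.4, 0.6), tolerance = 1e-9)
  expect_equal(sum(f), 1)

  # single het at one SNP only: still phase-unambiguous
  f2 <- em_pair_frequencies(c(2, 1, 0), c(2, 2, 0))
  expect_equal(unname(f2["BB"]), 3 / 6, tolerance = 1e-9)
  expect_equal(unname(f2["AB"]), 1 / 6, tolerance = 1e-9)
  expect_equal(unname(f2["AA"]), 2 / 6, tolerance = 1e-9)

  expect_error(em_pair_frequencies(c(NA, NA), c(1, 1)), "no informative")
})

test_that("EM matches the brute-force likelihood maximizer on the 9+1 example", {
  g1 <- c(rep(2, 9), 1); g2 <- c(rep(2, 9), 1)
  f <- em_pair_frequencies(g1, g2)
  oracle <- oracle_pair_mle(cbind(g1, g2))
  expect_equal(as.vector(f), oracle, tolerance = 1e-4,
               ignore_attr = TRUE)
  # analytic check: double het resolves to AA/BB, giving f(AA) = 1/20
  expect_equal(unname(f["AA"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(f["BB"]), 0.95, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and frequencies normalized", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(8:25, 1)
    hf <- as.numeric(rmultinom(1, 40, runif(4, 0.1, 1))) / 40
    h <- sample(0:3, 2 * n, replace = TRUE, prob = hf)
    g1 <- (h[1:n] %% 2) + (h[(n + 1):(2 * n)] %% 2)
    g2 <- (h[1:n] %/% 2) + (h[(n + 1):(2 * n)] %/% 2)
    f <- em_pair_frequencies(g1, g2)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    ll <- attr(f, "loglik")
    expect_true(all(diff(ll) >= -1e-9))
  }
})

make_two_snp_dataset <- function(calls1, calls2) {
  n <- length(calls1)
  genotype_dataset(
    cbind(calls1, calls2),
    samples = data.frame(sample_id = paste0("s", 1:n), breed = "b",
                         status = rep(c("case", "control"), length.out = n)),
    snps = data.frame(snp_id = c("p", "q"), chromosome = "chr1",
                      position_bp = c(100L, 200L)))
}

test_that("four-gamete rule merges 3-gamete pairs and splits 4-gamete pairs", {
  # AB, Ab, aB present, ab absent: compatible -> one block
  # haplotype pairs drawn without any ab gamete
  h1 <- c(0, 0, 1, 1, 0, 1)  # SNP1 alleles of hap pairs per individual
  g1 <- c(2, 2, 1, 1, 0, 0)
  g2 <- c(2, 0, 2, 1, 2, 2)
  gd3 <- make_two_snp_dataset(g1, g2)
  b3 <- four_gamete_blocks(gd3, "chr1")
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_snps, 2)

  # all four haplotypes at 0.25 (phase-unambiguous individuals)
  g1 <- c(2, 2, 0, 0, 1, 1, 1, 1)
  g2 <- c(2, 0, 2, 0, 2, 2, 0, 0)
  gd4 <- make_two_snp_dataset(g1, g2)
  f <- em_pair_frequencies(g1, g2)
  expect_true(all(f > 0.1))
  b4 <- four_gamete_blocks(gd4, "chr1")
  expect_equal(nrow(b4), 2)
  expect_equal(b4$n_snps, c(1, 1))

  expect_error(four_gamete_blocks(gd4, "chrX"), "not in dataset")
})

test_that("block partition is a partition and matches the brute-force rule", {
  set.seed(61)
  for (i in 1:40) {
    gd <- random_dataset(n_samples = 20, n_snps = 10, n_chr = 1,
                         missing_rate = 0.05)
    blocks <- four_gamete_blocks(gd, "chr1")
    # partition: ordered, disjoint, covering
    expect_equal(blocks$start_index[1], 1)
    expect_equal(blocks$end_index[nrow(blocks)], 10)
    if (nrow(blocks) > 1)
      expect_equal(blocks$start_index[-1], blocks$end_index[-nrow(blocks)] + 1)
    oracle <- oracle_four_gamete_partition(gd, "chr1")
    expect_equal(blocks$start_index, oracle[, 1])
    expect_equal(blocks$end_index, oracle[, 2])
  }
})

test_that("block frequencies reduce to allele/direct counts in easy cases", {
  set.seed(71)
  gd <- random_dataset(n_samples = 15, n_snps = 4, n_chr = 1,
                       missing_rate = 0)
  # width-1 block: haplotype frequencies are allele frequencies
  blk <- block_haplotype_frequencies(gd, "chr1", 2, 2)
  p <- mean(gd$calls[, 2]) / 2
  expect_equal(blk$haplotypes$frequency[blk$haplotypes$haplotype == "B"],
               p, tolerance = 1e-9)

  # fully homozygous individuals: direct counting over 3 SNPs
  calls <- matrix(c(2, 2, 0, 2, 2, 0, 2, 0, 0), 3, 3)
  gdh <- genotype_dataset(
    calls,
    samples = data.frame(sample_id = paste0("s", 1:3), breed = "b",
                         status = c("case", "control", "control")),
    snps = data.frame(snp_id = paste0("m", 1:3), chromosome = "chr1",
                      position_bp = c(1L, 2L, 3L) * 10L))
  blkh <- block_haplotype_frequencies(gdh, "chr1", 1, 3)
  got <- blkh$haplotypes
  expect_equal(got$frequency[got$haplotype == "BBB"], 1 / 3)
  expect_equal(got$frequency[got$haplotype == "BBA"], 1 / 3)
  expect_equal(got$frequency[got$haplotype == "AAA"], 1 / 3)

  expect_error(block_haplotype_frequencies(gd, "chr1", 1, 4, max_width = 3),
               "subdivide")
})

test_that("3-SNP block with one double heterozygote matches direct maximization", {
  # 5 individuals: four homozygous BBB or AAA, one het at SNPs 1 and 3
  calls <- rbind(c(2, 2, 2), c(2, 2, 2), c(0, 0, 0), c(0, 0, 0),
                 c(1, 2, 1))
  gd <- genotype_dataset(
    calls,
    samples = data.frame(sample_id = paste0("s", 1:5), breed = "b",
                         status = rep(c("case", "control"), length.out = 5)),
    snps = data.frame(snp_id = paste0("m", 1:3), chromosome = "chr1",
                      position_bp = c(10L, 20L, 30L)))
  blk <- block_haplotype_frequencies(gd, "chr1", 1, 3)
  got <- blk$haplotypes
  # the het must resolve BxB/AxA with middle allele B on both, i.e.
  # haplotypes BBB and ABA; BBB rides with the 4 homozygote BBBs
  expect_equal(got$frequency[got$haplotype == "BBB"], 5 / 10,
               tolerance = 1e-6)
  expect_equal(got$frequency[got$haplotype == "ABA"], 1 / 10,
               tolerance = 1e-6)
  expect_equal(got$frequency[got$haplotype == "AAA"], 4 / 10,
               tolerance = 1e-6)
})

test_that("a case-only homozygous haplotype tops the chromosome-wide scan", {
  # cases carry BBB homozygously; controls carry AAA or AAB, so the
  # four-gamete rule keeps the three SNPs in one block and BBB is
  # case-exclusive
  calls <- rbind(matrix(2L, 4, 3),
                 rbind(c(0, 0, 0), c(0, 0, 0),
                       c(0, 0, 2), c(0, 0, 2), c(0, 0, 2), c(0, 0, 2)))
  gd <- genotype_dataset(
    calls,
    samples = data.frame(sample_id = paste0("s", 1:10),
                         breed = rep(c("bc", "bu"), c(4, 6)),
                         status = rep(c("case", "control"), c(4, 6))),
    snps = data.frame(snp_id = paste0("m", 1:3), chromosome = "chr1",
                      position_bp = c(10L, 20L, 30L)))
  hs <- haplotype_scan(gd, "chr1", n_permutations = 300, seed = 2)
  ht <- hs$haplotype_tests
  top <- ht[which.max(ht$chi2), ]
  expect_equal(top$haplotype, "BBB")
  all_stats <- c(hs$snp_tests$chi2, ht$chi2)
  expect_equal(max(all_stats), top$chi2)

  hs2 <- haplotype_scan(gd, "chr1", n_permutations = 300, seed = 2)
  expect_identical(hs$haplotype_tests$p_chromosome,
                   hs2$haplotype_tests$p_chromosome)

  # the single-block wrapper returns that block's tests with the same
  # chromosome-wide correction
  ha <- haplotype_association(gd, "chr1", 1, 3, n_permutations = 300,
                              seed = 2)
  expect_equal(ha$chi2, hs$haplotype_tests$chi2)
  expect_equal(ha$p_chromosome, hs$haplotype_tests$p_chromosome)
})
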