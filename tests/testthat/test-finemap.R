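# Homozygous runs per breed and the shared critical interval.

region_dataset <- function(calls, breeds, status = NULL, spacing = 10000L) {
  n <- nrow(calls); m <- ncol(calls)
  genotype_dataset(
    calls,
    samples = data.frame(
      sample_id = paste0(breeds, "_", seq_len(n)),
      breed = breeds,
      status = status %||% rep("case", n)),
    snps = data.frame(snp_id = paste0("r", seq_len(m)),
                      chromosome = "chr1",
                      position_bp = seq_len(m) * spacing))
}

test_that("runs extend over homozygous-identical SNPs and stop at heterozygotes", {
  # 3 dogs homozygous-identical at SNPs 4..9, heterozygous at 3 and 10
  calls <- matrix(0L, 3, 12)
  calls[, 4:9] <- 2L
  calls[, 3] <- 1L
  calls[, 10] <- 1L
  gd <- region_dataset(calls, rep("pug", 3))
  run <- breed_homozygous_run(gd, "pug", "r6")
  expect_equal(run$snp_ids, paste0("r", 4:9))
  expect_equal(run$haplotype, "BBBBBB")
  expect_equal(run$n_individuals, 3)

  # a single fully homozygous dog spans the whole region
  solo <- region_dataset(matrix(2L, 1, 12), "boxer")
  run2 <- breed_homozygous_run(solo, "boxer", "r6")
  expect_equal(length(run2$snp_index), 12)

  # discordant homozygotes break the run like heterozygotes do
  calls3 <- matrix(2L, 2, 12)
  calls3[1, 10] <- 0L
  gd3 <- region_dataset(calls3, rep("chin", 2))
  run3 <- breed_homozygous_run(gd3, "chin", "r6")
  expect_equal(range(run3$snp_index), c(1, 9))
  # ...but are tolerated under a nonzero max_het_fraction
  run3b <- breed_homozygous_run(gd3, "chin", "r6", max_het_fraction = 0.5)
  expect_equal(range(run3b$snp_index), c(1, 12))
})

test_that("missing calls do not break a run but an uncalled SNP ends it", {
  calls <- matrix(2L, 2, 12)
  calls[1, 6] <- NA                    # partial missing: run continues
  calls[, 10] <- NA                    # nobody called: run cannot pass
  gd <- region_dataset(calls, rep("peke", 2))
  run <- breed_homozygous_run(gd, "peke", "r4")
  expect_equal(range(run$snp_index), c(1, 9))
  expect_error(breed_homozygous_run(gd, "peke", "r10"), "missing in every")
  expect_error(breed_homozygous_run(gd, "none", "r4"), "no individuals")
})

test_that("overlap interval is the concordant intersection of the runs", {
  # three breeds with runs [10,60], [30,90], [40,70] (kb scale via 10 kb
  # spacing -> SNPs 1..6, 3..9, 4..7), all sharing the B haplotype
  calls <- rbind(
    c(2, 2, 2, 2, 2, 2, 1, 0, 0, 0, 0, 0),
    c(0, 1, 2, 2, 2, 2, 2, 2, 2, 1, 0, 0),
    c(0, 0, 1, 2, 2, 2, 2, 1, 0, 0, 0, 0))
  gd <- region_dataset(calls, c("b1", "b2", "b3"))
  runs <- lapply(c("b1", "b2", "b3"), function(b)
    breed_homozygous_run(gd, b, "r5"))
  expect_equal(runs[[1]]$start_bp, 10000)
  expect_equal(runs[[1]]$end_bp, 60000)
  expect_equal(runs[[2]]$start_bp, 30000)
  expect_equal(runs[[2]]$end_bp, 90000)
  iv <- overlap_interval(runs)
  expect_equal(iv$start_bp, 40000)
  expect_equal(iv$end_bp, 60000)
  expect_equal(iv$haplotype, "BBB")

  # idempotence: two identical runs give back the run
  iv2 <- overlap_interval(runs[c(1, 1)])
  expect_equal(iv2$start_bp, runs[[1]]$start_bp)
  expect_equal(iv2$end_bp, runs[[1]]$end_bp)

  # order invariance and monotonicity
  iv3 <- overlap_interval(rev(runs))
  expect_equal(iv3$start_bp, iv$start_bp)
  expect_equal(iv3$end_bp, iv$end_bp)
  iv12 <- overlap_interval(runs[1:2])
  expect_true(iv$start_bp >= iv12$start_bp && iv$end_bp <= iv12$end_bp)

  expect_error(overlap_interval(runs[1]), "at least 2")
})

test_that("allele discordance truncates or voids the shared interval", {
  # two breeds homozygous everywhere but for opposite alleles at SNP 8
  calls <- rbind(rep(2L, 12),
                 c(rep(2L, 7), 0L, rep(2L, 4)))
  gd <- region_dataset(calls, c("b1", "b2"))
  runs <- lapply(c("b1", "b2"), function(b)
    breed_homozygous_run(gd, b, "r4"))
  iv <- overlap_interval(runs)
  expect_equal(range(iv$snp_index), c(1, 7))

  # discordant at the anchor: no shared haplotype
  calls2 <- rbind(rep(2L, 5), rep(0L, 5))
  gd2 <- region_dataset(calls2, c("b1", "b2"))
  runs2 <- lapply(c("b1", "b2"), function(b)
    breed_homozygous_run(gd2, b, "r3"))
  expect_error(overlap_interval(runs2), "no shared haplotype")
})

test_that("breeds on a different anchor haplotype form a separate group", {
  # b1, b2 share the B haplotype; b3 is homozygous A at the anchor and
  # b4 has no genotype there
  calls <- rbind(rep(2L, 8),
                 c(0L, rep(2L, 6), 0L),
                 rep(0L, 8),
                 c(2L, 2L, 2L, NA, 2L, 2L, 2L, 2L))
  gd <- region_dataset(calls, c("b1", "b2", "b3", "b4"))
  fm <- finemap_case_breeds(gd, c("b1", "b2", "b3", "b4"), "r4")
  expect_setequal(names(fm$runs), c("b1", "b2"))
  expect_match(fm$excluded$b3, "minority allele")
  expect_match(fm$excluded$b4, "missing in every")
  expect_equal(range(fm$interval$snp_index), c(2, 7))

  # with everyone discordant or absent the stage fails loudly
  expect_error(finemap_case_breeds(gd, c("b3", "b4"), "r4"),
               "fewer than 2")
})

test_that("fine mapping recovers the planted IBD core from simulation", {
  sim <- simulate_breeds(default_scenario(seed = 404))
  tr <- sim$truth
  runs <- lapply(tr$affected_breeds, function(b)
    breed_homozygous_run(sim$dataset, b, tr$causal_snp_id))
  for (r in runs) {
    expect_true(r$start_bp <= tr$causal_position_bp)
    expect_true(r$end_bp >= tr$causal_position_bp)
  }
  iv <- overlap_interval(runs)
  expect_true(iv$start_bp <= tr$causal_position_bp &&
                tr$causal_position_bp <= iv$end_bp)
  # intersection across 9 breeds cannot exceed the planted (pre-erosion)
  # core plus one flanking SNP on either side (runs may extend into
  # coincidentally shared flanks, but rarely across all nine breeds)
  expect_lte(iv$width_bp, (tr$core_end_bp - tr$core_start_bp) * 1.5)
})

test_that("more breeds give a weakly narrower interval on simulation", {
  widths <- sapply(c(3, 9), function(k) {
    mean(sapply(1:5, function(s) {
      sim <- simulate_breeds(default_scenario(seed = 600 + s))
      tr <- sim$truth
      runs <- lapply(tr$affected_breeds[seq_len(k)], function(b)
        breed_homozygous_run(sim$dataset, b, tr$causal_snp_id))
      overlap_interval(runs)$width_bp
    }))
  })
  expect_lte(widths[2], widths[1])
})
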