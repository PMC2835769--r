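# Shared fixtures and independent oracles used across the suite.

# Random small genotype dataset.  Counted alleles are kept at pooled
# frequency <= 0.5 so that PED round-trips reproduce the counts exactly.
random_dataset <- function(n_samples = 8, n_snps = 6, n_chr = 2,
                           missing_rate = 0.1, maf = NULL) {
  m_per <- ceiling(n_snps / n_chr)
  chroms <- rep(paste0("chr", seq_len(n_chr)), each = m_per)[seq_len(n_snps)]
  pos <- unlist(lapply(unique(chroms), function(ch)
    sort(sample.int(1e6, sum(chroms == ch)))))
  calls <- matrix(NA_integer_, n_samples, n_snps)
  for (j in seq_len(n_snps)) {
    p <- maf %||% runif(1, 0.05, 0.5)
    repeat {
      g <- rbinom(n_samples, 2, p)
      g[runif(n_samples) < missing_rate] <- NA
      cnt <- sum(g, na.rm = TRUE); tot <- 2 * sum(!is.na(g))
      if (tot == 0 || cnt / tot <= 0.5) break
    }
    calls[, j] <- g
  }
  status <- rep(c("case", "control"), length.out = n_samples)
  genotype_dataset(
    calls,
    samples = data.frame(sample_id = paste0("s", seq_len(n_samples)),
                         breed = paste0("b", rep(1:2, length.out = n_samples)),
                         status = status),
    snps = data.frame(snp_id = paste0("snp", seq_len(n_snps)),
                      chromosome = chroms, position_bp = pos))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent chi-square oracle: stats::chisq.test without continuity
# correction on the 2x2 allele table.
oracle_chi2 <- function(case_alleles, control_alleles) {
  tab <- rbind(case_alleles, control_alleles)
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

# --- two-locus haplotype likelihood oracle --------------------------------
# Haplotype order: AA, BA, AB, BB (as em_pair_frequencies).  Compatible
# ordered haplotype pairs found by brute force over all 16 combinations.
oracle_pair_loglik <- function(f, geno) {
  bit1 <- c(0, 1, 0, 1); bit2 <- c(0, 0, 1, 1)
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    p <- 0
    for (h in 1:4) for (k in 1:4) {
      if (bit1[h] + bit1[k] == geno[i, 1] && bit2[h] + bit2[k] == geno[i, 2])
        p <- p + f[h] * f[k]
    }
    ll <- ll + log(max(p, 1e-300))
  }
  ll
}

# Compatible ordered haplotype pairs per two-SNP genotype class, found by
# brute force over all 16 combinations (class key "g1g2").
oracle_pair_table <- local({
  bit1 <- c(0, 1, 0, 1); bit2 <- c(0, 0, 1, 1)
  tabs <- list()
  for (g1 in 0:2) for (g2 in 0:2) {
    pairs <- NULL
    for (h in 1:4) for (k in 1:4) {
      if (bit1[h] + bit1[k] == g1 && bit2[h] + bit2[k] == g2)
        pairs <- rbind(pairs, c(h, k))
    }
    tabs[[paste0(g1, g2)]] <- pairs
  }
  tabs
})

# Grid search over the frequency simplex (step `by`), refined with
# Nelder-Mead on softmax coordinates.  Independent of the EM.
oracle_pair_mle <- function(geno, by = 0.025) {
  counts <- table(paste0(geno[, 1], geno[, 2]))
  # all simplex grid points
  s <- seq(0, 1, by = by)
  grid <- expand.grid(f1 = s, f2 = s, f3 = s)
  grid <- grid[rowSums(grid) <= 1 + 1e-12, ]
  F <- cbind(grid$f1, grid$f2, grid$f3, pmax(0, 1 - rowSums(grid)))
  ll <- numeric(nrow(F))
  for (cls in names(counts)) {
    pairs <- oracle_pair_table[[cls]]
    P <- rowSums(vapply(seq_len(nrow(pairs)), function(r)
      F[, pairs[r, 1]] * F[, pairs[r, 2]], numeric(nrow(F))))
    ll <- ll + counts[[cls]] * log(pmax(P, 1e-300))
  }
  best <- F[which.max(ll), ]
  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
  obj <- function(x) -oracle_pair_loglik(softmax(c(0, x)), geno)
  start <- log(pmax(best, 1e-6)); start <- start - start[1]
  opt <- stats::optim(start[-1], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  softmax(c(0, opt$par))
}

# Brute-force four-gamete block partition: an independent re-implementation
# of the pair rule on top of em_pair_frequencies.
oracle_four_gamete_partition <- function(dataset, chromosome,
                                         freq_threshold = 0.01) {
  idx <- which(dataset$snps$chromosome == chromosome)
  m <- length(idx)
  compat <- vapply(seq_len(m - 1), function(j) {
    f <- tryCatch(em_pair_frequencies(dataset$calls[, idx[j]],
                                      dataset$calls[, idx[j + 1]]),
                  error = function(e) NULL)
    is.null(f) || sum(f >= freq_threshold) < 4
  }, TRUE)
  blocks <- list()
  start <- 1
  for (j in seq_len(m - 1)) {
    if (!compat[j]) { blocks[[length(blocks) + 1]] <- c(start, j); start <- j + 1 }
  }
  blocks[[length(blocks) + 1]] <- c(start, m)
  do.call(rbind, blocks)
}

# Tiny dataset with a single perfectly separating SNP.
perfect_split_dataset <- function() {
  genotype_dataset(
    calls = matrix(c(2L, 2L, 0L, 0L,
                     1L, 0L, 1L, 0L), ncol = 2),
    samples = data.frame(sample_id = paste0("s", 1:4),
                         breed = c("b1", "b1", "b2", "b2"),
                         status = c("case", "case", "control", "control")),
    snps = data.frame(snp_id = c("hit", "noise"),
                      chromosome = c("chr1", "chr2"),
                      position_bp = c(100L, 100L)))
}
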