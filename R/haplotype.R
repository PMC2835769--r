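# Haplotype-block analysis: EM frequency estimation from unphased
# genotypes, four-gamete-rule block partitioning, and haplotype-vs-rest
# association with chromosome-wide max-statistic permutation.

# Haplotypes over k SNPs are encoded as integers 0 .. 2^k - 1; bit j-1 is
# the allele at SNP j (0 = major "A", 1 = minor "B").

hap_to_string <- function(h, k) {
  bits <- bitwAnd(rep(h, each = k) %/% rep(2L^(0:(k - 1L)), length(h)), 1L)
  apply(matrix(c("A", "B")[bits + 1L], nrow = k), 2, paste, collapse = "")
}

# Enumerate the unordered haplotype pairs compatible with one multilocus
# genotype (vector over {0,1,2}, no NA).  Returns a 2-column integer
# matrix of haplotype codes.
compatible_pairs <- function(geno) {
  k <- length(geno)
  pow <- 2L^(0:(k - 1L))
  base <- sum(pow[geno == 2L])           # minor allele on both haplotypes
  het <- which(geno == 1L)
  t <- length(het)
  if (t == 0L) return(matrix(c(base, base), ncol = 2L))
  hetmask <- sum(pow[het])
  # fix the first het site's allele on haplotype 1 to avoid double counting
  free <- het[-1L]
  n_pairs <- 2L^(t - 1L)
  h1 <- rep(base, n_pairs)
  if (t > 1L) {
    combos <- as.matrix(expand.grid(rep(list(0:1), t - 1L)))
    h1 <- h1 + as.vector(combos %*% pow[free])
  }
  h2 <- bitwXor(h1, hetmask)
  cbind(h1, h2)
}

# Core EM for haplotype frequencies over k <= 30 SNPs from unphased
# genotypes.  `geno` is an n x k matrix over {0,1,2} with no missing
# values (callers drop incomplete individuals).  Returns frequencies over
# the compatible haplotype set, plus the log-likelihood trace.
em_haplotypes <- function(geno, tol = 1e-8, max_iter = 1000L) {
  n <- nrow(geno); k <- ncol(geno)
  if (n == 0L) stopf("no informative pairs: no complete individuals")
  # collapse identical genotypes
  key <- apply(geno, 1, paste, collapse = "")
  tab <- table(key)
  uniq <- match(names(tab), key)
  counts <- as.numeric(tab)
  pair_list <- lapply(uniq, function(i) compatible_pairs(geno[i, ]))
  haps <- sort(unique(unlist(pair_list)))
  hidx <- function(h) match(h, haps)

  # linkage-equilibrium start restricted to the compatible set
  p <- colMeans(geno) / 2
  le_freq <- function(h) {
    bits <- bitwAnd(h %/% 2L^(0:(k - 1L)), 1L)
    prod(ifelse(bits == 1L, p, 1 - p))
  }
  f <- vapply(haps, le_freq, 0)
  if (sum(f) <= 0) f <- rep(1, length(haps))
  f <- f / sum(f)

  N2 <- 2 * sum(counts)
  loglik <- numeric(0)
  for (iter in seq_len(max_iter)) {
    expected <- numeric(length(haps))
    ll <- 0
    for (g in seq_along(pair_list)) {
      pr <- pair_list[[g]]
      i1 <- hidx(pr[, 1]); i2 <- hidx(pr[, 2])
      w <- ifelse(pr[, 1] == pr[, 2], f[i1] * f[i2], 2 * f[i1] * f[i2])
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / length(w), length(w)); tot <- 1e-300 }
      post <- counts[g] * w / sum(w)
      for (r in seq_along(post)) {
        expected[i1[r]] <- expected[i1[r]] + post[r]
        expected[i2[r]] <- expected[i2[r]] + post[r]
      }
      ll <- ll + counts[g] * log(tot)
    }
    loglik <- c(loglik, ll)
    f_new <- expected / N2
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  list(haplotypes = haps, freq = f, k = k, n = n, loglik = loglik,
       iterations = length(loglik))
}

# Posterior expected haplotype dosage per individual given EM frequencies.
# Returns an n x length(haps) matrix (rows for individuals with missing
# genotypes are all zero).
em_dosage <- function(geno_full, fit) {
  n <- nrow(geno_full)
  D <- matrix(0, n, length(fit$haplotypes))
  complete <- which(rowSums(is.na(geno_full)) == 0L)
  for (i in complete) {
    pr <- compatible_pairs(geno_full[i, ])
    i1 <- match(pr[, 1], fit$haplotypes)
    i2 <- match(pr[, 2], fit$haplotypes)
    ok <- !is.na(i1) & !is.na(i2)
    if (!any(ok)) next
    i1 <- i1[ok]; i2 <- i2[ok]
    w <- ifelse(i1 == i2, fit$freq[i1] * fit$freq[i2],
                2 * fit$freq[i1] * fit$freq[i2])
    if (sum(w) <= 0) w <- rep(1, length(w))
    w <- w / sum(w)
    for (r in seq_along(w)) {
      D[i, i1[r]] <- D[i, i1[r]] + w[r]
      D[i, i2[r]] <- D[i, i2[r]] + w[r]
    }
  }
  D
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four two-SNP haplotype frequencies from unphased
#' genotype counts.  Double heterozygotes contribute a mixture of their
#' two phase resolutions; the EM starts from linkage equilibrium and
#' iterates until the largest frequency change is below \code{tol}.
#'
#' @param calls_snp1,calls_snp2 integer vectors over \code{c(0,1,2,NA)}
#'   (minor-allele counts); individuals missing either call are dropped.
#' @param tol convergence tolerance on frequencies.
#' @param max_iter iteration cap.
#' @return Named numeric vector of frequencies for haplotypes
#'   \code{AA, BA, AB, BB} (first letter = SNP 1 allele, A = major,
#'   B = minor), summing to 1.  Attribute \code{loglik} holds the
#'   log-likelihood trace.
#' @examples
#' em_pair_frequencies(c(0, 0, 2, 2), c(0, 0, 2, 2))
#' @export
em_pair_frequencies <- function(calls_snp1, calls_snp2, tol = 1e-8,
                                max_iter = 1000L) {
  geno <- cbind(calls_snp1, calls_snp2)
  geno <- geno[stats::complete.cases(geno), , drop = FALSE]
  if (nrow(geno) == 0L) stopf("no informative pairs")
  storage.mode(geno) <- "integer"
  fit <- em_haplotypes(geno, tol = tol, max_iter = max_iter)
  out <- numeric(4)
  names(out) <- hap_to_string(0:3, 2L)  # AA BA AB BB
  out[fit$haplotypes + 1L] <- fit$freq
  attr(out, "loglik") <- fit$loglik
  out
}

#' Partition a chromosome into haplotype blocks by the four-gamete rule
#'
#' Consecutive SNP pairs are declared compatible when fewer than four of
#' their EM-estimated two-locus haplotypes reach frequency
#' \code{freq_threshold} (observing all four gametes is evidence of
#' historical recombination).  Maximal runs of pairwise-compatible
#' consecutive SNPs form blocks; SNPs compatible with neither neighbour
#' form singleton blocks.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param chromosome chromosome label.
#' @param freq_threshold minimum frequency for a gamete to count as
#'   observed (default 0.01).
#' @return A data frame with one row per block: \code{chromosome},
#'   \code{start_index}, \code{end_index} (positions in the chromosome's
#'   SNP list), \code{start_bp}, \code{end_bp}, \code{n_snps}.
#' @export
four_gamete_blocks <- function(dataset, chromosome, freq_threshold = 0.01) {
  idx <- chromosome_snps(dataset, chromosome)
  m <- length(idx)
  if (m < 2L) {
    return(data.frame(chromosome = chromosome, start_index = 1L,
                      end_index = 1L,
                      start_bp = dataset$snps$position_bp[idx],
                      end_bp = dataset$snps$position_bp[idx],
                      n_snps = 1L, stringsAsFactors = FALSE))
  }
  compatible <- logical(m - 1L)
  for (j in seq_len(m - 1L)) {
    f <- tryCatch(
      em_pair_frequencies(dataset$calls[, idx[j]],
                          dataset$calls[, idx[j + 1L]]),
      error = function(e) NULL)
    # pairs with no jointly observed individuals give no recombination
    # evidence; treat as compatible
    compatible[j] <- is.null(f) || sum(f >= freq_threshold) < 4L
  }
  breaks <- which(!compatible)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, m)
  pos <- dataset$snps$position_bp[idx]
  data.frame(chromosome = chromosome, start_index = starts,
             end_index = ends, start_bp = pos[starts], end_bp = pos[ends],
             n_snps = ends - starts + 1L, stringsAsFactors = FALSE)
}

#' Haplotype frequencies within a block
#'
#' Runs the EM over all haplotypes consistent with each individual's
#' multilocus genotype in the block.  Individuals missing any SNP in the
#' block are excluded.  Haplotypes with estimated frequency below
#' \code{prune_below} are pruned from the output.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param chromosome chromosome label.
#' @param start_index,end_index inclusive indices into the chromosome's
#'   SNP list.
#' @param max_width widest block the EM will attempt (default 12 SNPs);
#'   wider blocks must be subdivided by the caller.
#' @param prune_below frequency below which haplotypes are dropped from
#'   the output.
#' @return An object of class \code{haplotype_block}: list with
#'   \code{chromosome}, \code{snp_ids}, \code{start_bp}, \code{end_bp},
#'   \code{haplotypes} (data frame of allele strings over \{A,B\} and
#'   frequencies), \code{n_used}, and the EM fit.
#' @export
block_haplotype_frequencies <- function(dataset, chromosome, start_index,
                                        end_index, max_width = 12L,
                                        prune_below = 1e-4) {
  idx <- chromosome_snps(dataset, chromosome)
  if (start_index < 1L || end_index > length(idx) || start_index > end_index)
    stopf("invalid block span [%d, %d] on %s (%d SNPs)",
          start_index, end_index, chromosome, length(idx))
  span <- idx[start_index:end_index]
  k <- length(span)
  if (k > max_width)
    stopf("block of %d SNPs exceeds max_width = %d; subdivide the block",
          k, max_width)
  geno <- dataset$calls[, span, drop = FALSE]
  complete <- stats::complete.cases(geno)
  if (!any(complete)) stopf("no individuals fully genotyped in block")
  fit <- em_haplotypes(geno[complete, , drop = FALSE])
  keep <- fit$freq >= prune_below
  haps <- data.frame(
    haplotype = hap_to_string(fit$haplotypes[keep], k),
    frequency = fit$freq[keep],
    stringsAsFactors = FALSE)
  haps <- haps[order(-haps$frequency), ]
  rownames(haps) <- NULL
  structure(list(chromosome = chromosome,
                 start_index = start_index, end_index = end_index,
                 snp_ids = dataset$snps$snp_id[span],
                 start_bp = dataset$snps$position_bp[span[1]],
                 end_bp = dataset$snps$position_bp[span[k]],
                 haplotypes = haps, n_used = sum(complete), fit = fit,
                 snp_cols = span),
            class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("haplotype_block %s:%d-%d (%d SNPs, %d individuals)\n",
              x$chromosome, x$start_bp, x$end_bp, length(x$snp_ids),
              x$n_used))
  print(x$haplotypes)
  invisible(x)
}

# Build dosage/inclusion columns for every haplotype (freq >= min_freq) of
# one block, using pooled-EM posterior phase probabilities.
block_test_matrices <- function(dataset, block, min_freq = 0.01) {
  geno <- dataset$calls[, block$snp_cols, drop = FALSE]
  Dall <- em_dosage(geno, block$fit)
  complete <- as.numeric(stats::complete.cases(geno))
  keep <- which(block$fit$freq >= min_freq)
  if (length(keep) == 0L) return(NULL)
  D <- Dall[, keep, drop = FALSE]
  U <- matrix(complete, nrow(D), length(keep))
  list(D = D, U = U,
       haplotype = hap_to_string(block$fit$haplotypes[keep],
                                 length(block$snp_cols)),
       frequency = block$fit$freq[keep])
}

#' Chromosome-wide SNP and haplotype association with permutation
#'
#' Partitions one chromosome into four-gamete blocks, estimates block
#' haplotype frequencies by EM, and tests every SNP (allelic chi-square)
#' and every common haplotype (haplotype-vs-all-others chi-square on
#' EM-posterior fractional haplotype counts in cases and controls).
#' Corrected p-values (\code{p_chromosome}) compare each statistic with
#' the chromosome-wide maximum over all SNP and haplotype tests under
#' case/control label permutation.
#'
#' Blocks wider than \code{max_width} SNPs are split into consecutive
#' chunks of at most \code{max_width} for frequency estimation and
#' testing.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param chromosome chromosome label.
#' @param n_permutations number of permutations (default 50,000).
#' @param seed integer seed.
#' @param freq_threshold four-gamete "observed" frequency cutoff.
#' @param min_hap_freq only haplotypes at or above this frequency are
#'   tested (default 0.01).
#' @param max_width EM width cap per block.
#' @param mode permutation mode as in \code{\link{maxT_permutation}}.
#' @return A list of class \code{haplotype_scan}: \code{blocks} (block
#'   partition), \code{snp_tests} and \code{haplotype_tests} data frames
#'   with \code{chi2}, \code{p_raw}, \code{p_chromosome}.
#' @export
haplotype_scan <- function(dataset, chromosome, n_permutations = 50000L,
                           seed = 1L, freq_threshold = 0.01,
                           min_hap_freq = 0.01, max_width = 12L,
                           mode = "auto") {
  z <- case_indicator(dataset)
  blocks <- four_gamete_blocks(dataset, chromosome, freq_threshold)
  idx <- chromosome_snps(dataset, chromosome)

  snp_mats <- snp_test_matrices(dataset, idx)
  hapD <- NULL; hapU <- NULL
  hap_meta <- list()
  for (b in seq_len(nrow(blocks))) {
    s <- blocks$start_index[b]; e <- blocks$end_index[b]
    chunk_starts <- seq(s, e, by = max_width)
    for (cs in chunk_starts) {
      ce <- min(cs + max_width - 1L, e)
      blk <- block_haplotype_frequencies(dataset, chromosome, cs, ce,
                                         max_width = max_width)
      bm <- block_test_matrices(dataset, blk, min_hap_freq)
      if (is.null(bm)) next
      hapD <- cbind(hapD, bm$D)
      hapU <- cbind(hapU, bm$U)
      hap_meta[[length(hap_meta) + 1L]] <- data.frame(
        block = b, chromosome = chromosome,
        start_bp = blk$start_bp, end_bp = blk$end_bp,
        haplotype = bm$haplotype, frequency = bm$frequency,
        stringsAsFactors = FALSE)
    }
  }
  n_hap <- if (is.null(hapD)) 0L else ncol(hapD)
  D <- cbind(snp_mats$D, hapD)
  U <- cbind(snp_mats$U, hapU)
  eng <- maxT_engine(D, U, z, n_permutations, seed, mode)

  m <- length(idx)
  snp_tests <- data.frame(
    snp_id = dataset$snps$snp_id[idx],
    chromosome = chromosome,
    position_bp = dataset$snps$position_bp[idx],
    chi2 = eng$chi2[seq_len(m)],
    p_raw = stats::pchisq(eng$chi2[seq_len(m)], 1, lower.tail = FALSE),
    p_chromosome = eng$p_corrected[seq_len(m)],
    stringsAsFactors = FALSE)
  hap_tests <- if (n_hap > 0L) {
    ht <- do.call(rbind, hap_meta)
    ht$chi2 <- eng$chi2[m + seq_len(n_hap)]
    ht$p_raw <- stats::pchisq(ht$chi2, 1, lower.tail = FALSE)
    ht$p_chromosome <- eng$p_corrected[m + seq_len(n_hap)]
    ht
  } else {
    data.frame()
  }
  structure(list(chromosome = chromosome, blocks = blocks,
                 snp_tests = snp_tests, haplotype_tests = hap_tests,
                 n_permutations = eng$n_permutations,
                 exhaustive = eng$exhaustive, seed = seed),
            class = "haplotype_scan")
}

#' Association tests for a single haplotype block
#'
#' Convenience wrapper: estimates the block's haplotype frequencies and
#' returns its haplotype tests from a chromosome-wide
#' \code{\link{haplotype_scan}} (the corrected p-value is always relative
#' to the chromosome-wide maximum statistic, as block-level correction
#' alone would understate multiplicity).
#'
#' @inheritParams haplotype_scan
#' @param start_index,end_index block span (indices into the chromosome's
#'   SNP list).
#' @return The rows of the scan's \code{haplotype_tests} falling inside
#'   the requested span.
#' @export
haplotype_association <- function(dataset, chromosome, start_index,
                                  end_index, n_permutations = 50000L,
                                  seed = 1L, mode = "auto") {
  scan <- haplotype_scan(dataset, chromosome, n_permutations = n_permutations,
                         seed = seed, mode = mode)
  idx <- chromosome_snps(dataset, chromosome)
  sbp <- dataset$snps$position_bp[idx[start_index]]
  ebp <- dataset$snps$position_bp[idx[end_index]]
  ht <- scan$haplotype_tests
  ht[ht$start_bp >= sbp & ht$end_bp <= ebp, , drop = FALSE]
}

#' @export
print.haplotype_scan <- function(x, ...) {
  cat(sprintf("haplotype_scan on %s: %d blocks, %d SNP tests, %d haplotype tests\n",
              x$chromosome, nrow(x$blocks), nrow(x$snp_tests),
              nrow(x$haplotype_tests)))
  cat(sprintf("  %d %s permutations\n", x$n_permutations,
              if (isTRUE(x$exhaustive)) "exhaustive" else "Monte-Carlo"))
  if (nrow(x$haplotype_tests)) {
    ord <- order(x$haplotype_tests$p_chromosome, -x$haplotype_tests$chi2)
    cat("top haplotypes:\n")
    print.data.frame(utils::head(x$haplotype_tests[ord, ], 5),
                     row.names = FALSE)
  }
  invisible(x)
}

#' Write haplotype scan results as TSV
#' @param scan a \code{haplotype_scan}.
#' @param path output path for the haplotype tests table.
#' @return Invisibly, the scan.
#' @export
write_haplotype_scan <- function(scan, path) {
  utils::write.table(scan$haplotype_tests, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(scan)
}
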