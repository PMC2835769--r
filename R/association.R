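#' Allelic chi-square test on a 2x2 allele-count table
#'
#' The 1-df Pearson chi-square on the case/control by minor/major allele
#' table, computed in closed form:
#' \deqn{\chi^2 = N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]}
#' where \code{a,b} are the case minor/major allele counts and \code{c,d}
#' the control counts.  A zero margin (pooled-monomorphic SNP) yields
#' \code{chi2 = 0, p = 1}.
#'
#' @param case_alleles numeric pair \code{c(minor, major)} of allele counts
#'   in cases.
#' @param control_alleles same for controls.
#' @return A list with \code{chi2} and \code{p_raw} (upper tail of the
#'   1-df chi-square distribution).
#' @examples
#' allelic_chi_square(c(15, 5), c(5, 15))  # chi2 = 10
#' @export
allelic_chi_square <- function(case_alleles, control_alleles) {
  a <- case_alleles[1]; b <- case_alleles[2]
  c_ <- control_alleles[1]; d <- control_alleles[2]
  if (any(c(a, b, c_, d) < 0)) stopf("allele counts must be non-negative")
  if (a + b == 0) stopf("no data for group: cases have zero alleles")
  if (c_ + d == 0) stopf("no data for group: controls have zero alleles")
  N <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) return(list(chi2 = 0, p_raw = 1))
  chi2 <- N * (a * d - b * c_)^2 / denom
  list(chi2 = chi2, p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Vectorised allelic chi-square for a set of tests under a label vector.
#
# D: n x t matrix of per-individual "minor dosage" for each test (for a SNP,
#    the 0/1/2 call with NA -> 0); U: n x t inclusion matrix (1 if the
#    individual contributes 2 alleles to test t, else 0); z: 0/1 case
#    indicator of length n (or n x B matrix for B label vectors at once).
# Returns a t-vector (or t x B matrix) of chi-square statistics.
chi2_for_labels <- function(D, U, z) {
  S <- colSums(D)            # pooled minor counts per test
  Tt <- 2 * colSums(U)       # pooled allele totals per test
  A <- crossprod(D, z)       # case minor counts (t x B)
  N1 <- 2 * crossprod(U, z)  # case allele totals
  N2 <- Tt - N1
  Cc <- S - A
  num <- Tt * (A * (N2 - Cc) - (N1 - A) * Cc)^2
  den <- N1 * N2 * S * (Tt - S)
  chi2 <- num / den
  chi2[!is.finite(chi2)] <- 0
  chi2
}

# Shared max-statistic permutation engine.
#
# Computes observed chi-square per test and a corrected p-value comparing
# each observed statistic with the distribution of the maximum statistic
# over all tests under case/control label permutation.  Modes:
#   auto        - exhaustive if choose(n, n_cases) <= exhaustive_cap
#   exhaustive  - enumerate every distinct label assignment; p = count/total
#   monte_carlo - B random shuffles; p = (1 + count) / (1 + B)
maxT_engine <- function(D, U, z, n_permutations, seed,
                        mode = c("auto", "monte_carlo", "exhaustive"),
                        exhaustive_cap = 1e6, block_size = 512L) {
  mode <- match.arg(mode)
  n <- length(z)
  k <- sum(z)
  obs <- as.numeric(chi2_for_labels(D, U, matrix(z, ncol = 1)))

  n_assign <- choose(n, k)
  use_ex <- switch(mode,
                   auto = n_assign <= exhaustive_cap,
                   exhaustive = TRUE,
                   monte_carlo = FALSE)
  if (use_ex && n_assign > exhaustive_cap)
    stopf("exhaustive enumeration requires choose(%d, %d) = %g <= %g assignments",
          n, k, n_assign, exhaustive_cap)

  if (use_ex) {
    sets <- utils::combn(n, k)
    B <- ncol(sets)
    maxs <- numeric(B)
    for (start in seq(1L, B, by = block_size)) {
      idx <- start:min(start + block_size - 1L, B)
      Z <- matrix(0, n, length(idx))
      Z[cbind(as.vector(sets[, idx, drop = FALSE]),
              rep(seq_along(idx), each = k))] <- 1
      chi <- chi2_for_labels(D, U, Z)
      maxs[idx] <- apply(chi, 2, max)
    }
    # observed assignment is one of the enumerated ones
    p_corr <- vapply(obs, function(o) sum(maxs >= o - 1e-12) / B, 0)
    list(chi2 = obs, p_corrected = p_corr, n_permutations = B,
         exhaustive = TRUE, max_null = maxs)
  } else {
    B <- as.integer(n_permutations)
    if (B < 1L) stopf("n_permutations must be >= 1")
    maxs <- numeric(B)
    with_seed(seed, {
      for (start in seq(1L, B, by = block_size)) {
        idx <- start:min(start + block_size - 1L, B)
        Z <- vapply(idx, function(i) sample(z), numeric(n))
        chi <- chi2_for_labels(D, U, Z)
        maxs[idx] <- apply(chi, 2, max)
      }
    })
    p_corr <- vapply(obs, function(o) (1 + sum(maxs >= o - 1e-12)) / (1 + B), 0)
    list(chi2 = obs, p_corrected = p_corr, n_permutations = B,
         exhaustive = FALSE, max_null = maxs)
  }
}

# Build the per-SNP dosage / inclusion matrices used by the chi2 engine.
snp_test_matrices <- function(dataset, snp_idx = seq_len(n_snps(dataset))) {
  G <- dataset$calls[, snp_idx, drop = FALSE]
  U <- !is.na(G)
  G[!U] <- 0L
  storage.mode(G) <- "double"
  storage.mode(U) <- "double"
  list(D = G, U = U)
}

case_indicator <- function(dataset) {
  st <- dataset$samples$status
  if (any(is.na(st)))
    stopf("%d samples have unknown status; association requires case/control",
          sum(is.na(st)))
  z <- as.numeric(st == "case")
  if (sum(z) == 0) stopf("no case samples")
  if (sum(z) == length(z)) stopf("no control samples")
  z
}

#' Genome-wide single-marker association scan
#'
#' Computes the allelic chi-square and raw p-value for every SNP,
#' contrasting case against control minor-allele counts.  Missing calls
#' are excluded from each SNP's table; SNPs monomorphic in the pooled
#' sample get \code{chi2 = 0, p_raw = 1}.
#'
#' @param dataset a QC'd \code{genotype_dataset} with case/control status
#'   for every sample.
#' @return A data frame of class \code{assoc_scan} with one row per SNP:
#'   \code{snp_id}, \code{chromosome}, \code{position_bp}, \code{chi2},
#'   \code{p_raw}, and \code{p_genome} (NA until
#'   \code{\link{maxT_permutation}} is run).
#' @export
genome_scan <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  z <- case_indicator(dataset)
  mats <- snp_test_matrices(dataset)
  chi2 <- as.numeric(chi2_for_labels(mats$D, mats$U, matrix(z, ncol = 1)))
  res <- data.frame(
    snp_id = dataset$snps$snp_id,
    chromosome = dataset$snps$chromosome,
    position_bp = dataset$snps$position_bp,
    chi2 = chi2,
    p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    p_genome = NA_real_,
    stringsAsFactors = FALSE)
  class(res) <- c("assoc_scan", "data.frame")
  res
}

#' Genome-wide max-T permutation correction
#'
#' Case/control labels are randomly reassigned (preserving group sizes),
#' all SNP chi-square statistics recomputed, and the genome-wide maximum
#' recorded for each permutation.  The corrected p-value of a SNP is
#' \code{(1 + #\{max >= observed\}) / (1 + B)} in Monte-Carlo mode, or the
#' exact fraction of label assignments in exhaustive mode (used
#' automatically when the number of distinct assignments is at most
#' \code{exhaustive_cap}).
#'
#' @param dataset a QC'd \code{genotype_dataset}.
#' @param n_permutations number of Monte-Carlo permutations (default
#'   100,000).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param mode \code{"auto"} (exhaustive when feasible), or force
#'   \code{"monte_carlo"} / \code{"exhaustive"}.
#' @param exhaustive_cap largest number of distinct assignments enumerated
#'   in auto/exhaustive mode.
#' @return An \code{assoc_scan} data frame with \code{p_genome} filled in,
#'   plus attributes \code{n_permutations}, \code{exhaustive}, \code{seed}.
#' @examples
#' gd <- simulate_breeds(default_scenario(seed = 1))$dataset
#' scan <- maxT_permutation(gd, n_permutations = 200, seed = 42)
#' head(scan[order(scan$p_genome, -scan$chi2), ])
#' @export
maxT_permutation <- function(dataset, n_permutations = 100000L, seed = 1L,
                             mode = c("auto", "monte_carlo", "exhaustive"),
                             exhaustive_cap = 1e6) {
  mode <- match.arg(mode)
  z <- case_indicator(dataset)
  mats <- snp_test_matrices(dataset)
  eng <- maxT_engine(mats$D, mats$U, z, n_permutations, seed, mode,
                     exhaustive_cap)
  res <- genome_scan(dataset)
  res$p_genome <- eng$p_corrected
  attr(res, "n_permutations") <- eng$n_permutations
  attr(res, "exhaustive") <- eng$exhaustive
  attr(res, "seed") <- seed
  res
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: %d SNPs", nrow(x)))
  if (!is.null(attr(x, "n_permutations")))
    cat(sprintf(", %d %s permutations", attr(x, "n_permutations"),
                if (isTRUE(attr(x, "exhaustive"))) "exhaustive" else "Monte-Carlo"))
  cat("\n")
  ord <- order(x$p_genome, -x$chi2, x$chromosome, x$position_bp)
  cat("top SNPs:\n")
  print.data.frame(utils::head(x[ord, ], 5), row.names = FALSE)
  invisible(x)
}

#' Best locus and support ratio over competing chromosomes
#'
#' Ranks SNPs by corrected p-value (ties broken by larger chi-square, then
#' by chromosome and position) and compares the top chromosome's best
#' corrected p-value with the best corrected p-value on any other
#' chromosome.  The locus is flagged accepted when the fold difference
#' exceeds 100, the working rule for trusting an across-breed hit.
#'
#' @param results an \code{assoc_scan} with \code{p_genome} defined.
#' @param accept_fold fold-difference threshold for acceptance (strict >).
#' @return A list of class \code{scan_result}: \code{best} (top SNP row),
#'   \code{support_ratio}, \code{accepted}, \code{next_best} and the full
#'   \code{results}.
#' @export
locus_support_ratio <- function(results, accept_fold = 100) {
  if (any(is.na(results$p_genome)))
    stopf("p_genome undefined; run maxT_permutation first")
  if (length(unique(results$chromosome)) < 2L)
    stopf("no competing chromosome: all SNPs are on one chromosome")
  ord <- order(results$p_genome, -results$chi2, results$chromosome,
               results$position_bp)
  best <- results[ord[1], ]
  others <- results[results$chromosome != best$chromosome, ]
  next_p <- min(others$p_genome)
  oord <- order(others$p_genome, -others$chi2, others$chromosome,
                others$position_bp)
  next_best <- others[oord[1], ]
  ratio <- next_p / best$p_genome
  structure(list(best = best, next_best = next_best,
                 support_ratio = ratio,
                 accepted = ratio > accept_fold,
                 accept_fold = accept_fold,
                 results = results),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result\n")
  cat(sprintf("  best locus: %s (%s:%d), chi2 = %.3f, p_raw = %.3g, p_genome = %.3g\n",
              x$best$snp_id, x$best$chromosome, x$best$position_bp,
              x$best$chi2, x$best$p_raw, x$best$p_genome))
  cat(sprintf("  next-best chromosome: %s, p_genome = %.3g\n",
              x$next_best$chromosome, x$next_best$p_genome))
  cat(sprintf("  support ratio: %.1f (%s at fold > %g)\n",
              x$support_ratio,
              if (x$accepted) "accepted" else "not accepted",
              x$accept_fold))
  invisible(x)
}

#' Write an association scan as TSV
#' @param results an \code{assoc_scan}.
#' @param path output path.
#' @return Invisibly, the results.
#' @export
write_assoc_scan <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(results)
}
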