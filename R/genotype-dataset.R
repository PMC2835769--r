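#' Construct a genotype dataset
#'
#' A \code{genotype_dataset} holds unphased biallelic SNP genotypes as
#' minor-allele dosage counts together with sample and SNP metadata.  It is
#' the common currency of every analysis stage in the package.
#'
#' Genotype calls are coded 0/1/2 as the number of copies of the SNP's
#' minor allele (determined once, when the data are loaded or simulated,
#' so that subsetting samples can never flip the counted allele); missing
#' calls are \code{NA}.
#'
#' @param calls integer matrix, one row per sample and one column per SNP,
#'   values in \code{c(0, 1, 2, NA)}.
#' @param samples data frame with columns \code{sample_id}, \code{breed},
#'   \code{status} (\code{"case"}, \code{"control"} or \code{NA}).
#' @param snps data frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position_bp} (1-based).  Positions must be strictly increasing
#'   within each chromosome.
#' @return An object of class \code{genotype_dataset}.
#' @examples
#' gd <- genotype_dataset(
#'   calls = matrix(c(0L, 1L, 2L, 0L), nrow = 2),
#'   samples = data.frame(sample_id = c("s1", "s2"),
#'                        breed = c("b1", "b2"),
#'                        status = c("case", "control")),
#'   snps = data.frame(snp_id = c("snp1", "snp2"),
#'                     chromosome = "chr1",
#'                     position_bp = c(100L, 200L)))
#' gd
#' @export
genotype_dataset <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  rownames(snps) <- NULL

  req_s <- c("sample_id", "breed", "status")
  req_m <- c("snp_id", "chromosome", "position_bp")
  if (!all(req_s %in% names(samples)))
    stopf("samples must have columns %s", paste(req_s, collapse = ", "))
  if (!all(req_m %in% names(snps)))
    stopf("snps must have columns %s", paste(req_m, collapse = ", "))
  if (nrow(calls) != nrow(samples))
    stopf("calls has %d rows but samples has %d entries",
          nrow(calls), nrow(samples))
  if (ncol(calls) != nrow(snps))
    stopf("calls has %d columns but snps has %d entries",
          ncol(calls), nrow(snps))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicated sample_id")
  if (anyDuplicated(snps$snp_id))
    stopf("duplicated snp_id")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stopf("calls contain values outside {0, 1, 2, NA}")
  if (!all(is.na(samples$status) | samples$status %in% c("case", "control")))
    stopf("status must be 'case', 'control' or NA")
  snps$position_bp <- as.integer(snps$position_bp)
  if (any(snps$position_bp < 1L, na.rm = TRUE))
    stopf("position_bp must be positive")
  for (chr in unique(snps$chromosome)) {
    pos <- snps$position_bp[snps$chromosome == chr]
    if (any(diff(pos) <= 0))
      stopf("positions not strictly increasing on chromosome %s", chr)
  }
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_dataset")
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

n_samples <- function(x) nrow(x$calls)
n_snps <- function(x) ncol(x$calls)

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs\n",
              n_samples(x), n_snps(x)))
  st <- table(factor(x$samples$status, levels = c("case", "control")),
              useNA = "ifany")
  cat(sprintf("  cases: %d  controls: %d  breeds: %d\n",
              st[["case"]], st[["control"]],
              length(unique(x$samples$breed))))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chromosome), collapse = ", ")))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  maf <- snp_maf(object)
  cr <- snp_call_rate(object)
  out <- list(
    n_samples = n_samples(object),
    n_snps = n_snps(object),
    n_cases = sum(object$samples$status == "case", na.rm = TRUE),
    n_controls = sum(object$samples$status == "control", na.rm = TRUE),
    breeds = sort(unique(object$samples$breed)),
    maf = summary(maf),
    snp_call_rate = summary(cr),
    missing_fraction = mean(is.na(object$calls)))
  class(out) <- "summary.genotype_dataset"
  out
}

#' @export
print.summary.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases, %d controls), %d SNPs\n",
              x$n_samples, x$n_cases, x$n_controls, x$n_snps))
  cat(sprintf("breeds (%d): %s\n", length(x$breeds),
              paste(x$breeds, collapse = ", ")))
  cat("MAF:\n"); print(x$maf)
  cat("SNP call rate:\n"); print(x$snp_call_rate)
  cat(sprintf("overall missing fraction: %.4f\n", x$missing_fraction))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x a \code{genotype_dataset}.
#' @param samples logical/integer index over samples (optional).
#' @param snps logical/integer index over SNPs (optional).
#' @return A \code{genotype_dataset} restricted to the selected rows/columns.
#' @export
subset_dataset <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  si <- samples %||% seq_len(n_samples(x))
  mi <- snps %||% seq_len(n_snps(x))
  genotype_dataset(x$calls[si, mi, drop = FALSE],
                   x$samples[si, , drop = FALSE],
                   x$snps[mi, , drop = FALSE])
}

# Per-SNP minor allele frequency over non-missing calls.  Monomorphic or
# all-missing SNPs report 0.  Note calls count the dataset-level minor
# allele, so after subsetting samples the "MAF" may exceed 0.5; it is the
# frequency of the stored counted allele.
snp_maf <- function(x) {
  cnt <- colSums(x$calls, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(x$calls))
  maf <- ifelse(tot > 0, cnt / tot, 0)
  pmin(maf, 1 - maf)
}

snp_call_rate <- function(x) colMeans(!is.na(x$calls))

sample_missingness <- function(x) rowMeans(is.na(x$calls))

snp_index <- function(x, snp_id) {
  i <- match(snp_id, x$snps$snp_id)
  if (is.na(i)) stopf("SNP '%s' not in dataset", snp_id)
  i
}

chromosome_snps <- function(x, chromosome) {
  idx <- which(x$snps$chromosome == chromosome)
  if (length(idx) == 0L)
    stopf("chromosome '%s' not in dataset", chromosome)
  idx
}
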