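#' Apply genotype quality control
#'
#' Filters a dataset in a fixed order: (1) samples whose missingness over
#' the input SNP set exceeds \code{sample_missing_max}; (2) SNPs whose call
#' rate over the retained samples falls below \code{snp_callrate_min};
#' (3) SNPs whose minor allele frequency (computed over retained samples,
#' non-missing calls only) is not above \code{maf_min}.  The defaults are
#' the conventional array-QC thresholds for this kind of study: MAF > 0.05,
#' SNP call rate >= 75\%, at most 25\% missing genotypes per individual.
#'
#' \code{maf_min = 0} disables the MAF filter entirely; any positive
#' \code{maf_min} removes monomorphic SNPs (MAF 0).
#'
#' @param dataset a \code{genotype_dataset}.
#' @param maf_min minimum minor allele frequency (strict; keep MAF > maf_min).
#' @param snp_callrate_min minimum per-SNP call rate (keep rate >= threshold).
#' @param sample_missing_max maximum per-sample missing fraction
#'   (keep missingness <= threshold).
#' @return A list with elements \code{dataset} (the filtered
#'   \code{genotype_dataset}) and \code{report} (a \code{qc_report}).
#' @examples
#' gd <- simulate_breeds(default_scenario(seed = 1))$dataset
#' qc <- apply_qc(gd)
#' qc$report
#' @export
apply_qc <- function(dataset, maf_min = 0.05, snp_callrate_min = 0.75,
                     sample_missing_max = 0.25) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  for (v in c(maf_min, snp_callrate_min, sample_missing_max))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stopf("QC thresholds must be single fractions in [0, 1]")

  n0 <- n_samples(dataset); m0 <- n_snps(dataset)

  keep_s <- sample_missingness(dataset) <= sample_missing_max
  ds1 <- subset_dataset(dataset, samples = which(keep_s))
  n_rm_samples <- sum(!keep_s)
  if (n_samples(ds1) == 0L)
    stopf("QC removed all samples (%d of %d over missingness > %g)",
          n_rm_samples, n0, sample_missing_max)

  keep_cr <- snp_call_rate(ds1) >= snp_callrate_min
  n_rm_callrate <- sum(!keep_cr)
  ds2 <- subset_dataset(ds1, snps = which(keep_cr))

  maf <- snp_maf(ds2)
  keep_maf <- if (maf_min == 0) rep(TRUE, n_snps(ds2)) else maf > maf_min
  n_rm_maf <- sum(!keep_maf)
  ds3 <- subset_dataset(ds2, snps = which(keep_maf))

  report <- structure(list(
    snps_removed_maf = n_rm_maf,
    snps_removed_callrate = n_rm_callrate,
    samples_removed_missingness = n_rm_samples,
    samples_in = n0, snps_in = m0,
    samples_out = n_samples(ds3), snps_out = n_snps(ds3),
    thresholds = c(maf_min = maf_min, snp_callrate_min = snp_callrate_min,
                   sample_missing_max = sample_missing_max)),
    class = "qc_report")

  if (n_snps(ds3) == 0L) {
    message(format_qc_report(report))
    stopf("QC removed all SNPs")
  }
  list(dataset = ds3, report = report)
}

format_qc_report <- function(x) {
  paste0(
    sprintf("QC thresholds: MAF > %g, SNP call rate >= %g, sample missingness <= %g\n",
            x$thresholds["maf_min"], x$thresholds["snp_callrate_min"],
            x$thresholds["sample_missing_max"]),
    sprintf("samples: %d -> %d (%d removed for missingness)\n",
            x$samples_in, x$samples_out, x$samples_removed_missingness),
    sprintf("SNPs: %d -> %d (%d removed for call rate, %d for MAF)",
            x$snps_in, x$snps_out, x$snps_removed_callrate,
            x$snps_removed_maf))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(format_qc_report(x), "\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a \code{qc_report}.
#' @param path output path.
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("samples_in", "samples_removed_missingness", "samples_out",
               "snps_in", "snps_removed_callrate", "snps_removed_maf",
               "snps_out", "maf_min", "snp_callrate_min",
               "sample_missing_max"),
    value = c(report$samples_in, report$samples_removed_missingness,
              report$samples_out, report$snps_in,
              report$snps_removed_callrate, report$snps_removed_maf,
              report$snps_out, unname(report$thresholds)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
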