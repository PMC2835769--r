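# Selective-sweep scan: normalized relative heterozygosity of cases
# versus controls in sliding windows along a chromosome.

#' Sample/SNP filters for the sweep scan
#'
#' The sweep scan uses its own, stricter filters than the association QC:
#' only samples with a call rate above 75\% are used, and SNPs with a call
#' rate below 95\% (over the retained samples) are removed.
#'
#' @param dataset a \code{genotype_dataset} with case and control samples.
#' @param sample_callrate_min retain samples with call rate strictly above
#'   this (default 0.75).
#' @param snp_callrate_min retain SNPs with call rate at or above this
#'   (default 0.95).
#' @return The filtered \code{genotype_dataset}.
#' @export
sweep_qc <- function(dataset, sample_callrate_min = 0.75,
                     snp_callrate_min = 0.95) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  keep_s <- 1 - sample_missingness(dataset) > sample_callrate_min
  if (!any(keep_s)) stopf("sweep_qc removed all samples")
  ds <- subset_dataset(dataset, samples = which(keep_s))
  keep_m <- snp_call_rate(ds) >= snp_callrate_min
  if (!any(keep_m)) stopf("sweep_qc removed all SNPs")
  subset_dataset(ds, snps = which(keep_m))
}

#' Heterozygosity rate of a call vector
#'
#' Fraction of non-missing calls that are heterozygous (dosage 1).
#'
#' @param calls integer vector over \code{c(0, 1, 2, NA)}.
#' @return A fraction in [0, 1], or \code{NA} if every call is missing.
#' @examples
#' heterozygosity_rate(c(1, 0, NA, 2))  # 1/3
#' @export
heterozygosity_rate <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) return(NA_real_)
  mean(calls[ok] == 1L)
}

#' Normalize a relative-heterozygosity ratio
#'
#' Maps the case/control heterozygosity ratio onto a scale that is
#' negative exactly when cases are less heterozygous than controls and
#' antisymmetric in the ratio's reciprocal:
#' \code{1 - 1/ratio} for \code{0 < ratio < 1}, otherwise \code{ratio - 1}
#' (so ratio 1 maps to 0, and ratio 0 — complete case fixation — maps to
#' -1 by the same "diminish by 1" branch).
#'
#' @param ratio non-negative ratio (vectorised; NA passes through).
#' @return Normalized value(s).
#' @examples
#' normalize_ratio(c(0.5, 1, 3))  # -1, 0, 2
#' @export
normalize_ratio <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) stopf("ratio must be non-negative")
  ifelse(!is.na(ratio) & ratio > 0 & ratio < 1, 1 - 1 / ratio, ratio - 1)
}

#' Sliding-window normalized relative heterozygosity along a chromosome
#'
#' Per-SNP heterozygosity rates are computed separately in cases and
#' controls, averaged over sliding windows of \code{window_snps}
#' consecutive SNPs (advancing one SNP at a time), and the window ratio
#' \code{het_cases / het_controls} is passed through
#' \code{\link{normalize_ratio}}.  A window with control heterozygosity 0
#' (and case heterozygosity > 0) has no defined ratio and is emitted as
#' \code{NA}.
#'
#' @param dataset a \code{genotype_dataset}, normally after
#'   \code{\link{sweep_qc}}.
#' @param chromosome chromosome label.
#' @param window_snps window width in SNPs (5 for the original array
#'   density, 10 for a denser panel are typical choices).
#' @param floor_zero if TRUE, windows with ratio exactly 0 are floored to
#'   the minimum normalized value observed elsewhere instead of the
#'   literal -1 (off by default).
#' @return A data frame of class \code{sweep_profile}: one row per window
#'   with \code{midpoint_bp}, \code{het_cases}, \code{het_controls},
#'   \code{ratio}, \code{normalized}.
#' @export
sliding_profile <- function(dataset, chromosome, window_snps = 5L,
                            floor_zero = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  window_snps <- as.integer(window_snps)
  if (window_snps < 1L) stopf("window_snps must be >= 1")
  idx <- chromosome_snps(dataset, chromosome)
  if (length(idx) < window_snps)
    stopf("chromosome %s has %d SNPs, fewer than window_snps = %d",
          chromosome, length(idx), window_snps)
  st <- dataset$samples$status
  cases <- which(!is.na(st) & st == "case")
  ctrls <- which(!is.na(st) & st == "control")
  if (length(cases) == 0L || length(ctrls) == 0L)
    stopf("sweep scan needs both case and control samples")

  het_case_snp <- apply(dataset$calls[cases, idx, drop = FALSE], 2,
                        heterozygosity_rate)
  het_ctrl_snp <- apply(dataset$calls[ctrls, idx, drop = FALSE], 2,
                        heterozygosity_rate)
  pos <- dataset$snps$position_bp[idx]

  n_win <- length(idx) - window_snps + 1L
  wmean <- function(v, i) mean(v[i:(i + window_snps - 1L)], na.rm = TRUE)
  het_cases <- vapply(seq_len(n_win), wmean, 0, v = het_case_snp)
  het_controls <- vapply(seq_len(n_win), wmean, 0, v = het_ctrl_snp)
  het_cases[is.nan(het_cases)] <- NA_real_
  het_controls[is.nan(het_controls)] <- NA_real_
  midpoint <- vapply(seq_len(n_win), wmean, 0, v = pos)

  ratio <- ifelse(is.na(het_cases) | is.na(het_controls) | het_controls == 0,
                  NA_real_, het_cases / het_controls)
  normalized <- normalize_ratio(ratio)
  if (floor_zero) {
    zero <- !is.na(ratio) & ratio == 0
    if (any(zero) && any(!zero & !is.na(normalized)))
      normalized[zero] <- min(normalized[!zero], na.rm = TRUE)
  }
  out <- data.frame(chromosome = chromosome, midpoint_bp = midpoint,
                    het_cases = het_cases, het_controls = het_controls,
                    ratio = ratio, normalized = normalized,
                    stringsAsFactors = FALSE)
  class(out) <- c("sweep_profile", "data.frame")
  out
}

#' Locate the minimum of a sweep profile
#'
#' @param profile a \code{sweep_profile}.
#' @return One-row data frame: the window with the most negative
#'   normalized value (ties broken by smaller midpoint).
#' @export
sweep_minimum <- function(profile) {
  ok <- !is.na(profile$normalized)
  if (!any(ok)) stopf("no defined windows in profile")
  sub <- profile[ok, ]
  sub[order(sub$normalized, sub$midpoint_bp)[1], ]
}

#' @export
print.sweep_profile <- function(x, ...) {
  cat(sprintf("sweep_profile on %s: %d windows (%d undefined)\n",
              x$chromosome[1], nrow(x), sum(is.na(x$normalized))))
  mn <- sweep_minimum(x)
  cat(sprintf("  minimum: %.3f at %.0f bp (het_cases %.3f, het_controls %.3f)\n",
              mn$normalized, mn$midpoint_bp, mn$het_cases, mn$het_controls))
  invisible(x)
}

#' Write a sweep profile as TSV
#' @param profile a \code{sweep_profile}.
#' @param path output path.
#' @return Invisibly, the profile.
#' @export
write_sweep_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(profile)
}
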