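# Fine mapping by intersecting homozygous haplotypes shared across
# affected breeds around the top associated SNP.

#' Homozygous haplotype run of one breed around an anchor SNP
#'
#' Extends left and right from the anchor SNP while, at each SNP, the
#' fraction of the breed's individuals that are heterozygous or homozygous
#' for a discordant allele is at most \code{max_het_fraction} (default 0:
#' every called individual homozygous for the same allele).  Missing calls
#' neither break nor support the run, but the run cannot extend past a SNP
#' at which no individual of the breed is called.
#'
#' @param dataset a \code{genotype_dataset} (typically a dense regional
#'   fine-mapping panel).
#' @param breed breed label.
#' @param anchor_snp snp_id of the anchor (normally the top associated
#'   SNP).
#' @param max_het_fraction tolerated fraction of non-conforming
#'   individuals per SNP.
#' @return An object of class \code{homozygous_run}: list with
#'   \code{breed}, \code{chromosome}, \code{start_bp}, \code{end_bp},
#'   \code{snp_index} (columns of the dataset in the run),
#'   \code{positions_bp}, \code{haplotype} (consensus allele string over
#'   \{A,B\}), \code{n_individuals}, \code{anchor_snp}.
#' @export
breed_homozygous_run <- function(dataset, breed, anchor_snp,
                                 max_het_fraction = 0) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  rows <- which(dataset$samples$breed == breed)
  if (length(rows) == 0L) stopf("breed '%s' has no individuals", breed)
  anchor <- snp_index(dataset, anchor_snp)
  chr <- dataset$snps$chromosome[anchor]
  idx <- chromosome_snps(dataset, chr)
  apos <- match(anchor, idx)
  G <- dataset$calls[rows, idx, drop = FALSE]

  if (all(is.na(G[, apos])))
    stopf("anchor SNP '%s' missing in every individual of breed '%s'",
          anchor_snp, breed)

  # a SNP conforms if one homozygote class covers enough of the called
  # individuals; returns the consensus allele code (0 or 2) or NA
  consensus <- function(j) {
    g <- G[, j]
    called <- !is.na(g)
    if (!any(called)) return(NA_integer_)      # no data: cannot extend past
    n_hom0 <- sum(g[called] == 0L)
    n_hom2 <- sum(g[called] == 2L)
    allele <- if (n_hom2 >= n_hom0) 2L else 0L
    n_ok <- if (allele == 2L) n_hom2 else n_hom0
    bad_frac <- (sum(called) - n_ok) / sum(called)
    if (bad_frac <= max_het_fraction) allele else NA_integer_
  }

  if (is.na(consensus(apos)))
    stopf("breed '%s' is not homozygous-concordant at anchor '%s'",
          breed, anchor_snp)
  m <- length(idx)
  left <- apos
  while (left > 1L && !is.na(consensus(left - 1L))) left <- left - 1L
  right <- apos
  while (right < m && !is.na(consensus(right + 1L))) right <- right + 1L

  span <- left:right
  hap <- vapply(span, function(j) if (consensus(j) == 2L) "B" else "A", "")
  structure(list(breed = breed,
                 chromosome = chr,
                 start_bp = dataset$snps$position_bp[idx[left]],
                 end_bp = dataset$snps$position_bp[idx[right]],
                 snp_index = idx[span],
                 snp_ids = dataset$snps$snp_id[idx[span]],
                 positions_bp = dataset$snps$position_bp[idx[span]],
                 haplotype = paste(hap, collapse = ""),
                 n_individuals = length(rows),
                 anchor_snp = anchor_snp,
                 anchor_index = anchor),
            class = "homozygous_run")
}

#' @export
print.homozygous_run <- function(x, ...) {
  cat(sprintf("homozygous_run: breed %s (%d individuals), %s:%d-%d (%d SNPs)\n",
              x$breed, x$n_individuals, x$chromosome, x$start_bp, x$end_bp,
              length(x$snp_index)))
  cat(sprintf("  haplotype: %s\n", x$haplotype))
  invisible(x)
}

#' Critical interval from overlapping homozygous runs
#'
#' Intersects the homozygous runs of several breeds: restricts to the SNPs
#' present in every run at which all runs carry the identical consensus
#' allele, and returns the maximal contiguous stretch of such SNPs
#' containing the anchor.  This is the minimal interval in which all
#' supplied breeds share one homozygous haplotype.
#'
#' Adding a run can only narrow the interval (monotonicity), and the
#' result does not depend on the order of the runs.
#'
#' @param runs list of \code{homozygous_run} objects (at least 2) built
#'   around the same anchor SNP.
#' @return An object of class \code{critical_interval}: \code{start_bp},
#'   \code{end_bp}, \code{width_bp}, \code{snp_index}, \code{snp_ids},
#'   \code{haplotype} (shared allele string), \code{breeds}.
#' @export
overlap_interval <- function(runs) {
  if (length(runs) < 2L) stopf("need at least 2 runs to intersect")
  stopifnot(all(vapply(runs, inherits, TRUE, "homozygous_run")))
  anchor <- unique(vapply(runs, function(r) r$anchor_index, 0L))
  if (length(anchor) != 1L)
    stopf("runs were built around different anchor SNPs")

  # each run covers a contiguous index span containing the anchor, so the
  # intersection is itself a contiguous span containing the anchor
  common <- sort(Reduce(intersect, lapply(runs, function(r) r$snp_index)))
  if (length(common) == 0L)
    stopf("no shared haplotype: run intervals do not overlap")

  allele_at <- function(r, snp) {
    pos <- match(snp, r$snp_index)
    substr(r$haplotype, pos, pos)
  }
  concord <- vapply(common, function(snp) {
    length(unique(vapply(runs, allele_at, "", snp = snp))) == 1L
  }, TRUE)
  if (!any(concord)) {
    bad <- runs[[1]]$snp_ids[match(common, runs[[1]]$snp_index)]
    stopf("no shared haplotype: alleles discordant at every overlapping SNP (%s)",
          paste(bad, collapse = ", "))
  }
  apos <- match(anchor, common)
  if (is.na(apos) || !concord[apos])
    stopf("no shared haplotype at the anchor SNP")

  left <- apos
  while (left > 1L && concord[left - 1L]) left <- left - 1L
  right <- apos
  while (right < length(concord) && concord[right + 1L]) right <- right + 1L
  span <- common[left:right]

  r1 <- runs[[1]]
  sel <- match(span, r1$snp_index)
  structure(list(start_bp = r1$positions_bp[sel[1]],
                 end_bp = r1$positions_bp[sel[length(sel)]],
                 width_bp = r1$positions_bp[sel[length(sel)]] -
                   r1$positions_bp[sel[1]],
                 snp_index = span,
                 snp_ids = r1$snp_ids[sel],
                 haplotype = paste(vapply(span, allele_at, "", r = r1),
                                   collapse = ""),
                 breeds = vapply(runs, function(r) r$breed, ""),
                 anchor_snp = r1$anchor_snp),
            class = "critical_interval")
}

#' @export
print.critical_interval <- function(x, ...) {
  cat(sprintf("critical_interval: %d-%d bp (%.1f kb), %d SNPs, %d breeds\n",
              x$start_bp, x$end_bp, x$width_bp / 1000,
              length(x$snp_index), length(x$breeds)))
  cat(sprintf("  shared haplotype: %s\n", x$haplotype))
  cat(sprintf("  breeds: %s\n", paste(x$breeds, collapse = ", ")))
  invisible(x)
}

#' Fine-map a region across case breeds
#'
#' Builds one homozygous run per case breed around the anchor SNP and
#' intersects them into the critical interval.  Breeds that cannot
#' contribute are set aside rather than aborting the analysis: a breed
#' with no genotype at the anchor, or not homozygous-concordant there,
#' yields no run; and breeds whose run carries the minority allele at the
#' anchor are treated as a separate haplotype group (affected dogs are
#' grouped by the haplotype they carry, not forced into one consensus)
#' and excluded from the shared-haplotype intersection.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param breeds breed labels to fine-map (normally the case breeds).
#' @param anchor_snp snp_id of the anchor (normally the top associated
#'   SNP).
#' @param max_het_fraction per-SNP tolerance, see
#'   \code{\link{breed_homozygous_run}}.
#' @return A list of class \code{fine_mapping}: \code{runs} (the
#'   contributing runs), \code{interval} (a \code{critical_interval}),
#'   \code{excluded} (named reasons for breeds that did not contribute).
#' @export
finemap_case_breeds <- function(dataset, breeds, anchor_snp,
                                max_het_fraction = 0) {
  runs <- list(); excluded <- list()
  for (b in breeds) {
    r <- tryCatch(breed_homozygous_run(dataset, b, anchor_snp,
                                       max_het_fraction),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) excluded[[b]] <- r else runs[[b]] <- r
  }
  if (length(runs) >= 2L) {
    # majority allele at the anchor across contributing runs
    anchor_allele <- vapply(runs, function(r) {
      pos <- match(r$anchor_index, r$snp_index)
      substr(r$haplotype, pos, pos)
    }, "")
    tab <- sort(table(anchor_allele), decreasing = TRUE)
    keep <- anchor_allele == names(tab)[1]
    for (b in names(runs)[!keep])
      excluded[[b]] <- "minority allele at anchor (separate haplotype group)"
    runs <- runs[keep]
  }
  if (length(runs) < 2L)
    stopf("fewer than 2 case breeds share a homozygous haplotype at %s",
          anchor_snp)
  interval <- overlap_interval(unname(runs))
  structure(list(runs = runs, interval = interval, excluded = excluded),
            class = "fine_mapping")
}

#' @export
print.fine_mapping <- function(x, ...) {
  cat(sprintf("fine_mapping: %d contributing breeds, %d excluded\n",
              length(x$runs), length(x$excluded)))
  print(x$interval)
  for (b in names(x$excluded))
    cat(sprintf("  excluded %s: %s\n", b, x$excluded[[b]]))
  invisible(x)
}

#' Write homozygous runs and critical interval as TSV
#'
#' @param runs list of \code{homozygous_run} objects.
#' @param interval a \code{critical_interval} (or NULL).
#' @param path output path.
#' @return Invisibly, NULL.
#' @export
write_fine_mapping <- function(runs, interval, path) {
  df <- do.call(rbind, lapply(runs, function(r) data.frame(
    record = "run", breed = r$breed, chromosome = r$chromosome,
    start_bp = r$start_bp, end_bp = r$end_bp,
    n_snps = length(r$snp_index), n_individuals = r$n_individuals,
    haplotype = r$haplotype, stringsAsFactors = FALSE)))
  if (!is.null(interval)) {
    df <- rbind(df, data.frame(
      record = "critical_interval",
      breed = paste(interval$breeds, collapse = ","),
      chromosome = runs[[1]]$chromosome,
      start_bp = interval$start_bp, end_bp = interval$end_bp,
      n_snps = length(interval$snp_index), n_individuals = NA,
      haplotype = interval$haplotype, stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
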