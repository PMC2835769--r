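# End-to-end orchestration: simulate or load -> QC -> genome scan ->
# max-T permutation -> support ratio -> haplotype analysis -> sweep scan
# -> fine mapping, with per-stage artifacts and a single run report.

#' Pipeline configuration
#'
#' Exactly one of \code{scenario} (a \code{\link{sim_config}}) or
#' \code{ped_path}/\code{map_path} must be supplied.
#'
#' @param scenario a \code{sim_config} to simulate input data (or NULL).
#' @param ped_path,map_path PED/MAP input files (or NULL).
#' @param maf_min,snp_callrate_min,sample_missing_max association QC
#'   thresholds (see \code{\link{apply_qc}}).
#' @param n_permutations_genome genome-wide Monte-Carlo permutations.
#' @param n_permutations_chromosome chromosome-wide permutations for the
#'   haplotype tests.
#' @param sweep_window_snps sliding-window width for the sweep scan.
#' @param accept_fold support-ratio acceptance threshold.
#' @param max_het_fraction fine-mapping per-SNP tolerance.
#' @param out_dir output directory for stage artifacts (NULL: no files).
#' @param seed master seed; per-stage seeds are derived from it so that
#'   changing one stage's settings does not perturb the others.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = NULL, ped_path = NULL,
                            map_path = NULL,
                            maf_min = 0.05, snp_callrate_min = 0.75,
                            sample_missing_max = 0.25,
                            n_permutations_genome = 100000L,
                            n_permutations_chromosome = 50000L,
                            sweep_window_snps = 5L,
                            accept_fold = 100,
                            max_het_fraction = 0,
                            out_dir = NULL, seed = 1L) {
  has_sim <- !is.null(scenario)
  has_files <- !is.null(ped_path) || !is.null(map_path)
  if (has_sim == has_files)
    stopf("supply exactly one of scenario or ped_path/map_path")
  if (has_files) {
    if (is.null(ped_path) || is.null(map_path))
      stopf("both ped_path and map_path are required in file mode")
    if (!file.exists(ped_path)) stopf("ped_path not found: %s", ped_path)
    if (!file.exists(map_path)) stopf("map_path not found: %s", map_path)
  }
  if (has_sim) stopifnot(inherits(scenario, "sim_config"))
  structure(list(scenario = scenario, ped_path = ped_path,
                 map_path = map_path, maf_min = maf_min,
                 snp_callrate_min = snp_callrate_min,
                 sample_missing_max = sample_missing_max,
                 n_permutations_genome = as.integer(n_permutations_genome),
                 n_permutations_chromosome =
                   as.integer(n_permutations_chromosome),
                 sweep_window_snps = as.integer(sweep_window_snps),
                 accept_fold = accept_fold,
                 max_het_fraction = max_het_fraction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the across-breed mapping pipeline
#'
#' Stages run in the analysis order of an across-breed study: input
#' (simulated or read from PED/MAP), association QC, genome-wide scan with
#' max-T permutation, best-locus support ratio, then — on the top locus
#' chromosome — haplotype-block association, sweep scan and homozygosity
#' fine mapping across the case breeds.  All stages are deterministic
#' given the master seed.  If a later stage fails, the report is returned
#' with that stage's error recorded and upstream results intact.
#'
#' @param config a \code{pipeline_config}.
#' @param quiet suppress progress messages.
#' @return A list of class \code{run_report} with elements \code{qc}
#'   (\code{qc_report}), \code{scan} (\code{assoc_scan}), \code{locus}
#'   (\code{scan_result}), \code{haplotypes} (\code{haplotype_scan}),
#'   \code{sweep} (\code{sweep_profile}), \code{finemap} (runs +
#'   \code{critical_interval}), \code{truth} (when simulated),
#'   \code{seed}, \code{skipped} (named reasons for skipped stages).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(scenario = default_scenario(seed = 7),
#'                        n_permutations_genome = 500,
#'                        n_permutations_chromosome = 500, seed = 7)
#' rep <- run_pipeline(cfg, quiet = TRUE)
#' rep
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- derive_seeds(config$seed, 3L)
  out <- list(seed = config$seed, skipped = list())
  odir <- config$out_dir
  if (!is.null(odir) && !dir.exists(odir))
    dir.create(odir, recursive = TRUE)
  art <- function(name) if (is.null(odir)) NULL else file.path(odir, name)

  # --- input ---------------------------------------------------------
  if (!is.null(config$scenario)) {
    say("simulating scenario (seed %d)", config$scenario$seed)
    sim <- simulate_breeds(config$scenario)
    dataset <- sim$dataset
    out$truth <- sim$truth
    if (!is.null(odir)) {
      write_ped_map(dataset, art("input.ped"), art("input.map"))
      write_sim_truth(sim$truth, art("truth.tsv"))
    }
  } else {
    say("reading %s / %s", config$ped_path, config$map_path)
    dataset <- read_ped_map(config$ped_path, config$map_path)
  }
  out$input_dim <- dim(dataset)

  # --- association QC ------------------------------------------------
  qc <- apply_qc(dataset, config$maf_min, config$snp_callrate_min,
                 config$sample_missing_max)
  out$qc <- qc$report
  say("%s", format_qc_report(qc$report))
  if (!is.null(odir)) write_qc_report(qc$report, art("qc_report.tsv"))
  ds <- qc$dataset

  # --- genome-wide association with max-T ----------------------------
  say("genome scan with %d permutations", config$n_permutations_genome)
  scan <- maxT_permutation(ds, config$n_permutations_genome,
                           seed = seeds[1])
  out$scan <- scan
  if (!is.null(odir)) write_assoc_scan(scan, art("assoc_scan.tsv"))

  out$locus <- tryCatch(locus_support_ratio(scan, config$accept_fold),
                        error = function(e) NULL)
  if (is.null(out$locus)) {
    out$skipped$locus <- "support ratio unavailable (single chromosome?)"
    ord <- order(scan$p_genome, -scan$chi2, scan$chromosome,
                 scan$position_bp)
    top <- scan[ord[1], ]
  } else {
    say("top locus %s (%s), support ratio %.1f (%s)",
        out$locus$best$snp_id, out$locus$best$chromosome,
        out$locus$support_ratio,
        if (out$locus$accepted) "accepted" else "not accepted")
    top <- out$locus$best
  }
  top_chr <- top$chromosome

  # --- haplotype analysis on the top chromosome ----------------------
  out$haplotypes <- tryCatch({
    say("haplotype scan on %s (%d permutations)", top_chr,
        config$n_permutations_chromosome)
    hs <- haplotype_scan(ds, top_chr,
                         n_permutations = config$n_permutations_chromosome,
                         seed = seeds[2])
    if (!is.null(odir)) write_haplotype_scan(hs, art("haplotype_tests.tsv"))
    hs
  }, error = function(e) {
    out$skipped$haplotypes <<- conditionMessage(e)
    NULL
  })

  # --- sweep scan on the top chromosome ------------------------------
  out$sweep <- tryCatch({
    say("sweep scan on %s (window %d SNPs)", top_chr,
        config$sweep_window_snps)
    sds <- sweep_qc(dataset)
    prof <- sliding_profile(sds, top_chr, config$sweep_window_snps)
    if (!is.null(odir)) write_sweep_profile(prof, art("sweep_profile.tsv"))
    prof
  }, error = function(e) {
    out$skipped$sweep <<- conditionMessage(e)
    NULL
  })

  # --- fine mapping across case breeds -------------------------------
  out$finemap <- tryCatch({
    case_breeds <- unique(ds$samples$breed[ds$samples$status == "case"])
    say("fine mapping: %d case breeds around %s", length(case_breeds),
        top$snp_id)
    fm <- finemap_case_breeds(ds, case_breeds, top$snp_id,
                              config$max_het_fraction)
    if (!is.null(odir)) write_fine_mapping(fm$runs, fm$interval,
                                           art("fine_mapping.tsv"))
    fm
  }, error = function(e) {
    out$skipped$finemap <<- conditionMessage(e)
    NULL
  })

  class(out) <- "run_report"
  if (!is.null(odir)) {
    writeLines(utils::capture.output(print(out)), art("run_report.txt"))
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("== across-breed mapping run report ==\n")
  cat(sprintf("seed: %d\n", x$seed))
  cat(sprintf("input: %d samples x %d SNPs\n", x$input_dim[1],
              x$input_dim[2]))
  if (!is.null(x$truth))
    cat(sprintf("simulated truth: causal %s (%s)\n",
                x$truth$causal_snp_id, x$truth$causal_chromosome))
  cat(format_qc_report(x$qc), "\n")
  if (!is.null(x$locus)) {
    print(x$locus)
  }
  if (!is.null(x$haplotypes)) {
    ht <- x$haplotypes$haplotype_tests
    if (nrow(ht)) {
      b <- ht[order(ht$p_chromosome, -ht$chi2)[1], ]
      cat(sprintf("top haplotype: %s %s:%d-%d, chi2 = %.2f, p_chromosome = %.3g\n",
                  b$haplotype, b$chromosome, b$start_bp, b$end_bp, b$chi2,
                  b$p_chromosome))
    }
  }
  if (!is.null(x$sweep)) {
    mn <- sweep_minimum(x$sweep)
    cat(sprintf("sweep minimum: %.3f at %s:%.0f\n", mn$normalized,
                mn$chromosome, mn$midpoint_bp))
  }
  if (!is.null(x$finemap)) {
    iv <- x$finemap$interval
    cat(sprintf("critical interval: %d-%d bp (%.1f kb) across %d breeds\n",
                iv$start_bp, iv$end_bp, iv$width_bp / 1000,
                length(iv$breeds)))
  }
  if (length(x$skipped)) {
    for (nm in names(x$skipped))
      cat(sprintf("stage %s skipped: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}
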