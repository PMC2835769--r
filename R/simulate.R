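# Multi-breed genotype simulator with known ground truth.
#
# Emulates the three statistical features the across-breed mapping design
# exploits: long within-breed LD (bottleneck founding + drift), short
# across-breed LD (breeds founded independently from a shared ancestral
# pool), and a causal locus fixed identical-by-descent in every affected
# breed with a surrounding sweep footprint of zero heterozygosity.

#' Simulation scenario configuration
#'
#' @param n_chromosomes number of chromosomes.
#' @param snps_per_chromosome SNPs per chromosome.
#' @param mean_spacing_bp mean inter-SNP spacing (bp); spacings are drawn
#'   from an exponential distribution (Poisson marker process).
#' @param ld_scale_bp decay scale (bp) of ancestral-pool LD: the latent
#'   allelic correlation between SNPs a distance d apart is exp(-d / scale).
#' @param pool_haplotypes number of ancestral haplotypes in the pool.
#' @param n_affected_breeds,n_control_breeds breed counts.
#' @param dogs_per_breed dogs per breed: a single count, or a list of two
#'   vectors (affected, control) giving per-breed counts.
#' @param founder_haplotypes_per_breed bottleneck size: haplotypes drawn
#'   from the pool to found each breed.
#' @param breed_population_haplotypes census size (in haplotypes) at which
#'   each breed drifts after the founding bottleneck; the founding
#'   bottleneck sets the identity-by-descent sharing, this size sets the
#'   residual within-breed heterozygosity.
#' @param drift_generations generations of random union with recombination
#'   within each breed after founding.
#' @param recomb_rate_per_bp crossover probability per bp per meiosis
#'   (default 1e-8, i.e. 1 cM/Mb).
#' @param causal_chromosome,causal_position_bp location of the causal
#'   locus (the nearest simulated SNP becomes the causal SNP).
#' @param sweep_core_bp extent of forced IBD sharing around the causal SNP
#'   in affected breeds; 0 disables the sweep (null mode).
#' @param erosion_mean_snps mean of the geometric per-breed erosion (in
#'   SNPs) of each flank of the planted core.
#' @param missing_rate fraction of calls masked missing.
#' @param seed integer master seed.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 5L, snps_per_chromosome = 400L,
                       mean_spacing_bp = 50000L, ld_scale_bp = 500000,
                       pool_haplotypes = 200L,
                       n_affected_breeds = 9L, n_control_breeds = 13L,
                       dogs_per_breed = 3L,
                       founder_haplotypes_per_breed = 10L,
                       breed_population_haplotypes = 50L,
                       drift_generations = 20L,
                       recomb_rate_per_bp = 1e-8,
                       causal_chromosome = "chr3",
                       causal_position_bp = 10000000L,
                       sweep_core_bp = 1000000L,
                       erosion_mean_snps = 2,
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              mean_spacing_bp = as.numeric(mean_spacing_bp),
              ld_scale_bp = as.numeric(ld_scale_bp),
              pool_haplotypes = as.integer(pool_haplotypes),
              n_affected_breeds = as.integer(n_affected_breeds),
              n_control_breeds = as.integer(n_control_breeds),
              dogs_per_breed = dogs_per_breed,
              founder_haplotypes_per_breed =
                as.integer(founder_haplotypes_per_breed),
              breed_population_haplotypes =
                as.integer(breed_population_haplotypes),
              drift_generations = as.integer(drift_generations),
              recomb_rate_per_bp = as.numeric(recomb_rate_per_bp),
              causal_chromosome = as.character(causal_chromosome),
              causal_position_bp = as.numeric(causal_position_bp),
              sweep_core_bp = as.numeric(sweep_core_bp),
              erosion_mean_snps = as.numeric(erosion_mean_snps),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_chromosomes", "snps_per_chromosome", "mean_spacing_bp",
           "ld_scale_bp", "pool_haplotypes", "n_affected_breeds",
           "n_control_breeds", "founder_haplotypes_per_breed",
           "breed_population_haplotypes")
  for (f in pos)
    if (cfg[[f]] <= 0) stopf("sim_config: %s must be positive", f)
  if (cfg$drift_generations < 0)
    stopf("sim_config: drift_generations must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stopf("sim_config: missing_rate must be in [0, 1)")
  if (cfg$sweep_core_bp < 0)
    stopf("sim_config: sweep_core_bp must be >= 0")
  chrs <- paste0("chr", seq_len(cfg$n_chromosomes))
  if (!(cfg$causal_chromosome %in% chrs))
    stopf("sim_config: causal_chromosome '%s' not among %s",
          cfg$causal_chromosome, paste(chrs, collapse = ", "))
  max_bp <- cfg$snps_per_chromosome * cfg$mean_spacing_bp * 2
  if (cfg$causal_position_bp < 1 || cfg$causal_position_bp > max_bp)
    stopf("sim_config: causal_position_bp outside its chromosome")
  dpb <- breed_sizes(cfg)
  if (any(c(dpb$affected, dpb$control) < 1))
    stopf("sim_config: dogs_per_breed must be >= 1 everywhere")
  if (cfg$founder_haplotypes_per_breed > cfg$pool_haplotypes)
    stopf("sim_config: founder count %d exceeds pool size %d",
          cfg$founder_haplotypes_per_breed, cfg$pool_haplotypes)
  invisible(cfg)
}

breed_sizes <- function(cfg) {
  d <- cfg$dogs_per_breed
  if (is.list(d)) {
    list(affected = as.integer(d[[1]]), control = as.integer(d[[2]]))
  } else {
    list(affected = rep(as.integer(d), cfg$n_affected_breeds),
         control = rep(as.integer(d), cfg$n_control_breeds))
  }
}

#' @export
print.sim_config <- function(x, ...) {
  sz <- breed_sizes(x)
  cat(sprintf("sim_config: %d chromosomes x %d SNPs (%g bp mean spacing)\n",
              x$n_chromosomes, x$snps_per_chromosome, x$mean_spacing_bp))
  cat(sprintf("  %d affected breeds (%d dogs), %d control breeds (%d dogs)\n",
              x$n_affected_breeds, sum(sz$affected),
              x$n_control_breeds, sum(sz$control)))
  cat(sprintf("  pool %d haplotypes (LD scale %g bp), founders %d, %d drift generations\n",
              x$pool_haplotypes, x$ld_scale_bp,
              x$founder_haplotypes_per_breed, x$drift_generations))
  cat(sprintf("  causal locus %s:%g, sweep core %g bp, missing rate %g, seed %d\n",
              x$causal_chromosome, x$causal_position_bp, x$sweep_core_bp,
              x$missing_rate, x$seed))
  invisible(x)
}

#' Desk-scale default scenario
#'
#' The study design this package targets: 9 affected and 13 control
#' breeds totalling 20 case and 31 control dogs, on a reduced genome of
#' 5 chromosomes x 400 SNPs at 50 kb mean spacing with 500 kb pool LD
#' (a desk-scale stand-in for a 38-autosome, 50K array), with a 1 Mb IBD
#' sweep core planted around the causal SNP.
#'
#' @param seed integer master seed.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
default_scenario <- function(seed = 1L, ...) {
  sim_config(n_chromosomes = 5L, snps_per_chromosome = 400L,
             mean_spacing_bp = 50000L, ld_scale_bp = 500000,
             n_affected_breeds = 9L, n_control_breeds = 13L,
             dogs_per_breed = list(c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 3L),
                                   c(3L, 3L, 3L, 3L, 3L,
                                     2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L)),
             founder_haplotypes_per_breed = 10L,
             drift_generations = 20L,
             causal_chromosome = "chr3", causal_position_bp = 10000000L,
             sweep_core_bp = 1000000L, erosion_mean_snps = 2,
             missing_rate = 0.02, seed = seed, ...)
}

#' Null-calibration scenario
#'
#' A scenario with no planted sweep (\code{sweep_core_bp = 0}) and
#' case/control status randomly assigned across single-dog breeds, so the
#' randomisation unit coincides with the unit permuted by the max-T test
#' and the permutation p-value is exact by construction.  Used to check
#' the calibration of the association machinery.
#'
#' @param seed integer master seed (also randomises the status
#'   assignment).
#' @param n_breeds total number of single-dog breeds (half assigned case).
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
null_scenario <- function(seed = 1L, n_breeds = 24L, ...) {
  n_breeds <- as.integer(n_breeds)
  n_case <- n_breeds %/% 2L
  sim_config(n_chromosomes = 2L, snps_per_chromosome = 100L,
             mean_spacing_bp = 50000L, ld_scale_bp = 500000,
             n_affected_breeds = n_case,
             n_control_breeds = n_breeds - n_case,
             dogs_per_breed = 1L,
             founder_haplotypes_per_breed = 10L,
             drift_generations = 10L,
             causal_chromosome = "chr1", causal_position_bp = 2500000L,
             sweep_core_bp = 0, missing_rate = 0.02, seed = seed, ...)
}

#' Simulate the ancestral haplotype pool
#'
#' Per-SNP allele frequencies are drawn from a U-shaped Beta(0.5, 0.5)
#' rescaled to (0.05, 0.95); haplotypes come from a first-order latent
#' Gaussian process whose correlation between adjacent SNPs decays as
#' \code{exp(-distance / ld_scale_bp)}, thresholded at each SNP's allele
#' frequency quantile.
#'
#' @param config a \code{sim_config}.
#' @return A list of class \code{ancestral_pool} with one element per
#'   chromosome: \code{haplotypes} (pool x SNPs 0/1 matrix),
#'   \code{positions}, \code{freq}.
#' @export
simulate_ancestral_pool <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    pool <- lapply(seq_len(config$n_chromosomes), function(ci) {
      m <- config$snps_per_chromosome
      gaps <- pmax(1, round(stats::rexp(m, rate = 1 / config$mean_spacing_bp)))
      positions <- cumsum(gaps)
      freq <- 0.05 + 0.9 * stats::rbeta(m, 0.5, 0.5)
      r <- if (m > 1) exp(-diff(positions) / config$ld_scale_bp) else numeric(0)
      H <- config$pool_haplotypes
      lat <- matrix(stats::rnorm(H * m), H, m)
      if (m > 1) {
        for (j in 2:m) {
          lat[, j] <- r[j - 1] * lat[, j - 1] +
            sqrt(1 - r[j - 1]^2) * lat[, j]
        }
      }
      thr <- stats::qnorm(freq)
      haps <- matrix(0L, H, m)
      haps[lat < rep(thr, each = H)] <- 1L
      list(haplotypes = haps, positions = as.integer(positions), freq = freq)
    })
    names(pool) <- paste0("chr", seq_len(config$n_chromosomes))
    structure(pool, class = "ancestral_pool")
  })
}

# one generation of random union with recombination within a haplotype
# pool; produces n_out offspring haplotypes (expansion after bottleneck)
drift_generation <- function(haps, crossover_p, n_out = nrow(haps)) {
  H <- nrow(haps); m <- ncol(haps)
  p1 <- sample.int(H, n_out, replace = TRUE)
  p2 <- sample.int(H, n_out, replace = TRUE)
  start <- sample.int(2L, n_out, replace = TRUE) - 1L
  src <- matrix(start, n_out, m)
  if (m > 1) {
    # crossovers are rare; draw per-gap counts and scatter them
    cnt <- stats::rbinom(m - 1L, n_out, crossover_p)
    for (j in which(cnt > 0L)) {
      rows <- sample.int(n_out, cnt[j])
      src[rows, (j + 1L):m] <- src[rows, (j + 1L):m] + 1L
    }
    src <- src %% 2L
  }
  g1 <- haps[p1, , drop = FALSE]
  g2 <- haps[p2, , drop = FALSE]
  out <- g1
  out[src == 1L] <- g2[src == 1L]
  out
}

#' Simulate multi-breed genotype data with ground truth
#'
#' Each breed is founded from \code{founder_haplotypes_per_breed} pool
#' haplotypes and drifts for \code{drift_generations} generations of
#' random union with recombination (crossover probability per adjacent
#' SNP pair proportional to spacing).  In affected breeds both haplotypes
#' of every dog are overwritten with one planted ancestral haplotype
#' across the sweep core around the causal SNP (IBD fixation shared by
#' all affected breeds), with per-breed geometric erosion of the core's
#' flanks.  Calls are then masked missing at \code{missing_rate} and
#' status is assigned by breed (trait fixed within breeds).
#'
#' @param config a \code{sim_config}.
#' @return A list with \code{dataset} (a \code{genotype_dataset}) and
#'   \code{truth} (class \code{sim_truth}): causal SNP id/position,
#'   affected breeds, the planted core interval (bp, after the widest
#'   possible extent, pre-erosion) and per-breed planted intervals.
#' @export
simulate_breeds <- function(config) {
  validate_sim_config(config)
  pool <- simulate_ancestral_pool(config)
  seeds <- derive_seeds(config$seed + 1L, 4L)
  sz <- breed_sizes(config)
  n_breeds <- config$n_affected_breeds + config$n_control_breeds
  breeds <- c(paste0("aff", seq_len(config$n_affected_breeds)),
              paste0("ctl", seq_len(config$n_control_breeds)))
  affected <- c(rep(TRUE, config$n_affected_breeds),
                rep(FALSE, config$n_control_breeds))
  dogs <- c(sz$affected, sz$control)

  positions <- lapply(pool, `[[`, "positions")
  all_m <- vapply(positions, length, 0L)
  chr_names <- names(pool)

  # causal SNP: nearest simulated SNP to the requested position
  cc <- config$causal_chromosome
  cpos <- positions[[cc]]
  causal_j <- which.min(abs(cpos - config$causal_position_bp))
  # the trait allele arose once on an ancestral haplotype and is swept to
  # fixation only in affected breeds, so it should be the rarer allele in
  # the pool: relabel alleles at the causal column if needed (a pure
  # 0/1 swap, LD structure untouched)
  if (mean(pool[[cc]]$haplotypes[, causal_j]) > 0.5) {
    pool[[cc]]$haplotypes[, causal_j] <- 1L - pool[[cc]]$haplotypes[, causal_j]
    pool[[cc]]$freq[causal_j] <- 1 - pool[[cc]]$freq[causal_j]
  }
  if (config$sweep_core_bp > 0) {
    core_lo <- config$causal_position_bp - config$sweep_core_bp / 2
    core_hi <- config$causal_position_bp + config$sweep_core_bp / 2
    core_snps <- sort(union(which(cpos >= core_lo & cpos <= core_hi),
                            causal_j))
  } else {
    core_snps <- integer(0)
  }

  sim <- with_seed(seeds[1], {
    # planted haplotype: one pool haplotype, forced to carry the derived
    # allele at the causal SNP
    planted <- lapply(chr_names, function(chr)
      pool[[chr]]$haplotypes[sample.int(config$pool_haplotypes, 1L), ])
    names(planted) <- chr_names
    planted[[cc]][causal_j] <- 1L

    crossover <- lapply(chr_names, function(chr) {
      d <- diff(positions[[chr]])
      pmin(0.5, d * config$recomb_rate_per_bp)
    })
    names(crossover) <- chr_names

    breed_haps <- vector("list", n_breeds)
    for (b in seq_len(n_breeds)) {
      breed_haps[[b]] <- lapply(chr_names, function(chr) {
        founders <- sample.int(config$pool_haplotypes,
                               config$founder_haplotypes_per_breed)
        haps <- pool[[chr]]$haplotypes[founders, , drop = FALSE]
        # bottleneck founding, then drift at the breed census size
        P <- config$breed_population_haplotypes
        for (g in seq_len(config$drift_generations))
          haps <- drift_generation(haps, crossover[[chr]], n_out = P)
        haps
      })
      names(breed_haps[[b]]) <- chr_names
    }
    list(planted = planted, breed_haps = breed_haps)
  })

  # per-breed eroded core intervals
  breed_core <- with_seed(seeds[2], {
    lapply(seq_len(n_breeds), function(b) {
      if (!affected[b] || config$sweep_core_bp <= 0 ||
          length(core_snps) == 0L)
        return(integer(0))
      lo <- 1L; hi <- length(core_snps)
      cj <- match(causal_j, core_snps)
      if (config$erosion_mean_snps > 0) {
        p <- 1 / (1 + config$erosion_mean_snps)
        lo <- min(lo + stats::rgeom(1, p), cj)
        hi <- max(hi - stats::rgeom(1, p), cj)
      }
      core_snps[lo:hi]
    })
  })

  n_total <- sum(dogs)
  calls <- NULL
  sample_breed <- rep(breeds, dogs)
  status <- rep(ifelse(affected, "case", "control"), dogs)

  calls <- with_seed(seeds[3], {
    per_chr <- lapply(chr_names, function(chr) {
      m <- length(positions[[chr]])
      G <- matrix(0L, n_total, m)
      row <- 0L
      for (b in seq_len(n_breeds)) {
        haps <- sim$breed_haps[[b]][[chr]]
        H <- nrow(haps)
        for (dg in seq_len(dogs[b])) {
          row <- row + 1L
          pick <- sample.int(H, 2, replace = TRUE)
          h1 <- haps[pick[1], ]; h2 <- haps[pick[2], ]
          if (chr == cc && length(breed_core[[b]]) > 0L) {
            h1[breed_core[[b]]] <- sim$planted[[cc]][breed_core[[b]]]
            h2[breed_core[[b]]] <- sim$planted[[cc]][breed_core[[b]]]
          }
          G[row, ] <- h1 + h2
        }
      }
      G
    })
    do.call(cbind, per_chr)
  })

  if (config$missing_rate > 0) {
    calls <- with_seed(seeds[4], {
      mask <- matrix(stats::runif(length(calls)) < config$missing_rate,
                     nrow(calls))
      calls[mask] <- NA_integer_
      calls
    })
  }

  snps <- data.frame(
    snp_id = unlist(lapply(chr_names, function(chr)
      paste0(chr, ".", positions[[chr]]))),
    chromosome = rep(chr_names, all_m),
    position_bp = unlist(positions),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_d%d", sample_breed,
                        unlist(lapply(dogs, seq_len))),
    breed = sample_breed,
    status = status,
    stringsAsFactors = FALSE)

  dataset <- genotype_dataset(calls, samples, snps)
  truth <- structure(list(
    causal_snp_id = paste0(cc, ".", cpos[causal_j]),
    causal_chromosome = cc,
    causal_position_bp = cpos[causal_j],
    affected_breeds = breeds[affected],
    core_start_bp = if (length(core_snps)) cpos[core_snps[1]] else NA,
    core_end_bp = if (length(core_snps)) cpos[core_snps[length(core_snps)]]
                  else NA,
    core_snp_ids = if (length(core_snps)) paste0(cc, ".", cpos[core_snps])
                   else character(0),
    planted_haplotype = if (length(core_snps))
      paste(c("A", "B")[sim$planted[[cc]][core_snps] + 1L], collapse = "")
      else "",
    breed_core_snp_ids = lapply(breed_core[affected], function(js)
      if (length(js)) paste0(cc, ".", cpos[js]) else character(0))),
    class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: causal SNP %s at %s:%d\n", x$causal_snp_id,
              x$causal_chromosome, x$causal_position_bp))
  cat(sprintf("  planted core: %s-%s bp (%d SNPs)\n",
              format(x$core_start_bp), format(x$core_end_bp),
              length(x$core_snp_ids)))
  cat(sprintf("  affected breeds: %s\n",
              paste(x$affected_breeds, collapse = ", ")))
  invisible(x)
}

#' Write simulator ground truth as TSV
#' @param truth a \code{sim_truth}.
#' @param path output path.
#' @return Invisibly, the truth object.
#' @export
write_sim_truth <- function(truth, path) {
  df <- data.frame(
    field = c("causal_snp_id", "causal_chromosome", "causal_position_bp",
              "core_start_bp", "core_end_bp", "affected_breeds",
              "planted_haplotype"),
    value = c(truth$causal_snp_id, truth$causal_chromosome,
              truth$causal_position_bp, truth$core_start_bp,
              truth$core_end_bp,
              paste(truth$affected_breeds, collapse = ","),
              truth$planted_haplotype))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
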