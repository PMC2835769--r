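#' Read genotypes from PLINK-style PED/MAP text files
#'
#' Parses whitespace-separated PED/MAP files into a
#' \code{\link{genotype_dataset}}.  The PED family-ID column is interpreted
#' as the breed label, the phenotype column as 2 = case, 1 = control and
#' 0 or -9 = unknown.  For each SNP the minor allele is determined from
#' allele frequencies across the whole file and genotypes are stored as
#' minor-allele counts; \code{"0 0"} allele pairs become missing.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (columns: chromosome, snp_id,
#'   optionally genetic distance, position in bp).
#' @return A \code{genotype_dataset}.
#' @seealso \code{\link{write_ped_map}}
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stopf("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stopf("MAP file not found: %s", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (length(nf) && !all(nf %in% c(3L, 4L)))
    stopf("MAP row %d has %d fields (expected 3 or 4)",
          which(!(nf %in% c(3L, 4L)))[1], nf[!(nf %in% c(3L, 4L))][1])
  snps <- data.frame(
    snp_id = vapply(map_fields, `[`, "", 2L),
    chromosome = vapply(map_fields, `[`, "", 1L),
    position_bp = as.integer(vapply(map_fields, function(f) f[length(f)], "")),
    stringsAsFactors = FALSE)
  m <- nrow(snps)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  samples <- data.frame(sample_id = character(n), breed = character(n),
                        status = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stopf("PED row %d has %d fields; expected %d (6 + 2 per SNP)",
            i, length(f), 6L + 2L * m)
    samples$breed[i] <- f[1]
    samples$sample_id[i] <- f[2]
    samples$status[i] <- switch(f[6], "2" = "case", "1" = "control",
                                NA_character_)
    if (m > 0L) {
      a1[i, ] <- f[seq(7L, by = 2L, length.out = m)]
      a2[i, ] <- f[seq(8L, by = 2L, length.out = m)]
    }
  }
  if (anyDuplicated(samples$sample_id))
    samples$sample_id <- paste(samples$breed, samples$sample_id, sep = "_")

  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    sym <- sort(unique(obs))
    if (length(sym) > 2L)
      stopf("SNP '%s' has %d allele symbols (%s); only biallelic SNPs supported",
            snps$snp_id[j], length(sym), paste(sym, collapse = ","))
    if (length(sym) == 0L) next  # all missing
    counts <- table(factor(obs, levels = sym))
    # minor allele: lower count; tie broken towards the later-sorting
    # symbol so that A/B round-trips (A = major by convention).
    minor <- if (length(sym) == 1L) NA_character_
             else if (counts[1] < counts[2]) sym[1]
             else sym[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    if (is.na(minor)) {
      calls[!miss, j] <- 0L
    } else {
      calls[!miss, j] <- (a1[!miss, j] == minor) + (a2[!miss, j] == minor)
    }
  }
  genotype_dataset(calls, samples, snps)
}

#' Write a genotype dataset to PED/MAP files
#'
#' Allele symbols are fixed as A = major, B = minor, so
#' \code{read_ped_map(write_ped_map(x))} reproduces \code{x} exactly.
#' Missing calls are written as \code{"0 0"}; unknown status as phenotype 0.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the input dataset.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- n_samples(dataset); m <- n_snps(dataset)
  map <- sprintf("%s\t%s\t0\t%d",
                 dataset$snps$chromosome, dataset$snps$snp_id,
                 dataset$snps$position_bp)
  ok <- tryCatch({
    writeLines(map, map_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write MAP file: %s", map_path)

  pheno <- ifelse(is.na(dataset$samples$status), "0",
                  ifelse(dataset$samples$status == "case", "2", "1"))
  geno_txt <- character(n)
  if (m > 0L) {
    for (i in seq_len(n)) {
      g <- dataset$calls[i, ]
      first <- ifelse(is.na(g), "0", ifelse(g == 2L, "B", "A"))
      second <- ifelse(is.na(g), "0", ifelse(g >= 1L, "B", "A"))
      geno_txt[i] <- paste(rbind(first, second), collapse = " ")
    }
  }
  rows <- if (n == 0L) character(0) else
    trimws(paste(dataset$samples$breed, dataset$samples$sample_id,
                 "0", "0", "0", pheno,
                 if (m > 0L) geno_txt else rep("", n)))
  ok <- tryCatch({
    writeLines(rows, ped_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write PED file: %s", ped_path)
  invisible(dataset)
}
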