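#' Read and write genotypes as a plain TSV table
#'
#' One row per variant: `id`, `chrom`, `pos`, `a1`, `a2`, then one dosage
#' column per individual (`NA` for missing calls).
#'
#' @param g A [genotype_matrix()].
#' @param path File path.
#' @return `read_genotypes_tsv()` returns a [genotype_matrix()];
#'   `write_genotypes_tsv()` returns `path` invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  tab <- cbind(g$variants, as.data.frame(t(g$dosage)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  meta_cols <- c("id", "chrom", "pos", "a1", "a2")
  variants <- tab[, meta_cols]
  variants$chrom <- as.character(variants$chrom)
  dosage <- t(as.matrix(tab[, setdiff(names(tab), meta_cols),
                            drop = FALSE]))
  genotype_matrix(dosage, rownames(dosage), variants)
}

#' Read and write PLINK bed/bim/fam filesets
#'
#' Minimal implementation of the variant-major PLINK 1 binary layout:
#' the two-bit codes `00`/`10`/`11` map to 2/1/0 copies of the bim A1
#' allele and `01` to a missing call. `write_plink()` emits
#' `<prefix>.bed`, `.bim` (chrom, id, 0, pos, a1, a2) and `.fam`
#' (id used as both family and individual id).
#'
#' @param g A [genotype_matrix()].
#' @param prefix Path prefix without extension.
#' @return `read_plink()` returns a [genotype_matrix()]; `write_plink()`
#'   returns `prefix` invisibly.
#' @export
write_plink <- function(g, prefix) {
  variants <- g$variants
  utils::write.table(
    data.frame(variants$chrom, variants$id, 0, variants$pos,
               variants$a1, variants$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$individual_ids, g$individual_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  n <- length(g$individual_ids)
  codes <- c(`2` = 0L, miss = 1L, `1` = 2L, `0` = 3L)  # two-bit values
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(ncol(g$dosage))) {
    x <- g$dosage[, j]
    code <- ifelse(is.na(x), 1L, ifelse(x == 2, 0L, ifelse(x == 1, 2L, 3L)))
    pad <- (4 - n %% 4) %% 4
    code <- c(code, rep(0L, pad))
    quads <- matrix(code, nrow = 4)
    bytes <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * ceiling(n / 4))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a variant-major PLINK .bed file")
  }
  body <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n / 4)
  lookup <- c(2, NA, 1, 0)  # two-bit code -> dosage of A1
  dosage <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1) * bpv + 1):(j * bpv)]
    code <- c(rbind(bytes %% 4, bytes %/% 4 %% 4, bytes %/% 16 %% 4,
                    bytes %/% 64))[seq_len(n)]
    dosage[, j] <- lookup[code + 1]
  }
  variants <- data.frame(id = bim$id, chrom = as.character(bim$chrom),
                         pos = bim$pos, a1 = bim$a1, a2 = bim$a2,
                         stringsAsFactors = FALSE)
  genotype_matrix(dosage, as.character(fam$V2), variants)
}

#' Read and write GWAS summary statistics
#'
#' TSV with columns `SNP`, `CHR`, `BP`, `A1` (effect allele), `A2`, `OR`,
#' `P`. `CHR`/`BP` are written as 0 when unknown.
#'
#' @param ss A `summary_stats` data frame.
#' @param path File path.
#' @param variants Optional variant table supplying `CHR`/`BP` on write.
#' @return `read_sumstats()` returns a `summary_stats` data frame;
#'   `write_sumstats()` returns `path` invisibly.
#' @export
write_sumstats <- function(ss, path, variants = NULL) {
  chr <- bp <- rep(0, nrow(ss))
  if (!is.null(variants)) {
    i <- match(ss$id, variants$id)
    chr <- ifelse(is.na(i), 0, variants$chrom[i])
    bp <- ifelse(is.na(i), 0, variants$pos[i])
  }
  tab <- data.frame(SNP = ss$id, CHR = chr, BP = bp,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    OR = ss$or, P = ss$p)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(id = as.character(tab$SNP),
                    effect_allele = tab$A1, other_allele = tab$A2,
                    or = tab$OR, p = tab$P, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  validate_summary_stats(out)
  out
}

#' Read and write the trial cohort as CSV
#'
#' One row per individual-timepoint, individual-level covariates
#' repeated on each row.
#'
#' @param cohort A `trial_cohort`.
#' @param path File path.
#' @param timepoints Timepoint ordering used when reading; defaults to
#'   order of first appearance.
#' @return `read_cohort_csv()` returns a `trial_cohort`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- merge(cohort$outcomes, cohort$individuals, by = "id")
  d <- d[order(match(d$id, cohort$individuals$id),
               as.integer(d$timepoint)), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, timepoints = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(timepoints)) timepoints <- unique(d$timepoint)
  ind_cols <- setdiff(names(d), c("timepoint", "srs_total"))
  individuals <- unique(d[, ind_cols])
  rownames(individuals) <- NULL
  individuals$arm <- factor(individuals$arm,
                            levels = c("standard_care", "SSGT"))
  individuals$center <- factor(individuals$center)
  individuals$age_group <- factor(individuals$age_group,
                                  levels = c("child", "adolescent"))
  individuals$sex <- factor(individuals$sex, levels = c("male", "female"))
  outcomes <- d[, c("id", "timepoint", "srs_total")]
  outcomes$timepoint <- factor(outcomes$timepoint, levels = timepoints)
  rownames(outcomes) <- NULL
  cohort <- structure(list(individuals = individuals, outcomes = outcomes),
                      class = "trial_cohort")
  validate_trial_cohort(cohort)
  cohort
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then gene ids. The
#' description field is kept as the set's category when non-empty.
#'
#' @param path File path.
#' @return Named list of gene-id vectors with attribute `"category"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  attr(sets, "category") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Read a gene-location table
#'
#' Whitespace-separated columns: gene id, chromosome, start, end
#' (1-based inclusive).
#'
#' @param path File path.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_loc <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene_id", "chrom", "start",
                                         "end"))
  tab$chrom <- as.character(tab$chrom)
  if (any(tab$start > tab$end)) stop("gene start must be <= end")
  tab
}

#' Write PRS profiles as TSV
#'
#' One row per individual: id, then a raw and (if standardized) a z
#' column per threshold.
#'
#' @param profile A `prs_profile`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_prs_tsv <- function(profile, path) {
  tab <- data.frame(id = profile$individual_ids, profile$raw,
                    check.names = FALSE)
  colnames(tab) <- c("id", paste0("raw_", colnames(profile$raw)))
  if (!is.null(profile$z)) {
    z <- as.data.frame(profile$z)
    colnames(z) <- paste0("z_", colnames(profile$z))
    tab <- cbind(tab, z)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the generator truth record as JSON
#'
#' @param truth The `"truth"` attribute of a simulated cohort.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
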