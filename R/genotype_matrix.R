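#' Additive genotype matrix
#'
#' The central genotype container: an individuals x variants matrix of
#' additive dosages (number of copies of the counted allele, `0`, `1`, `2`,
#' or `NA` for a failed call) together with variant metadata.
#'
#' @param dosage Numeric matrix, individuals in rows, variants in columns.
#'   Values must be in `{0, 1, 2, NA}`.
#' @param individual_ids Character vector of unique individual identifiers,
#'   one per row of `dosage`.
#' @param variants Data frame with one row per column of `dosage` and
#'   columns `id`, `chrom`, `pos` (1-based bp), `a1` (counted allele) and
#'   `a2` (other allele).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `individual_ids` and `variants`.
#' @export
genotype_matrix <- function(dosage, individual_ids, variants) {
  dosage <- as.matrix(dosage)
  individual_ids <- as.character(individual_ids)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(required %in% names(variants))) {
    stop("variants must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(dosage) != length(individual_ids)) {
    stop("dosage has ", nrow(dosage), " rows but ", length(individual_ids),
         " individual ids were given")
  }
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " columns but ", nrow(variants),
         " variant records were given")
  }
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(!is.na(variants$a1) & variants$a1 == variants$a2)) {
    stop("counted and other allele must differ")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  dimnames(dosage) <- list(individual_ids, variants$id)
  structure(
    list(dosage = dosage, individual_ids = individual_ids,
         variants = variants),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$individual_ids), " individuals x ",
      nrow(x$variants), " variants\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  missing call rate: ", format(miss, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Counted-allele frequency and minor allele frequency
#'
#' Frequencies are computed on non-missing calls only.
#'
#' @param g A [genotype_matrix()].
#' @return `allele_freq()` returns the per-variant frequency of the counted
#'   allele; `maf()` folds it to the minor allele frequency
#'   (`pmin(f, 1 - f)`).
#' @export
allele_freq <- function(g) {
  colMeans(g$dosage, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
maf <- function(g) {
  f <- allele_freq(g)
  pmin(f, 1 - f)
}

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param individuals,variants Logical, integer, or character index of
#'   individuals / variants to keep; `NULL` keeps all.
#' @return A [genotype_matrix()] restricted to the selection.
#' @export
subset_genotypes <- function(g, individuals = NULL, variants = NULL) {
  ii <- if (is.null(individuals)) seq_along(g$individual_ids) else individuals
  if (is.character(ii)) ii <- match(ii, g$individual_ids)
  vi <- if (is.null(variants)) seq_len(nrow(g$variants)) else variants
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  genotype_matrix(g$dosage[ii, vi, drop = FALSE],
                  g$individual_ids[ii],
                  g$variants[vi, , drop = FALSE])
}

#' Maximum attainable total score of the outcome scale
#'
#' The parent-reported Social Responsiveness Scale has 65 Likert items
#' scored 0-3, so totals range from 0 to 195.
#'
#' @param n_items Number of items on the scale.
#' @param item_max Maximum score per item.
#' @return The maximum total score (195 for the default SRS layout).
#' @export
srs_max_total <- function(n_items = 65, item_max = 3) {
  stopifnot(n_items >= 1, item_max >= 1)
  n_items * item_max
}
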