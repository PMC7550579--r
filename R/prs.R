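#' PRS construction parameters
#'
#' @param thresholds Strictly increasing P-value inclusion thresholds in
#'   `(0, 1]`; a variant enters the score at threshold `Pt` when its GWAS
#'   P value is strictly below `Pt`. Defaults to the five conventional
#'   cutoffs 0.01, 0.05, 0.1, 0.5 and 1.
#' @param clump_r2 Dosage r-squared at or above which a variant is claimed
#'   by a more significant index variant.
#' @param clump_window_kb Clumping window: a variant is inside an index's
#'   window iff the absolute position difference is at most
#'   `clump_window_kb * 1000` bp on the same chromosome.
#' @param palindromic_policy `"keep"` scores palindromic (A/T, C/G)
#'   variants like any other; `"drop"` excludes them during
#'   harmonization (advisable for real strand-ambiguous data).
#' @param missing_dosage `"mean"` substitutes the variant's mean oriented
#'   dosage for missing calls; `"omit"` drops missing calls from the sum.
#' @return A list of class `prs_config`.
#' @export
prs_config <- function(thresholds = c(0.01, 0.05, 0.1, 0.5, 1),
                       clump_r2 = 0.1, clump_window_kb = 500,
                       palindromic_policy = c("keep", "drop"),
                       missing_dosage = c("mean", "omit")) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must be strictly increasing and in (0, 1]")
  }
  if (clump_r2 < 0 || clump_r2 > 1) stop("clump_r2 must be in [0, 1]")
  structure(list(thresholds = thresholds, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 palindromic_policy = match.arg(palindromic_policy),
                 missing_dosage = match.arg(missing_dosage)),
            class = "prs_config")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

is_palindromic <- function(a1, a2) {
  !is.na(complement_allele(a1)) & complement_allele(a1) == a2
}

#' Harmonize summary statistics with genotype alleles
#'
#' Matches variants by id and reconciles the genotype's counted allele
#' with the GWAS effect allele. When the counted allele is the GWAS other
#' allele, the orientation map marks the dosage for reflection
#' (`2 - dosage`). Strand-complemented matches are accepted; allele pairs
#' that cannot be reconciled are dropped and logged, as are palindromic
#' variants under `palindromic_policy = "drop"`.
#'
#' @param ss A `summary_stats` data frame.
#' @param g A [genotype_matrix()].
#' @param cfg A [prs_config()]; only the palindromic policy is used.
#' @return List: `summary` (harmonized stats, in genotype variant order),
#'   `orientation` (named `"as_is"`/`"flip"` vector) and `dropped`
#'   (data frame of excluded variants with reasons).
#' @export
harmonize_sumstats <- function(ss, g, cfg = prs_config()) {
  validate_summary_stats(ss)
  shared <- intersect(g$variants$id, ss$id)
  if (length(shared) == 0) {
    stop("no variants shared between summary statistics and genotypes")
  }
  gv <- g$variants[match(shared, g$variants$id), ]
  sv <- ss[match(shared, ss$id), ]

  orientation <- rep(NA_character_, length(shared))
  reason <- rep(NA_character_, length(shared))
  pal <- is_palindromic(gv$a1, gv$a2)
  ca1 <- complement_allele(gv$a1)
  ca2 <- complement_allele(gv$a2)

  as_is <- (gv$a1 == sv$effect_allele & gv$a2 == sv$other_allele)
  flip <- (gv$a1 == sv$other_allele & gv$a2 == sv$effect_allele)
  as_is_c <- !is.na(ca1) & !is.na(ca2) &
    ca1 == sv$effect_allele & ca2 == sv$other_allele
  flip_c <- !is.na(ca1) & !is.na(ca2) &
    ca1 == sv$other_allele & ca2 == sv$effect_allele

  orientation[as_is | as_is_c] <- "as_is"
  orientation[(flip | flip_c) & is.na(orientation)] <- "flip"
  reason[is.na(orientation)] <- "allele_mismatch"
  if (cfg$palindromic_policy == "drop") {
    reason[pal & is.na(reason)] <- "palindromic"
    orientation[pal] <- NA_character_
  }

  keep <- is.na(reason)
  if (!any(keep)) stop("no variants could be harmonized")
  dropped <- data.frame(id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out_ss <- sv[keep, , drop = FALSE]
  rownames(out_ss) <- NULL
  class(out_ss) <- c("summary_stats", "data.frame")
  list(summary = out_ss,
       orientation = stats::setNames(orientation[keep], shared[keep]),
       dropped = dropped)
}

dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest GWAS P value
#' as an index (ties broken by position, then id) and claims every
#' unclaimed variant on the same chromosome within the window whose dosage
#' r-squared with the index is at least `clump_r2`. Index variants form
#' the retained set; no two retained variants on the same chromosome
#' within the window have r-squared at or above the cutoff.
#'
#' @param ss Harmonized `summary_stats` (all ids must be present in `g`).
#' @param g A [genotype_matrix()] supplying the LD (r-squared over
#'   pairwise-complete dosages).
#' @param cfg A [prs_config()].
#' @return Character vector of retained variant ids.
#' @export
ld_clump <- function(ss, g, cfg = prs_config()) {
  idx <- match(ss$id, g$variants$id)
  if (anyNA(idx)) stop("summary variants missing from the genotype matrix")
  v <- g$variants[idx, ]
  window_bp <- cfg$clump_window_kb * 1000
  ord <- order(ss$p, v$pos, ss$id)
  claimed <- rep(FALSE, nrow(ss))
  retained <- character(0)
  for (k in ord) {
    if (claimed[k]) next
    claimed[k] <- TRUE
    retained <- c(retained, ss$id[k])
    near <- which(!claimed & v$chrom == v$chrom[k] &
                    abs(v$pos - v$pos[k]) <= window_bp)
    if (length(near)) {
      x <- g$dosage[, idx[k]]
      hit <- vapply(near, function(j) {
        dosage_r2(x, g$dosage[, idx[j]]) >= cfg$clump_r2
      }, logical(1))
      claimed[near[hit]] <- TRUE
    }
  }
  retained
}

#' Compute raw polygenic scores at each threshold
#'
#' For each threshold `Pt`, an individual's score is the sum over retained
#' variants with GWAS P strictly below `Pt` of `log(OR)` times the
#' oriented dosage (reflected to `2 - dosage` where the orientation map
#' says `"flip"`). Missing calls contribute the variant's mean oriented
#' dosage among non-missing individuals (or nothing, under
#' `missing_dosage = "omit"`).
#'
#' @param g A [genotype_matrix()].
#' @param harmonized Result of [harmonize_sumstats()].
#' @param retained Variant ids surviving [ld_clump()]; must be a subset of
#'   the harmonized variants.
#' @param cfg A [prs_config()].
#' @return A `prs_profile`: list with `raw` (individuals x thresholds
#'   matrix), `n_snps_used`, `thresholds` and `individual_ids`.
#' @export
prs_score <- function(g, harmonized, retained, cfg = prs_config()) {
  ss <- harmonized$summary
  if (!all(retained %in% ss$id)) {
    stop("retained variants must be a subset of the harmonized set")
  }
  ss <- ss[ss$id %in% retained, , drop = FALSE]
  orient <- harmonized$orientation[ss$id]
  gi <- match(ss$id, g$variants$id)
  d <- g$dosage[, gi, drop = FALSE]
  flip <- orient == "flip"
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  if (anyNA(d)) {
    if (cfg$missing_dosage == "mean") {
      mu <- colMeans(d, na.rm = TRUE)
      na_idx <- which(is.na(d), arr.ind = TRUE)
      d[na_idx] <- mu[na_idx[, 2]]
    } else {
      d[is.na(d)] <- 0
    }
  }
  w <- log(ss$or)
  nthr <- length(cfg$thresholds)
  raw <- matrix(0, nrow(d), nthr,
                dimnames = list(g$individual_ids,
                                paste0("Pt_", cfg$thresholds)))
  n_used <- integer(nthr)
  for (t in seq_len(nthr)) {
    sel <- ss$p < cfg$thresholds[t]
    n_used[t] <- sum(sel)
    if (n_used[t] == 0) {
      warning("threshold ", cfg$thresholds[t], " selects no variants; ",
              "scores set to 0")
      next
    }
    raw[, t] <- as.numeric(d[, sel, drop = FALSE] %*% w[sel])
  }
  structure(list(raw = raw,
                 n_snps_used = stats::setNames(n_used, colnames(raw)),
                 thresholds = cfg$thresholds,
                 individual_ids = g$individual_ids),
            class = "prs_profile")
}

#' Standardize polygenic scores
#'
#' Per threshold, `z = (raw - mean) / sd` with the sample SD
#' (denominator `n - 1`), so each column has mean 0 and SD 1.
#'
#' @param profile A `prs_profile` from [prs_score()].
#' @return The profile with a `z` matrix added.
#' @export
prs_standardize <- function(profile) {
  raw <- profile$raw
  if (nrow(raw) < 2) stop("standardization needs at least 2 individuals")
  s <- apply(raw, 2, stats::sd)
  zero <- s == 0 & profile$n_snps_used > 0
  if (any(zero)) {
    stop("zero score variance at threshold(s): ",
         paste(colnames(raw)[zero], collapse = ", "))
  }
  z <- raw
  for (t in seq_len(ncol(raw))) {
    z[, t] <- if (s[t] == 0) 0 else (raw[, t] - mean(raw[, t])) / s[t]
  }
  profile$z <- z
  profile
}

#' @exportS3Method base::print
print.prs_profile <- function(x, ...) {
  cat("<prs_profile> ", length(x$individual_ids), " individuals, thresholds: ",
      paste(x$thresholds, collapse = ", "), "\n", sep = "")
  cat("  SNPs used:", paste(x$n_snps_used, collapse = ", "), "\n")
  cat(if (is.null(x$z)) "  raw only\n" else "  standardized\n")
  invisible(x)
}

#' Full clump-and-threshold PRS pipeline
#'
#' Harmonizes, clumps, scores and standardizes in one call.
#'
#' @inheritParams harmonize_sumstats
#' @return A standardized `prs_profile` with attributes `retained`
#'   (clumped variant ids) and `dropped` (harmonization exclusions).
#' @export
compute_prs <- function(ss, g, cfg = prs_config()) {
  h <- harmonize_sumstats(ss, g, cfg)
  retained <- ld_clump(h$summary, g, cfg)
  profile <- prs_standardize(prs_score(g, h, retained, cfg))
  attr(profile, "retained") <- retained
  attr(profile, "dropped") <- h$dropped
  profile
}
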