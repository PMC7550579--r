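#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype counts of a biallelic marker.
#' Given the allele counts, the probability of each admissible heterozygote
#' count (same parity as the minor-allele count) is computed from the
#' hypergeometric-type conditional distribution via the standard
#' ratio recurrence, and the P value is the sum of probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return The exact two-sided P value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n == 0) stop("at least one genotype is required")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa   # minor allele count
  if (n_rare == 0) return(1)

  # admissible heterozygote counts share the parity of n_rare
  het <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(het))
  # start from the mid-range het count for numerical stability
  start <- which.min(abs(het - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[start] <- 1
  # P(h+2)/P(h) = [h_rare_hom * h_comm_hom * 4] / [(h+2)(h+1)], with
  # hom counts implied by the fixed allele totals
  if (start < length(het)) {
    for (k in start:(length(het) - 1)) {
      h <- het[k]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[k + 1] <- probs[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (start > 1) {
    for (k in start:2) {
      h <- het[k]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[het == n_Aa]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

new_qc_report <- function(removed_individuals, removed_variants, thresholds,
                          order) {
  structure(list(removed_individuals = removed_individuals,
                 removed_variants = removed_variants,
                 thresholds = thresholds,
                 order = order),
            class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("<qc_report> removed ", nrow(x$removed_individuals), " individuals, ",
      nrow(x$removed_variants), " variants\n", sep = "")
  if (nrow(x$removed_individuals)) {
    print(table(x$removed_individuals$reason))
  }
  if (nrow(x$removed_variants)) {
    print(table(x$removed_variants$reason))
  }
  cat("filter order:", paste(x$order, collapse = " -> "), "\n")
  invisible(x)
}

#' Per-individual genotype quality control
#'
#' Removes individuals with a genotype failure (missing-call) rate above
#' `ind_fail_rate`, then individuals whose heterozygosity rate deviates
#' from the cohort mean by more than `het_sd` cohort standard deviations.
#' Each removal is recorded with a single primary reason, in that order.
#'
#' @param g A [genotype_matrix()].
#' @param het_sd Heterozygosity outlier cutoff in cohort SD units.
#' @param ind_fail_rate Maximum tolerated per-individual missing fraction.
#' @return List with the filtered `genotypes` and a `report` (`qc_report`).
#' @export
qc_individuals <- function(g, het_sd = 3, ind_fail_rate = 0.03) {
  if (length(g$individual_ids) == 0) stop("empty genotype matrix")
  miss <- rowMeans(is.na(g$dosage))
  fail_miss <- miss > ind_fail_rate

  het <- rowMeans(g$dosage == 1, na.rm = TRUE)
  het_pool <- het[!fail_miss]
  mu <- mean(het_pool)
  s <- stats::sd(het_pool)
  fail_het <- !fail_miss &
    (if (is.na(s) || s == 0) rep(FALSE, length(het))
     else abs(het - mu) > het_sd * s)

  removed <- data.frame(
    id = g$individual_ids[fail_miss | fail_het],
    reason = ifelse(fail_miss[fail_miss | fail_het], "missingness",
                    "heterozygosity"),
    stringsAsFactors = FALSE
  )
  keep <- !(fail_miss | fail_het)
  if (!any(keep)) stop("individual QC removed every individual")
  report <- new_qc_report(
    removed_individuals = removed,
    removed_variants = data.frame(id = character(0), reason = character(0)),
    thresholds = list(het_sd = het_sd, ind_fail_rate = ind_fail_rate),
    order = c("individual_missingness", "heterozygosity")
  )
  list(genotypes = subset_genotypes(g, individuals = keep), report = report)
}

#' Per-marker genotype quality control
#'
#' Applies, in order: the combined individual missingness filter
#' (fraction > `ind_miss_max` removes the individual), marker missingness
#' (> `marker_miss_max`), minor allele frequency (< `maf_min`, computed on
#' non-missing calls), and the exact Hardy-Weinberg test
#' (P < `hwe_min_p`). Each removed marker carries the first reason that
#' fired. Rerunning on the filtered output with the same thresholds
#' removes nothing further.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_min_p Minimum exact Hardy-Weinberg P value.
#' @param marker_miss_max Maximum per-marker missing fraction.
#' @param ind_miss_max Maximum per-individual missing fraction.
#' @return List with the filtered `genotypes` and a `report` (`qc_report`).
#' @export
qc_markers <- function(g, maf_min = 0.05, hwe_min_p = 1e-6,
                       marker_miss_max = 0.05, ind_miss_max = 0.1) {
  if (length(g$individual_ids) == 0 || nrow(g$variants) == 0) {
    stop("empty genotype matrix")
  }
  ind_miss <- rowMeans(is.na(g$dosage))
  drop_ind <- ind_miss > ind_miss_max
  removed_ind <- data.frame(id = g$individual_ids[drop_ind],
                            reason = rep("missingness", sum(drop_ind)),
                            stringsAsFactors = FALSE)
  if (all(drop_ind)) stop("individual missingness filter removed everyone")
  g2 <- subset_genotypes(g, individuals = !drop_ind)

  d <- g2$dosage
  n_ind <- nrow(d)
  marker_miss <- colMeans(is.na(d))
  f <- maf(g2)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  }, numeric(1))

  reason <- rep(NA_character_, ncol(d))
  reason[is.na(reason) & marker_miss > marker_miss_max] <- "missingness"
  reason[is.na(reason) & (is.nan(f) | f < maf_min)] <- "maf"
  reason[is.na(reason) & hwe_p < hwe_min_p] <- "hwe"
  keep <- is.na(reason)
  if (!any(keep)) stop("marker QC removed every marker")

  report <- new_qc_report(
    removed_individuals = removed_ind,
    removed_variants = data.frame(id = g2$variants$id[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE),
    thresholds = list(maf = maf_min, hwe_p = hwe_min_p,
                      marker_missingness = marker_miss_max,
                      individual_missingness = ind_miss_max),
    order = c("individual_missingness", "marker_missingness", "maf", "hwe")
  )
  list(genotypes = subset_genotypes(g2, variants = keep), report = report)
}
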