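#' Simulate GWAS summary statistics
#'
#' Emulates the external reference GWAS that supplies per-variant odds
#' ratios and P values for polygenic scoring. A random subset of
#' `n_causal` variants receives a true log odds ratio drawn from
#' `N(0, effect_sd^2)`; all others are null. Each variant's estimate is
#' `beta_hat = beta + se * z0` with `z0 ~ N(0, 1)` and the large-sample
#' logistic-regression standard error for a balanced case-control design,
#' `se = sqrt(2 / (gwas_n * f * (1 - f)))` at counted-allele frequency
#' `f`. P values are two-sided normal tail probabilities of
#' `beta_hat / se`, so null variants give uniform P by construction.
#'
#' @param g A [genotype_matrix()]; its counted alleles become the effect
#'   alleles and its sample allele frequencies set the standard errors.
#' @param n_causal Number of causal variants (`0` for a fully null GWAS).
#' @param effect_sd SD of causal log odds ratios (log-OR units).
#' @param gwas_n Reference GWAS sample size.
#' @param seed Integer seed.
#' @return A `summary_stats` data frame with columns `id`,
#'   `effect_allele`, `other_allele`, `or`, `p` and attributes
#'   `causal` (variant ids) and `true_logor`.
#' @export
simulate_summary_stats <- function(g, n_causal, effect_sd = 0.1,
                                   gwas_n = 5e4, seed = 1L) {
  m <- nrow(g$variants)
  if (n_causal > m) stop("n_causal exceeds the number of variants")
  set.seed(as.integer(seed))
  f <- allele_freq(g)
  f <- pmin(pmax(f, 1e-3), 1 - 1e-3)
  true_logor <- numeric(m)
  causal_idx <- if (n_causal > 0) sort(sample.int(m, n_causal)) else integer(0)
  if (n_causal > 0 && effect_sd > 0) {
    true_logor[causal_idx] <- stats::rnorm(n_causal, 0, effect_sd)
  }
  se <- sqrt(2 / (gwas_n * f * (1 - f)))
  beta_hat <- true_logor + se * stats::rnorm(m)
  z <- beta_hat / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    id = g$variants$id,
    effect_allele = g$variants$a1,
    other_allele = g$variants$a2,
    or = exp(beta_hat),
    p = pmin(pmax(p, .Machine$double.xmin), 1),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "causal") <- g$variants$id[causal_idx]
  attr(out, "true_logor") <- stats::setNames(true_logor, g$variants$id)
  out
}

validate_summary_stats <- function(ss) {
  required <- c("id", "effect_allele", "other_allele", "or", "p")
  if (!all(required %in% names(ss))) {
    stop("summary stats need columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(ss$id)) stop("duplicate variant ids in summary stats")
  if (any(ss$or <= 0)) stop("odds ratios must be positive")
  if (any(ss$p <= 0 | ss$p > 1)) stop("P values must lie in (0, 1]")
  invisible(ss)
}
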