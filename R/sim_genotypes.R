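#' Simulate genotypes with block-diagonal linkage disequilibrium
#'
#' Draws diploid additive dosages from a Gaussian-copula haplotype model:
#' each haplotype's latent variables are multivariate normal with
#' compound-symmetric correlation `within_block_r` inside each LD block and
#' zero across blocks; a latent value below the MAF quantile codes one copy
#' of the counted allele. Per-variant MAFs are drawn uniformly from
#' `maf_range`. Blocks are laid out on chromosomes 1-22 (round-robin) with
#' 10 kb spacing inside a block and a 10 Mb gap between blocks sharing a
#' chromosome, so within-block pairs fall inside any realistic clumping
#' window while cross-block pairs do not.
#'
#' The correlation of the resulting dosages is the phi coefficient implied
#' by thresholding a bivariate normal at the two MAF quantiles; it is
#' smaller in magnitude than the latent `within_block_r`
#' (see [expected_dosage_cor()]).
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with attribute `"maf"` holding the
#'   generating minor allele frequencies.
#' @export
simulate_ld_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  m <- cfg$n_variants
  r <- cfg$within_block_r
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thresh <- stats::qnorm(maf)
  block <- rep(seq_along(cfg$ld_block_sizes), cfg$ld_block_sizes)

  draw_haplotype <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (r > 0) {
      for (b in unique(block)) {
        cols <- which(block == b)
        shared <- stats::rnorm(n)
        z[, cols] <- sqrt(r) * shared + sqrt(1 - r) * z[, cols]
      }
    }
    # allele indicator: one copy of the counted allele
    sweep(z, 2, thresh, `<`) * 1L
  }
  dosage <- draw_haplotype() + draw_haplotype()

  n_blocks <- length(cfg$ld_block_sizes)
  chrom_of_block <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  pos <- integer(m)
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    rank_on_chrom <- sum(chrom_of_block[seq_len(b)] == chrom_of_block[b]) - 1L
    start <- 1e6 + rank_on_chrom * 1e7
    pos[cols] <- as.integer(start + (seq_along(cols) - 1L) * 1e4)
  }
  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(chrom_of_block[block]),
    pos = pos,
    a1 = "A",
    a2 = "G",
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dosage, sprintf("ind%04d", seq_len(n)), variants)
  attr(g, "maf") <- maf
  g
}

#' Expected dosage correlation under the copula genotype model
#'
#' Numerically integrates the bivariate-normal orthant probability to get
#' the phi coefficient between two thresholded latent variables, which
#' equals the expected Pearson correlation of the additive dosages.
#'
#' @param maf1,maf2 Minor allele frequencies of the two variants.
#' @param r Latent correlation.
#' @return Expected correlation of the two dosage variables.
#' @export
expected_dosage_cor <- function(maf1, maf2, r) {
  t1 <- stats::qnorm(maf1)
  t2 <- stats::qnorm(maf2)
  if (abs(r) < 1e-12) return(0)
  # P(X1 < t1, X2 < t2) for standard bivariate normal with correlation r
  p11 <- stats::integrate(function(x) {
    stats::pnorm((t2 - r * x) / sqrt(1 - r^2)) * stats::dnorm(x)
  }, -Inf, t1, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Inject missing genotype calls
#'
#' Masks entries at random: an entry is set missing if it is hit by the
#' per-marker mask (probability `marker_rate`) or the per-individual mask
#' (probability `individual_rate`), drawn independently. With one rate at
#' zero the realized missing fraction of the other margin is binomial at
#' the requested rate; with both nonzero the per-entry rate is
#' `1 - (1 - marker_rate) * (1 - individual_rate)`.
#'
#' @param g A [genotype_matrix()].
#' @param marker_rate,individual_rate Fractions in `[0, 1)`.
#' @param seed Integer seed; the mask is reproducible.
#' @return A [genotype_matrix()] with additional `NA` calls; retained
#'   entries are unchanged.
#' @export
inject_missingness <- function(g, marker_rate = 0, individual_rate = 0,
                               seed = 1L) {
  if (marker_rate < 0 || marker_rate >= 1 ||
      individual_rate < 0 || individual_rate >= 1) {
    stop("missingness rates must be in [0, 1)")
  }
  if (marker_rate == 0 && individual_rate == 0) return(g)
  set.seed(as.integer(seed))
  d <- g$dosage
  nm <- length(d)
  mask <- stats::runif(nm) < marker_rate
  if (individual_rate > 0) {
    mask <- mask | (stats::runif(nm) < individual_rate)
  }
  d[mask] <- NA
  out <- genotype_matrix(d, g$individual_ids, g$variants)
  attr(out, "maf") <- attr(g, "maf")
  out
}
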