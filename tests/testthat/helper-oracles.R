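# Independent oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately naive (explicit loops, full enumeration) and
# share no code with the implementation they check.

# build a genotype_matrix from a dosage matrix with evenly spaced
# positions on one chromosome
toy_genotypes <- function(dosage, chrom = "1", spacing = 1e4,
                          a1 = "A", a2 = "G") {
  m <- ncol(dosage)
  genotype_matrix(
    dosage,
    sprintf("i%03d", seq_len(nrow(dosage))),
    data.frame(id = sprintf("v%03d", seq_len(m)),
               chrom = rep(chrom, length.out = m),
               pos = as.integer(seq_len(m)) * as.integer(spacing),
               a1 = rep(a1, length.out = m),
               a2 = rep(a2, length.out = m),
               stringsAsFactors = FALSE)
  )
}

toy_sumstats <- function(ids, or, p, effect = "A", other = "G") {
  out <- data.frame(id = ids,
                    effect_allele = rep(effect, length.out = length(ids)),
                    other_allele = rep(other, length.out = length(ids)),
                    or = or, p = p, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# exact Hardy-Weinberg P by direct enumeration with log-factorials:
# P(n_Aa = h | n, n_minor) = n! n_minor! n_major! 2^h /
#                            (2n)! hom_r! h! hom_c!
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * min(n_AA, n_aa) + n_Aa
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_minor - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) + lfactorial(n_minor) + lfactorial(n_major) +
      h * log(2) - lfactorial(2 * n) - lfactorial(hom_r) -
      lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_Aa]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# greedy clumping recomputed from scratch with explicit pairwise r2
clump_oracle <- function(ss, g, r2_cut, window_bp) {
  v <- g$variants[match(ss$id, g$variants$id), ]
  remaining <- order(ss$p, v$pos, ss$id)
  kept <- character(0)
  while (length(remaining)) {
    i <- remaining[1]
    kept <- c(kept, ss$id[i])
    drop <- i
    for (j in remaining[-1]) {
      if (v$chrom[j] == v$chrom[i] &&
          abs(v$pos[j] - v$pos[i]) <= window_bp) {
        x <- g$dosage[, match(ss$id[i], g$variants$id)]
        y <- g$dosage[, match(ss$id[j], g$variants$id)]
        ok <- !is.na(x) & !is.na(y)
        r2 <- if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) 0
              else cor(x[ok], y[ok])^2
        if (r2 >= r2_cut) drop <- c(drop, j)
      }
    }
    remaining <- setdiff(remaining, drop)
  }
  kept
}

# scoring with explicit loops, mean substitution for missing dosages
score_oracle <- function(dosage, weights, pvals, threshold) {
  n <- nrow(dosage)
  scores <- numeric(n)
  for (j in seq_len(ncol(dosage))) {
    if (!(pvals[j] < threshold)) next
    col <- dosage[, j]
    mu <- mean(col[!is.na(col)])
    for (i in seq_len(n)) {
      d <- if (is.na(col[i])) mu else col[i]
      scores[i] <- scores[i] + weights[j] * d
    }
  }
  scores
}

# interval-scan annotation oracle
annotate_oracle <- function(variants, genes, window_bp = 0) {
  res <- list()
  for (i in seq_len(nrow(genes))) {
    hits <- character(0)
    for (k in seq_len(nrow(variants))) {
      if (variants$chrom[k] == genes$chrom[i] &&
          variants$pos[k] >= genes$start[i] - window_bp &&
          variants$pos[k] <= genes$end[i] + window_bp) {
        hits <- c(hits, variants$id[k])
      }
    }
    res[[genes$gene_id[i]]] <- hits
  }
  res
}

# textbook Pearson correlation and t-distribution P from explicit sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# pooled-variance two-sample t from the closed form
ttest_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Benjamini-Hochberg by explicit sorting (step-up)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# small null cohort for calibration runs: no PRS effect anywhere
null_sim_config <- function(seed, n = 188, ...) {
  sim_config(n_individuals = n,
             arm_sizes = c(ceiling(n * 99 / 188), n - ceiling(n * 99 / 188)),
             prs_main_beta = 0,
             prs_time_beta = c(0, 0),
             prs_time_arm_beta = c(0, 0),
             seed = seed, ...)
}

# null-effect cohort + per-block gene table for gene-set calibration;
# optionally plants a single causal SNP effect into the change score
make_geneset_fixture <- function(seed, n = 150, planted_beta = 0) {
  cfg <- sim_config(n_individuals = n, arm_sizes = c(ceiling(n / 2),
                                                     floor(n / 2)),
                    n_variants = 120, ld_block_sizes = rep(4, 30),
                    prs_time_beta = c(0, 0), prs_time_arm_beta = c(0, 0),
                    seed = seed)
  sim <- simulate_trial(cfg)
  genes <- block_genes(sim$genotypes)
  change <- delta_srs(sim$cohort, "post")
  if (planted_beta != 0) {
    snp <- sim$genotypes$variants$id[1]
    dos <- sim$genotypes$dosage[match(change$id,
                                      sim$genotypes$individual_ids),
                                snp]
    change$change <- change$change + planted_beta * dos
  }
  covariates <- sim$cohort$individuals[, c("id", "age_group", "sex", "arm",
                                           "pc1", "pc2", "pc3", "pc4")]
  list(sim = sim, genes = genes, change = change, covariates = covariates)
}

# gene table tiling the simulated LD blocks (one gene per block)
block_genes <- function(g, gap = 5e6) {
  v <- g$variants
  key <- paste(v$chrom, floor(v$pos / gap))
  blocks <- split(v, key)
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(gene_id = paste0("G_", b$chrom[1], "_", min(b$pos)),
               chrom = b$chrom[1], start = min(b$pos), end = max(b$pos),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}
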