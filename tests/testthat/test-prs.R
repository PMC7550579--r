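test_that("harmonization orients, complements, and drops as required", {
  d <- matrix(c(0, 1, 2,
                2, 1, 0,
                1, 1, 1,
                0, 2, 1), nrow = 3)
  g <- genotype_matrix(
    d, c("a", "b", "c"),
    data.frame(id = c("v1", "v2", "v3", "v4"),
               chrom = "1", pos = c(100, 200, 300, 400),
               a1 = c("A", "C", "A", "C"),
               a2 = c("G", "T", "T", "G"),
               stringsAsFactors = FALSE))
  ss <- toy_sumstats(
    c("v1", "v2", "v3", "v4"),
    or = c(exp(1), 2, 1.5, 3), p = c(0.001, 0.01, 0.02, 0.03),
    effect = c("A", "T", "A", "A"),
    other = c("G", "C", "T", "C"))
  h <- harmonize_sumstats(ss, g)
  expect_equal(unname(h$orientation["v1"]), "as_is")
  expect_equal(unname(h$orientation["v2"]), "flip")
  # v3 palindromic (A/T) kept under default policy
  expect_equal(unname(h$orientation["v3"]), "as_is")
  # v4: C/G genotype vs A/C stats: complement G->C matches other=C,
  # complement C->G does not match effect=A -> mismatch dropped
  expect_true("v4" %in% h$dropped$id)

  hd <- harmonize_sumstats(ss, g, prs_config(palindromic_policy = "drop"))
  expect_true("v3" %in% hd$dropped$id)
  expect_equal(hd$dropped$reason[hd$dropped$id == "v3"], "palindromic")
})

test_that("flipped orientation scores 2 - dosage", {
  d <- matrix(c(0, 1, 2), ncol = 1)
  g <- genotype_matrix(d, c("a", "b", "c"),
                       data.frame(id = "v1", chrom = "1", pos = 100,
                                  a1 = "A", a2 = "G"))
  ss <- toy_sumstats("v1", or = exp(0.5), p = 0.001,
                     effect = "G", other = "A")
  h <- harmonize_sumstats(ss, g)
  prof <- prs_score(g, h, "v1", prs_config(thresholds = 0.05))
  expect_equal(unname(prof$raw[, 1]), 0.5 * (2 - c(0, 1, 2)))
})

test_that("clumping keeps the most significant of a correlated set", {
  d <- matrix(rep(c(0, 1, 2, 1, 0), 3), ncol = 3)  # identical columns
  g <- toy_genotypes(d)
  ss <- toy_sumstats(c("v001", "v002", "v003"), or = c(1.1, 1.2, 1.3),
                     p = c(0.01, 0.001, 0.02))
  expect_equal(ld_clump(ss, g), "v002")

  # independent variants are all retained
  set.seed(11)
  d2 <- matrix(rbinom(5000 * 3, 2, 0.5), ncol = 3)
  g2 <- toy_genotypes(d2)
  ss2 <- toy_sumstats(c("v001", "v002", "v003"), or = c(1.1, 1.2, 1.3),
                      p = c(0.01, 0.001, 0.02))
  expect_setequal(ld_clump(ss2, g2), c("v001", "v002", "v003"))
})

test_that("clumping matches the exhaustive greedy oracle", {
  set.seed(12)
  for (rep in 1:5) {
    n_var <- 50
    d <- matrix(rbinom(5 * n_var, 2, runif(1, 0.2, 0.5)), 5, n_var)
    g <- toy_genotypes(d, chrom = rep(c("1", "2"), each = n_var / 2),
                       spacing = 2e5)
    ss <- toy_sumstats(g$variants$id, or = exp(rnorm(n_var, 0, 0.1)),
                       p = runif(n_var))
    cfg <- prs_config(clump_r2 = 0.1, clump_window_kb = 500)
    expect_identical(ld_clump(ss, g, cfg),
                     clump_oracle(ss, g, 0.1, 5e5))
  }
})

test_that("no retained pair within the window exceeds the r2 cutoff", {
  cfg <- sim_config(n_individuals = 200, arm_sizes = c(100, 100), seed = 17)
  g <- simulate_ld_genotypes(cfg)
  ss <- simulate_summary_stats(g, n_causal = 30, seed = 17)
  pcfg <- prs_config()
  kept <- ld_clump(ss, g, pcfg)
  v <- g$variants[match(kept, g$variants$id), ]
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1)) {
      if (v$chrom[i] == v$chrom[j] &&
          abs(v$pos[i] - v$pos[j]) <= pcfg$clump_window_kb * 1000) {
        r2 <- cor(g$dosage[, match(kept[i], g$variants$id)],
                  g$dosage[, match(kept[j], g$variants$id)])^2
        expect_lt(r2, pcfg$clump_r2)
      }
    }
  }
})

test_that("scoring is the ln(OR)-weighted dosage sum", {
  d <- matrix(c(0, 1, 2), ncol = 1)
  g <- genotype_matrix(d, c("a", "b", "c"),
                       data.frame(id = "v1", chrom = "1", pos = 100,
                                  a1 = "A", a2 = "G"))
  ss <- toy_sumstats("v1", or = exp(1), p = 0.001)
  h <- harmonize_sumstats(ss, g)
  prof <- prs_score(g, h, "v1", prs_config(thresholds = 0.05))
  expect_equal(unname(prof$raw[, 1]), c(0, 1, 2))
})

test_that("scores match an explicit-loop oracle, with missing dosages", {
  set.seed(13)
  d <- matrix(rbinom(50, 2, 0.4), 5, 10)
  d[sample(50, 6)] <- NA
  g <- toy_genotypes(d)
  or <- exp(rnorm(10, 0, 0.2))
  p <- runif(10)
  ss <- toy_sumstats(g$variants$id, or = or, p = p)
  h <- harmonize_sumstats(ss, g)
  cfg <- prs_config()
  prof <- suppressWarnings(prs_score(g, h, g$variants$id, cfg))
  for (t in seq_along(cfg$thresholds)) {
    expect_equal(unname(prof$raw[, t]),
                 score_oracle(d, log(or), p, cfg$thresholds[t]),
                 tolerance = 1e-12)
  }
  # five default thresholds give five score columns
  expect_equal(ncol(prof$raw), 5)
  # monotone inclusion
  expect_true(all(diff(prof$n_snps_used) >= 0))
})

test_that("scoring is additive over disjoint variant sets", {
  set.seed(14)
  d <- matrix(rbinom(80, 2, 0.3), 8, 10)
  g <- toy_genotypes(d)
  ss <- toy_sumstats(g$variants$id, or = exp(rnorm(10, 0, 0.2)),
                     p = runif(10))
  h <- harmonize_sumstats(ss, g)
  cfg <- prs_config(thresholds = 1)
  all_ids <- g$variants$id
  s_all <- prs_score(g, h, all_ids, cfg)$raw
  s_a <- prs_score(g, h, all_ids[1:4], cfg)$raw
  s_b <- prs_score(g, h, all_ids[5:10], cfg)$raw
  expect_equal(s_all, s_a + s_b, tolerance = 1e-12)
})

test_that("an empty threshold warns and scores zero", {
  d <- matrix(c(0, 1, 2, 1), ncol = 1)
  g <- toy_genotypes(d)
  ss <- toy_sumstats("v001", or = 1.5, p = 0.5)
  h <- harmonize_sumstats(ss, g)
  expect_warning(
    prof <- prs_score(g, h, "v001", prs_config(thresholds = c(0.01, 1))),
    "no variants")
  expect_true(all(prof$raw[, 1] == 0))
  expect_equal(unname(prof$n_snps_used), c(0L, 1L))
})

test_that("standardization gives mean 0, SD 1, and is affine-invariant", {
  prof <- structure(list(
    raw = matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "Pt_1")),
    n_snps_used = c(Pt_1 = 3L), thresholds = 1,
    individual_ids = c("a", "b", "c")), class = "prs_profile")
  z <- prs_standardize(prof)$z
  expect_equal(unname(z[, 1]), c(-1, 0, 1))

  set.seed(15)
  raw <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("Pt_0.5", "Pt_1")))
  p1 <- structure(list(raw = raw, n_snps_used = c(2L, 3L),
                       thresholds = c(0.5, 1),
                       individual_ids = sprintf("i%02d", 1:20)),
                  class = "prs_profile")
  p2 <- p1
  p2$raw <- 3.2 * raw + 7
  z1 <- prs_standardize(p1)$z
  z2 <- prs_standardize(p2)$z
  expect_equal(z1, z2, tolerance = 1e-10)
  expect_equal(colMeans(z1), c(Pt_0.5 = 0, Pt_1 = 0), tolerance = 1e-10)
  expect_equal(apply(z1, 2, sd), c(Pt_0.5 = 1, Pt_1 = 1), tolerance = 1e-10)

  p3 <- p1
  p3$raw[, 1] <- 5
  expect_error(prs_standardize(p3), "Pt_0.5")
})

test_that("variant sets nest across increasing thresholds end to end", {
  cfg <- sim_config(seed = 18)
  g <- simulate_ld_genotypes(cfg)
  ss <- simulate_summary_stats(g, n_causal = 30, seed = 18)
  prof <- compute_prs(ss, g)
  expect_true(all(diff(prof$n_snps_used) >= 0))
  expect_equal(colMeans(prof$z), colMeans(prof$z) * 0, tolerance = 1e-10,
               ignore_attr = TRUE)
})
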