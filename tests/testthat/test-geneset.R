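test_that("change scores subtract baseline and log exclusions", {
  outcomes <- data.frame(
    id = c("a", "a", "b", "b", "c"),
    timepoint = factor(c("pre", "post", "pre", "post", "pre"),
                       levels = c("pre", "post", "followup")),
    srs_total = c(100L, 90L, 120L, 125L, 80L))
  individuals <- data.frame(id = c("a", "b", "c"))
  cohort <- structure(list(individuals = individuals, outcomes = outcomes),
                      class = "trial_cohort")
  ch <- delta_srs(cohort, "post")
  expect_equal(ch$change[ch$id == "a"], -10)
  expect_equal(ch$change[ch$id == "b"], 5)
  expect_equal(attr(ch, "excluded"), "c")
  expect_equal(mean(ch$change), mean(c(-10, 5)))
  expect_error(delta_srs(cohort, "followup"), "no individual")
})

test_that("annotation uses inclusive bounds and matches the scan oracle", {
  variants <- data.frame(id = c("v1", "v2", "v3"), chrom = "1",
                         pos = c(100, 200, 201))
  genes <- data.frame(gene_id = "g1", chrom = "1", start = 100, end = 200)
  map <- annotate_snps(variants, genes)
  expect_setequal(map$g1, c("v1", "v2"))   # start inclusive, 1 bp past out

  set.seed(41)
  variants2 <- data.frame(id = sprintf("v%03d", 1:500),
                          chrom = as.character(sample(1:3, 500, TRUE)),
                          pos = sample.int(1e6, 500))
  genes2 <- data.frame(gene_id = sprintf("g%02d", 1:50),
                       chrom = as.character(sample(1:3, 50, TRUE)),
                       start = sample.int(9e5, 50))
  genes2$end <- genes2$start + sample.int(5e4, 50)
  for (w in c(0, 10)) {
    expect_identical(annotate_snps(variants2, genes2, window_kb = w),
                     annotate_oracle(variants2, genes2, window_bp = w * 1000))
  }
})

test_that("gene statistics are deterministic and honor the P floor", {
  fx <- make_geneset_fixture(51)
  map <- annotate_snps(fx$sim$genotypes$variants, fx$genes)
  gs1 <- gene_stats(fx$sim$genotypes, fx$change, fx$covariates, map,
                    fx$genes, n_perm = 100, seed = 9)
  gs2 <- gene_stats(fx$sim$genotypes, fx$change, fx$covariates, map,
                    fx$genes, n_perm = 100, seed = 9)
  expect_identical(gs1, gs2)
  expect_true(all(gs1$p >= 1 / 101))
  expect_true(all(gs1$n_snps >= 1))
  expect_equal(nrow(gs1), nrow(fx$genes))
})

test_that("a planted causal gene outranks the null genes", {
  hits <- vapply(1:10, function(s) {
    fx <- make_geneset_fixture(60 + s, planted_beta = 12)
    map <- annotate_snps(fx$sim$genotypes$variants, fx$genes)
    gs <- gene_stats(fx$sim$genotypes, fx$change, fx$covariates, map,
                     fx$genes, n_perm = 200, seed = s)
    planted <- fx$genes$gene_id[1]
    gs$z[gs$gene_id == planted] >
      quantile(gs$z[gs$gene_id != planted], 0.95)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("competitive test output behaves and is shift-invariant", {
  fx <- make_geneset_fixture(52)
  map <- annotate_snps(fx$sim$genotypes$variants, fx$genes)
  gs <- gene_stats(fx$sim$genotypes, fx$change, fx$covariates, map,
                   fx$genes, n_perm = 100, seed = 3)
  coll <- list(s1 = gs$gene_id[1:10])
  res <- competitive_test(gs, coll, "s1")
  expect_equal(res$n_genes_scored, nrow(gs))

  gs_shift <- gs
  gs_shift$z <- gs$z + 5
  res_shift <- competitive_test(gs_shift, coll, "s1")
  expect_equal(res$beta, res_shift$beta, tolerance = 1e-10)

  # constant z: zero effect
  gs_const <- gs
  gs_const$z <- 1
  expect_equal(suppressWarnings(competitive_test(gs_const, coll, "s1")$beta),
               0, tolerance = 1e-10)

  expect_error(competitive_test(gs, list(s2 = gs$gene_id), "s2"),
               "outside")
  expect_error(competitive_test(gs, coll, "nope"), "unknown")
})

test_that("correction caps, multiplies, and matches the BH oracle", {
  one <- data.frame(set = "s", beta = 1, se = 1, p = 0.03,
                    corrected_p = NA_real_, n_genes_scored = 10)
  expect_equal(correct_pvalues(one, "bonferroni")$corrected_p, 0.03)

  many <- do.call(rbind, replicate(32, one, simplify = FALSE))
  many$p <- c(0.002, runif(31, 0.1, 1))
  bonf <- correct_pvalues(many, "bonferroni")
  expect_equal(bonf$corrected_p[1], 0.064)
  expect_true(all(bonf$corrected_p <= 1))
  expect_true(all(bonf$corrected_p >= bonf$p))

  bh <- correct_pvalues(many, "BH")
  expect_equal(bh$corrected_p, bh_oracle(many$p), tolerance = 1e-12)
})

test_that("a full 32-set collection yields 32 result rows", {
  fx <- make_geneset_fixture(53)
  set.seed(54)
  categories <- c("synaptic", "glial", "FMRP", "glutamate", "mitochondrial")
  coll <- lapply(1:32, function(i) sample(fx$genes$gene_id, 8))
  names(coll) <- sprintf("set%02d", 1:32)
  attr(coll, "category") <- setNames(rep(categories, length.out = 32),
                                     names(coll))
  res <- geneset_analysis(fx$sim$genotypes, fx$sim$cohort, fx$genes, coll,
                          endpoint = "post", n_perm = 100, seed = 4)
  expect_equal(nrow(res), 32)
  expect_setequal(unique(res$category), categories)
  expect_true(all(res$corrected_p >= res$p))
})
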