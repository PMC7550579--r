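make_sim <- function(seed = 20, ...) simulate_trial(sim_config(seed = seed, ...))

test_that("the design encodes interactions, references, and covariates", {
  sim <- make_sim()
  des <- build_design(sim$cohort, mlm_spec("ADHD", "three_way", "clinsig"))
  mm <- model.matrix(lme4::nobars(des$formula), des$data)
  three_way <- grep("^prs:time.*:armSSGT$", colnames(mm), value = TRUE)
  expect_length(three_way, 2)
  expect_setequal(three_way, c("prs:timepost:armSSGT",
                               "prs:timefollowup:armSSGT"))
  expect_true("cnv_clinsigTRUE" %in% colnames(mm))
  expect_true("adhd_comorbidTRUE" %in% colnames(mm))  # forced for ADHD

  des2 <- build_design(sim$cohort,
                       mlm_spec("ASD", "two_way", arm_subset = "SSGT"))
  mm2 <- model.matrix(lme4::nobars(des2$formula), des2$data)
  expect_false(any(grepl("arm", colnames(mm2))))
  expect_true(all(des2$data$arm == "SSGT"))
  expect_false("adhd_comorbidTRUE" %in% colnames(mm2))
})

test_that("fixed effects match an OLS oracle when random variances vanish", {
  # a null-variance generator under which both variance components are
  # estimated at the zero boundary, so GLS collapses to OLS
  sim <- make_sim(seed = 23, center_sd = 0, individual_sd = 0,
                  residual_sd = 6)
  des <- build_design(sim$cohort, mlm_spec("ADHD", "three_way", "clinsig"))
  fit <- fit_mlm(des)
  expect_true(fit$singular)
  expect_equal(unname(fit$varcomp[c("individual", "center")]), c(0, 0))
  ols <- lm(lme4::nobars(des$formula), data = des$data)
  expect_lt(max(abs(fit$beta[names(coef(ols))] - coef(ols))), 1e-4)
})

test_that("significance thresholds divide alpha and round to 4 decimals", {
  expect_equal(significance_threshold(3, 0.05), 0.0167)
  expect_equal(significance_threshold(1, 0.05), 0.05)
  expect_equal(significance_threshold(5, 0.05), 0.01)
  expect_error(significance_threshold(0), ">= 1")
})

test_that("interaction estimates expose the timepoint terms with flags", {
  sim <- make_sim(seed = 23)
  fit <- fit_mlm(build_design(sim$cohort, mlm_spec("ADHD", "three_way")))
  est <- interaction_estimates(fit)
  expect_equal(est$term, c("prs:timepost:armSSGT",
                           "prs:timefollowup:armSSGT"))
  expect_equal(est$significant, est$p < 0.0167)
  expect_equal(est$ci_lo, est$beta - 1.96 * est$se)
  expect_equal(est$ci_hi, est$beta + 1.96 * est$se)

  fit2 <- fit_mlm(build_design(sim$cohort, mlm_spec("ADHD", "two_way")))
  est2 <- interaction_estimates(fit2)
  expect_equal(est2$term, c("prs:timepost", "prs:timefollowup"))
})

test_that("R-squared pair respects its bounds and degenerate limits", {
  sim <- make_sim(seed = 24)
  fit <- fit_mlm(build_design(sim$cohort, mlm_spec("ADHD", "three_way")))
  r2 <- nakagawa_r2(fit)
  expect_gte(r2$marginal, 0)
  expect_lte(r2$marginal, r2$conditional)
  expect_lte(r2$conditional, 1)

  # with the random variances estimated at zero, marginal == conditional
  sim0 <- make_sim(seed = 23, center_sd = 0, individual_sd = 0,
                   residual_sd = 6)
  fit0 <- fit_mlm(build_design(sim0$cohort,
                               mlm_spec("ADHD", "three_way", "clinsig")))
  r20 <- nakagawa_r2(fit0)
  expect_equal(r20$marginal, r20$conditional, tolerance = 1e-8)
})

test_that("the full model never has lower ML likelihood than the reduced", {
  sim <- make_sim(seed = 26)
  spec <- mlm_spec("ADHD", "three_way")
  full <- fit_mlm(build_design(sim$cohort, spec), reml = FALSE)
  red <- fit_mlm(build_design(sim$cohort, spec, include_prs = FALSE),
                 reml = FALSE)
  expect_gte(full$loglik, red$loglik - 1e-6)
})

test_that("a noise PRS adds (almost) no explained variance", {
  set.seed(27)
  sim <- make_sim(seed = 27)
  noise <- rnorm(nrow(sim$cohort$individuals))
  dr <- delta_r2(sim$cohort, mlm_spec("ADHD", "three_way"),
                 prs_values = noise)
  expect_lt(abs(dr$marginal), 0.03)
})

test_that("the generating three-way effect is recovered at large n", {
  cfg <- sim_config(n_individuals = 3000, arm_sizes = c(1500, 1500),
                    n_variants = 40, ld_block_sizes = rep(2, 20),
                    prs_time_arm_beta = c(0, 6.7), seed = 28)
  sim <- simulate_trial(cfg)
  fit <- fit_mlm(build_design(sim$cohort, mlm_spec("ADHD", "three_way")))
  est <- interaction_estimates(fit)
  fu <- est[est$term == "prs:timefollowup:armSSGT", ]
  expect_gt(fu$ci_hi, 6.7 - 0.5)
  expect_lt(fu$ci_lo, 6.7 + 0.5)
})

test_that("the R-squared grid covers every phenotype-threshold cell", {
  sim <- make_sim(seed = 29)
  prof <- compute_prs(sim$summary_stats, sim$genotypes)
  grid <- r2_grid(sim$cohort, list(ADHD = prof, ASD = prof))
  expect_equal(nrow(grid), 2 * length(prof$thresholds))
  expect_true(all(is.finite(grid$delta_marginal)))
})
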