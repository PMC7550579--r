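#' Simulate a two-arm longitudinal trial cohort
#'
#' Builds the clinical layer on top of simulated genotypes: arm and center
#' assignment, demographics, ancestry covariates, CNV carrier flags, ADHD
#' comorbidity, per-phenotype standardized polygenic scores, and
#' longitudinal SRS totals generated from the outcome model described in
#' [sim_config()].
#'
#' The score for `cfg$prs_phenotype` is the standardized genotype-derived
#' score `scale(dosage %*% log(OR))` using the summary-statistic weights
#' over all variants, so it is both heritable and recoverable by the PRS
#' engine; the two remaining phenotype scores are Gaussians correlated with
#' it (0.41 for ASD-ADHD, -0.22 for ADHD-EA, near 0 for ASD-EA, echoing
#' the correlations observed among the three scores in the trial cohort).
#' ADHD comorbidity is Bernoulli with log-odds
#' `qlogis(comorbidity_base_rate) + comorbidity_prs_shift * z_ADHD`.
#' SRS totals are rounded to integers and truncated to `[0, 195]`.
#' Post-baseline records are deleted completely at random at
#' `cfg$dropout_rates`.
#'
#' @param g A [genotype_matrix()] with `cfg$n_individuals` rows.
#' @param ss A `summary_stats` object covering the variants of `g`.
#' @param cfg A [sim_config()].
#' @return A `trial_cohort`: list with data frames `individuals` (one row
#'   per individual) and `outcomes` (one row per retained
#'   individual-timepoint), plus attribute `"truth"` recording the
#'   generating parameters, causal variants, variance components and true
#'   scores.
#' @export
simulate_trial_cohort <- function(g, ss, cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_individuals
  if (length(g$individual_ids) != n) {
    stop("genotype matrix and config disagree on the number of individuals")
  }
  set.seed(cfg$seed + 1L)

  # genotype-derived score driving the outcome model
  w <- log(ss$or[match(g$variants$id, ss$id)])
  w[is.na(w)] <- 0
  d <- g$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  raw_score <- as.numeric(d %*% w)
  z_target <- if (stats::sd(raw_score) > 0) {
    as.numeric(scale(raw_score))
  } else {
    stats::rnorm(n)
  }

  phenos <- c("ADHD", "ASD", "EA")
  others <- setdiff(phenos, cfg$prs_phenotype)
  cor_with_target <- c(ASD = 0.41, EA = -0.22, ADHD = 0.41)
  prs <- list()
  prs[[cfg$prs_phenotype]] <- z_target
  for (ph in others) {
    rho <- cor_with_target[[ph]]
    prs[[ph]] <- as.numeric(scale(
      rho * z_target + sqrt(1 - rho^2) * stats::rnorm(n)
    ))
  }

  arm <- factor(
    sample(rep(c("SSGT", "standard_care"), cfg$arm_sizes)),
    levels = c("standard_care", "SSGT")
  )
  center <- factor(
    sample.int(cfg$n_centers, n, replace = TRUE),
    levels = seq_len(cfg$n_centers)
  )
  age_group <- factor(sample(c("child", "adolescent"), n, replace = TRUE),
                      levels = c("child", "adolescent"))
  sex <- factor(sample(c("male", "female"), n, replace = TRUE,
                       prob = c(0.8, 0.2)),
                levels = c("male", "female"))
  pcs <- matrix(stats::rnorm(n * 4, 0, 0.01), n, 4,
                dimnames = list(NULL, paste0("pc", 1:4)))
  cnv_clinsig <- stats::runif(n) < cfg$cnv_carrier_rate
  cnv_large <- cnv_clinsig | (stats::runif(n) < cfg$cnv_carrier_rate)
  p_comorb <- stats::plogis(stats::qlogis(cfg$comorbidity_base_rate) +
                              cfg$comorbidity_prs_shift * prs$ADHD)
  adhd_comorbid <- stats::runif(n) < p_comorb

  individuals <- data.frame(
    id = g$individual_ids,
    arm = arm,
    center = center,
    age_group = age_group,
    sex = sex,
    pcs,
    cnv_clinsig = cnv_clinsig,
    cnv_large = cnv_large,
    adhd_comorbid = adhd_comorbid,
    prs_ADHD = prs$ADHD,
    prs_ASD = prs$ASD,
    prs_EA = prs$EA,
    stringsAsFactors = FALSE
  )

  nt <- length(cfg$timepoints)
  u_center <- stats::rnorm(cfg$n_centers, 0, cfg$center_sd)
  u_indiv <- stats::rnorm(n, 0, cfg$individual_sd)
  is_active <- as.numeric(arm == "SSGT")
  prs_time <- c(0, cfg$prs_time_beta)
  prs_time_arm <- c(0, cfg$prs_time_arm_beta)

  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    mu <- cfg$baseline_srs + cfg$time_effect[t] +
      cfg$arm_time_effect[t] * is_active +
      cfg$prs_main_beta * z_target +
      prs_time[t] * z_target +
      prs_time_arm[t] * z_target * is_active +
      u_center[as.integer(center)] + u_indiv
    srs <- mu + stats::rnorm(n, 0, cfg$residual_sd)
    srs <- pmin(pmax(round(srs), 0), srs_max_total())
    keep <- stats::runif(n) >= cfg$dropout_rates[t]
    rows[[t]] <- data.frame(
      id = g$individual_ids[keep],
      timepoint = cfg$timepoints[t],
      srs_total = as.integer(srs[keep]),
      stringsAsFactors = FALSE
    )
  }
  outcomes <- do.call(rbind, rows)
  outcomes$timepoint <- factor(outcomes$timepoint, levels = cfg$timepoints)
  outcomes <- outcomes[order(match(outcomes$id, g$individual_ids),
                             as.integer(outcomes$timepoint)), ]
  rownames(outcomes) <- NULL

  cohort <- structure(list(individuals = individuals, outcomes = outcomes),
                      class = "trial_cohort")
  attr(cohort, "truth") <- list(
    config = cfg,
    causal = attr(ss, "causal"),
    true_logor = attr(ss, "true_logor"),
    z_target = z_target,
    varcomp = c(center = cfg$center_sd^2,
                individual = cfg$individual_sd^2,
                residual = cfg$residual_sd^2)
  )
  validate_trial_cohort(cohort)
  cohort
}

#' Validate a trial cohort object
#'
#' Checks the structural invariants: every individual has a baseline
#' record, timepoints are unique within individual, arm and center are
#' constant per individual (guaranteed by the one-row-per-individual
#' layout), and SRS totals lie in the instrument range.
#'
#' @param cohort A `trial_cohort`.
#' @return The cohort, invisibly; stops on violation.
#' @export
validate_trial_cohort <- function(cohort) {
  ind <- cohort$individuals
  out <- cohort$outcomes
  if (anyDuplicated(ind$id)) stop("duplicate individual ids")
  if (!all(out$id %in% ind$id)) stop("outcome rows for unknown individuals")
  base <- levels(out$timepoint)[1]
  with_base <- unique(out$id[out$timepoint == base])
  if (!all(ind$id %in% with_base)) {
    stop("every individual needs a record at the baseline timepoint")
  }
  if (anyDuplicated(out[, c("id", "timepoint")])) {
    stop("duplicate individual-timepoint records")
  }
  if (any(out$srs_total < 0 | out$srs_total > srs_max_total())) {
    stop("SRS totals must lie in [0, ", srs_max_total(), "]")
  }
  invisible(cohort)
}

#' @exportS3Method base::print
print.trial_cohort <- function(x, ...) {
  cat("<trial_cohort> ", nrow(x$individuals), " individuals (",
      sum(x$individuals$arm == "SSGT"), " SSGT / ",
      sum(x$individuals$arm == "standard_care"), " standard care), ",
      nrow(x$outcomes), " outcome records\n", sep = "")
  print(table(x$outcomes$timepoint))
  invisible(x)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing genotypes, reference summary statistics
#' and the trial cohort from a single configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `genotypes`, `summary_stats`, `cohort` and
#'   `truth` (the cohort's truth record).
#' @export
simulate_trial <- function(cfg = sim_config()) {
  g <- simulate_ld_genotypes(cfg)
  ss <- simulate_summary_stats(g, n_causal = cfg$n_causal,
                               effect_sd = cfg$effect_sd,
                               gwas_n = cfg$gwas_n, seed = cfg$seed + 2L)
  cohort <- simulate_trial_cohort(g, ss, cfg)
  list(genotypes = g, summary_stats = ss, cohort = cohort,
       truth = attr(cohort, "truth"))
}
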