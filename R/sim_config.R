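#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the analysed trial: 188 genotyped participants in two arms (99 active
#' social skills group training, 89 standard care) recruited across 13
#' clinical centers, with parent-reported SRS totals recorded at
#' pre-intervention, post-intervention and 3-month follow-up, and
#' missing-completely-at-random dropout leaving about 169 individuals with a
#' post record and 152 with a follow-up record.
#'
#' The outcome model is
#' `SRS = baseline + time + arm:time + PRS terms + center + individual + noise`,
#' where the PRS terms are `prs_main_beta * z`, `prs_time_beta[t] * z` at
#' non-baseline timepoint `t`, and `prs_time_arm_beta[t] * z` additionally in
#' the active arm; `z` is the individual's standardized genetic score. Totals
#' are rounded and truncated to the instrument range `[0, 195]`.
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of variants; must equal `sum(ld_block_sizes)`.
#' @param ld_block_sizes Integer vector of LD block sizes.
#' @param within_block_r Latent (copula) correlation of variants within a
#'   block, in `[0, 1)`; cross-block correlation is 0.
#' @param maf_range Range the per-variant minor allele frequency is drawn
#'   from, within `(0, 0.5]`.
#' @param n_centers Number of clinical centers (random-intercept grouping).
#' @param arm_sizes Length-2 vector `c(active, control)`; must sum to
#'   `n_individuals`.
#' @param timepoints Ordered timepoint labels; the first is baseline and is
#'   never dropped.
#' @param dropout_rates Per-timepoint probability that a record is missing;
#'   the baseline rate must be 0.
#' @param baseline_srs Expected SRS total at baseline (SRS points).
#' @param time_effect Per-timepoint mean shift (SRS points; first entry 0).
#' @param arm_time_effect Additional per-timepoint shift in the active arm
#'   (SRS points; first entry 0).
#' @param prs_main_beta SRS points per PRS standard deviation, all records.
#' @param prs_time_beta SRS points per PRS SD at each non-baseline
#'   timepoint (length `length(timepoints) - 1`), both arms.
#' @param prs_time_arm_beta Additional SRS points per PRS SD at each
#'   non-baseline timepoint in the active arm. The default places a
#'   `+6.7`-point penalty per PRS SD at follow-up, the magnitude of the
#'   headline three-way interaction.
#' @param center_sd,individual_sd,residual_sd Random-effect and residual
#'   standard deviations (SRS points).
#' @param cnv_carrier_rate Probability of carrying a clinically significant
#'   CNV; large (>500 kb) CNV carriage is a superset drawn at the same rate.
#' @param comorbidity_prs_shift Log-odds increase of ADHD comorbidity per
#'   PRS SD.
#' @param comorbidity_base_rate Baseline ADHD comorbidity probability.
#' @param prs_phenotype Which phenotype's score drives the outcome model
#'   (the genotype-derived score); the other two are correlated Gaussians.
#' @param n_causal Number of causal variants in the simulated reference
#'   GWAS; defaults to `min(30, n_variants)`.
#' @param effect_sd SD of causal log odds ratios.
#' @param gwas_n Sample size of the simulated reference GWAS.
#' @param seed Integer seed; identical configs give bit-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 188,
                       n_variants = 300,
                       ld_block_sizes = rep(10L, 30L),
                       within_block_r = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_centers = 13,
                       arm_sizes = c(99, 89),
                       timepoints = c("pre", "post", "followup"),
                       dropout_rates = c(0, 19 / 188, 36 / 188),
                       baseline_srs = 100,
                       time_effect = c(0, -6, -8),
                       arm_time_effect = c(0, -2, -3),
                       prs_main_beta = 0,
                       prs_time_beta = c(-4.7, -5.3),
                       prs_time_arm_beta = c(0, 6.7),
                       center_sd = 5,
                       individual_sd = 20,
                       residual_sd = 10,
                       cnv_carrier_rate = 0.1,
                       comorbidity_prs_shift = 0.4,
                       comorbidity_base_rate = 0.5,
                       prs_phenotype = "ADHD",
                       n_causal = NULL,
                       effect_sd = 0.1,
                       gwas_n = 5e4,
                       seed = 1L) {
  if (is.null(n_causal)) n_causal <- min(30L, as.integer(n_variants))
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    ld_block_sizes = as.integer(ld_block_sizes),
    within_block_r = within_block_r,
    maf_range = maf_range,
    n_centers = as.integer(n_centers),
    arm_sizes = as.integer(arm_sizes),
    timepoints = as.character(timepoints),
    dropout_rates = dropout_rates,
    baseline_srs = baseline_srs,
    time_effect = time_effect,
    arm_time_effect = arm_time_effect,
    prs_main_beta = prs_main_beta,
    prs_time_beta = prs_time_beta,
    prs_time_arm_beta = prs_time_arm_beta,
    center_sd = center_sd,
    individual_sd = individual_sd,
    residual_sd = residual_sd,
    cnv_carrier_rate = cnv_carrier_rate,
    comorbidity_prs_shift = comorbidity_prs_shift,
    comorbidity_base_rate = comorbidity_base_rate,
    prs_phenotype = match.arg(prs_phenotype, c("ADHD", "ASD", "EA")),
    n_causal = as.integer(n_causal),
    effect_sd = effect_sd,
    gwas_n = as.integer(gwas_n),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  nt <- length(cfg$timepoints)
  if (sum(cfg$ld_block_sizes) != cfg$n_variants) {
    stop("ld_block_sizes must sum to n_variants (",
         sum(cfg$ld_block_sizes), " != ", cfg$n_variants, ")")
  }
  if (sum(cfg$arm_sizes) != cfg$n_individuals) {
    stop("arm_sizes must sum to n_individuals")
  }
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1) {
    stop("within_block_r must be in [0, 1)")
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (length(cfg$dropout_rates) != nt) {
    stop("dropout_rates must have one entry per timepoint")
  }
  if (cfg$dropout_rates[1] != 0) {
    stop("the baseline timepoint can never be dropped")
  }
  if (any(cfg$dropout_rates < 0 | cfg$dropout_rates >= 1)) {
    stop("dropout_rates must be in [0, 1)")
  }
  if (any(c(cfg$center_sd, cfg$individual_sd, cfg$residual_sd) < 0)) {
    stop("variance-component SDs must be >= 0")
  }
  if (length(cfg$time_effect) != nt || length(cfg$arm_time_effect) != nt) {
    stop("time_effect and arm_time_effect need one entry per timepoint")
  }
  if (length(cfg$prs_time_beta) != nt - 1 ||
      length(cfg$prs_time_arm_beta) != nt - 1) {
    stop("prs_time_beta / prs_time_arm_beta need one entry per ",
         "non-baseline timepoint")
  }
  if (cfg$cnv_carrier_rate < 0 || cfg$cnv_carrier_rate > 1) {
    stop("cnv_carrier_rate must be a probability")
  }
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_variants) {
    stop("n_causal must be between 0 and n_variants")
  }
  invisible(cfg)
}
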