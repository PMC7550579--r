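#' Mixed-model analysis specification
#'
#' Describes one outcome model: which phenotype's PRS enters, whether the
#' interaction is the full PRS x time x intervention three-way structure
#' or the within-sample PRS x time two-way structure, which CNV carrier
#' flag is adjusted for, and (for ADHD) whether clinical ADHD comorbidity
#' is a fixed covariate. Comorbidity adjustment is forced on when the
#' phenotype is ADHD.
#'
#' @param prs_phenotype `"ADHD"`, `"ASD"` or `"EA"`.
#' @param interaction `"three_way"` (PRS x time x arm, all individuals) or
#'   `"two_way"` (PRS x time, optionally on one arm).
#' @param cnv_adjustment `"clinsig"`, `"large"` or `"none"`.
#' @param adjust_adhd_comorbidity Logical; default `TRUE` iff the
#'   phenotype is ADHD (and always forced on for ADHD).
#' @param arm_subset Optional arm label (`"SSGT"` or `"standard_care"`)
#'   restricting a two-way model to one arm.
#' @return A list of class `mlm_spec`.
#' @export
mlm_spec <- function(prs_phenotype = c("ADHD", "ASD", "EA"),
                     interaction = c("three_way", "two_way"),
                     cnv_adjustment = c("clinsig", "large", "none"),
                     adjust_adhd_comorbidity = NULL,
                     arm_subset = NULL) {
  prs_phenotype <- match.arg(prs_phenotype)
  interaction <- match.arg(interaction)
  cnv_adjustment <- match.arg(cnv_adjustment)
  if (prs_phenotype == "ADHD") {
    adjust_adhd_comorbidity <- TRUE
  } else if (is.null(adjust_adhd_comorbidity)) {
    adjust_adhd_comorbidity <- FALSE
  }
  if (!is.null(arm_subset)) {
    arm_subset <- match.arg(arm_subset, c("SSGT", "standard_care"))
    if (interaction == "three_way") {
      stop("arm subsets are only meaningful for two-way models")
    }
  }
  structure(list(prs_phenotype = prs_phenotype, interaction = interaction,
                 cnv_adjustment = cnv_adjustment,
                 adjust_adhd_comorbidity = adjust_adhd_comorbidity,
                 arm_subset = arm_subset),
            class = "mlm_spec")
}

#' Build the mixed-model design
#'
#' Merges individual covariates with the longitudinal outcome records and
#' assembles the model formula. Time is a treatment-coded factor with the
#' baseline as reference, arm with standard care as reference, so an
#' interaction coefficient reads directly as the SRS-point difference per
#' PRS SD at that timepoint (in the active arm, for the three-way terms);
#' positive values mean an inferior outcome under SSGT. Fixed covariates:
#' age group, sex, the four ancestry PCs, the spec'd CNV flag and (when
#' required) ADHD comorbidity. Random intercepts: clinical center and
#' individual.
#'
#' @param cohort A `trial_cohort`.
#' @param spec An [mlm_spec()].
#' @param include_prs Set `FALSE` to build the nested reduced model with
#'   every PRS-containing term removed (used by [delta_r2()]).
#' @param prs_values Optional numeric vector (one value per individual, in
#'   `cohort$individuals` order) overriding the stored PRS column, e.g. to
#'   sweep thresholds.
#' @return List with `formula`, `data` (one row per observation) and the
#'   spec, of class `mlm_design`.
#' @export
build_design <- function(cohort, spec, include_prs = TRUE,
                         prs_values = NULL) {
  validate_trial_cohort(cohort)
  ind <- cohort$individuals
  prs_col <- paste0("prs_", spec$prs_phenotype)
  if (is.null(prs_values)) {
    if (!prs_col %in% names(ind)) {
      if (include_prs) stop("cohort is missing the PRS column ", prs_col)
      prs_values <- numeric(nrow(ind))
    } else {
      prs_values <- ind[[prs_col]]
    }
  }
  if (length(prs_values) != nrow(ind)) {
    stop("prs_values must have one value per individual")
  }
  ind$prs <- prs_values
  d <- merge(cohort$outcomes, ind, by = "id")
  d$time <- d$timepoint
  if (!is.null(spec$arm_subset)) {
    d <- d[d$arm == spec$arm_subset, , drop = FALSE]
    d$arm <- droplevels(d$arm)
  }

  covars <- c("age_group", "sex", "pc1", "pc2", "pc3", "pc4")
  covars <- c(covars, switch(spec$cnv_adjustment,
                             clinsig = "cnv_clinsig",
                             large = "cnv_large",
                             none = NULL))
  if (spec$adjust_adhd_comorbidity) covars <- c(covars, "adhd_comorbid")

  fixed <- if (include_prs) {
    if (spec$interaction == "three_way") "prs * time * arm"
    else "prs * time"
  } else {
    if (spec$interaction == "three_way") "time * arm" else "time"
  }
  fml <- stats::as.formula(paste(
    "srs_total ~", fixed, "+", paste(covars, collapse = " + "),
    "+ (1 | center) + (1 | id)"
  ))
  structure(list(formula = fml, data = d, spec = spec,
                 include_prs = include_prs),
            class = "mlm_design")
}

#' Fit the two-random-intercept mixed model
#'
#' Restricted maximum likelihood fit of the design via `lme4::lmer`, with
#' Wald z two-sided P values on the fixed effects. A singular fit (a
#' variance component estimated at zero) is flagged but not an error.
#'
#' @param design An `mlm_design` from [build_design()].
#' @param reml Fit criterion; `FALSE` refits by maximum likelihood (used
#'   for likelihood comparisons of nested fixed structures).
#' @return An `mlm_fit`: coefficient table (`beta`, `se`, `ci95`, `p`),
#'   variance components (`individual`, `center`, `residual`), log
#'   likelihood, counts, `converged`/`singular` flags and the underlying
#'   `lmerMod` object.
#' @export
fit_mlm <- function(design, reml = TRUE) {
  d <- design$data
  if (length(unique(d$center)) < 2) {
    stop("at least 2 centers are required")
  }
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(design$formula, data = d, REML = reml)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  conv <- fit@optinfo$conv
  converged <- is.null(conv$lme4$code) || conv$lme4$code >= 0
  singular <- lme4::isSingular(fit)

  sm <- summary(fit)$coefficients
  beta <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  p <- 2 * stats::pnorm(-abs(beta / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(
    individual = vc$vcov[vc$grp == "id"],
    center = vc$vcov[vc$grp == "center"],
    residual = vc$vcov[vc$grp == "Residual"]
  )
  structure(list(
    beta = beta, se = se,
    ci95 = cbind(lo = beta - 1.96 * se, hi = beta + 1.96 * se),
    p = p,
    varcomp = varcomp,
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(d),
    n_individuals = length(unique(d$id)),
    converged = converged,
    singular = singular,
    model = fit,
    design = design
  ), class = "mlm_fit")
}

#' @exportS3Method base::print
print.mlm_fit <- function(x, ...) {
  cat("<mlm_fit> ", x$n_obs, " observations from ", x$n_individuals,
      " individuals\n", sep = "")
  tab <- data.frame(beta = x$beta, se = x$se, p = x$p)
  print(round(tab, 4))
  cat("variance components:",
      paste(names(x$varcomp), round(x$varcomp, 2), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Family-wise significance threshold
#'
#' Bonferroni-style nominal threshold for testing several PRS phenotypes:
#' `alpha / n_phenotypes`, rounded to 4 decimals (0.0167 for three
#' phenotypes at alpha 0.05).
#'
#' @param n_phenotypes Number of phenotypes tested (>= 1).
#' @param alpha Family-wise level.
#' @return The per-test threshold.
#' @export
significance_threshold <- function(n_phenotypes, alpha = 0.05) {
  if (n_phenotypes < 1) stop("n_phenotypes must be >= 1")
  round(alpha / n_phenotypes, 4)
}

#' Extract the PRS interaction coefficients
#'
#' Pulls the PRS x timepoint (x arm, for three-way models) rows from a
#' fit, with 95% confidence intervals, Wald P values and a significance
#' flag against the family threshold.
#'
#' @param fit An `mlm_fit`.
#' @param n_phenotypes,alpha Passed to [significance_threshold()].
#' @return Data frame: `term`, `beta`, `se`, `ci_lo`, `ci_hi`, `p`,
#'   `significant`.
#' @export
interaction_estimates <- function(fit, n_phenotypes = 3, alpha = 0.05) {
  spec <- fit$design$spec
  tps <- levels(fit$design$data$time)[-1]
  terms <- if (spec$interaction == "three_way") {
    paste0("prs:time", tps, ":armSSGT")
  } else {
    paste0("prs:time", tps)
  }
  missing_terms <- setdiff(terms, names(fit$beta))
  if (length(missing_terms)) {
    stop("term(s) not in the fit: ", paste(missing_terms, collapse = ", "))
  }
  thr <- significance_threshold(n_phenotypes, alpha)
  data.frame(
    term = terms,
    beta = unname(fit$beta[terms]),
    se = unname(fit$se[terms]),
    ci_lo = unname(fit$ci95[terms, "lo"]),
    ci_hi = unname(fit$ci95[terms, "hi"]),
    p = unname(fit$p[terms]),
    significant = unname(fit$p[terms] < thr),
    stringsAsFactors = FALSE
  )
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance decomposition for a Gaussian random-intercept model: the
#' marginal R-squared is the variance of the fixed-effect linear
#' predictor over the total (fixed + center + individual + residual)
#' variance; the conditional R-squared adds both random-intercept
#' variances to the numerator.
#'
#' @param fit An `mlm_fit`.
#' @return List with `marginal` and `conditional`, each in `[0, 1]` and
#'   `marginal <= conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  X <- stats::model.matrix(fit$model)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit$model)))
  total <- var_f + sum(fit$varcomp)
  if (total <= 0) stop("total variance is zero")
  list(marginal = unname(var_f / total),
       conditional = unname((var_f + fit$varcomp[["individual"]] +
                               fit$varcomp[["center"]]) / total))
}

#' R-squared gained by adding the PRS
#'
#' Fits the full model and the nested model with every PRS-containing
#' term (main effect and all interactions) removed, both by REML with
#' otherwise identical fixed structure, and differences their marginal
#' and conditional R-squared.
#'
#' @param cohort A `trial_cohort`.
#' @param spec An [mlm_spec()].
#' @param prs_values Optional per-individual PRS override (see
#'   [build_design()]).
#' @return List: `marginal`, `conditional` (the differences), plus
#'   `full` and `reduced` R-squared pairs.
#' @export
delta_r2 <- function(cohort, spec, prs_values = NULL) {
  full <- fit_mlm(build_design(cohort, spec, include_prs = TRUE,
                               prs_values = prs_values))
  reduced <- fit_mlm(build_design(cohort, spec, include_prs = FALSE))
  r_full <- nakagawa_r2(full)
  r_red <- nakagawa_r2(reduced)
  list(marginal = r_full$marginal - r_red$marginal,
       conditional = r_full$conditional - r_red$conditional,
       full = r_full, reduced = r_red)
}

#' R-squared grid over phenotypes and thresholds
#'
#' Reproduces the variance-explained report: for each phenotype's
#' standardized score at each P-value threshold, the marginal and
#' conditional R-squared gained by adding the PRS to the model.
#'
#' @param cohort A `trial_cohort`.
#' @param profiles Named list (`ADHD`, `ASD`, `EA`, any subset) of
#'   standardized `prs_profile` objects aligned to the cohort's
#'   individuals.
#' @param interaction,cnv_adjustment Passed to [mlm_spec()].
#' @return Data frame: `phenotype`, `threshold`, `delta_marginal`,
#'   `delta_conditional`.
#' @export
r2_grid <- function(cohort, profiles, interaction = "three_way",
                    cnv_adjustment = "clinsig") {
  rows <- list()
  for (ph in names(profiles)) {
    prof <- profiles[[ph]]
    if (!identical(prof$individual_ids, cohort$individuals$id)) {
      stop("profile for ", ph, " is not aligned to the cohort")
    }
    for (t in seq_along(prof$thresholds)) {
      dr <- delta_r2(cohort,
                     mlm_spec(ph, interaction = interaction,
                              cnv_adjustment = cnv_adjustment),
                     prs_values = prof$z[, t])
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, threshold = prof$thresholds[t],
        delta_marginal = dr$marginal, delta_conditional = dr$conditional,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
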