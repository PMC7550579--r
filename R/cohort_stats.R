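#' Pearson correlation with t-distribution P value
#'
#' Thin wrapper around `stats::cor.test` returning the sample Pearson
#' correlation with its two-sided P value.
#'
#' @param x,y Numeric vectors of equal length (>= 3, finite, nonzero
#'   variance).
#' @return List: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sided Student's t test between two groups
#'
#' Equal-variance (pooled) t test by default, matching the classical
#' Student test; set `var_equal = FALSE` for the Welch variant.
#'
#' @param values Numeric vector.
#' @param groups Vector with exactly two levels, each with >= 2 members.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return List: `t`, `p`, `df`, `group_means` (named by group level).
#' @export
group_t_test <- function(values, groups, var_equal = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("both groups need at least 2 members")
  tt <- stats::t.test(values ~ groups, var.equal = var_equal)
  means_raw <- tapply(values, groups, mean)
  means <- stats::setNames(as.numeric(means_raw), names(means_raw))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), group_means = means)
}

#' PRS-by-CNV interaction on SRS change scores
#'
#' Ordinary least squares of the change score on the PRS, CNV carrier
#' status, their product and optional covariates. The interaction row
#' tests whether the PRS slope differs between carriers and noncarriers.
#'
#' @param change Numeric change scores.
#' @param prs Standardized PRS values.
#' @param cnv Logical (or 0/1) carrier flags; both classes need >= 2
#'   members.
#' @param covariates Optional data frame of additional covariates.
#' @return List with the full coefficient table (`coefficients`) and the
#'   interaction row as `beta`, `se`, `p`.
#' @export
prs_cnv_interaction <- function(change, prs, cnv, covariates = NULL) {
  cnv <- as.logical(cnv)
  if (sum(cnv) < 2 || sum(!cnv) < 2) {
    stop("need at least 2 carriers and 2 noncarriers")
  }
  d <- data.frame(change = change, prs = prs, cnv = as.numeric(cnv))
  fml <- change ~ prs * cnv
  if (!is.null(covariates)) {
    d <- cbind(d, covariates)
    fml <- stats::as.formula(paste("change ~ prs * cnv +",
                                   paste(names(covariates), collapse = " + ")))
  }
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  list(coefficients = sm,
       beta = sm["prs:cnv", "Estimate"],
       se = sm["prs:cnv", "Std. Error"],
       p = sm["prs:cnv", "Pr(>|t|)"])
}
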