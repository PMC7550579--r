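#' Cluster-bootstrap power estimation for a PRS interaction term
#'
#' For each target sample size, individuals are resampled with
#' replacement (carrying all their longitudinal records); resampled
#' duplicates receive fresh identifiers so the individual random
#' intercept stays well defined, and keep their original center. The
#' spec'd mixed model is refit on each resample and the power is the
#' fraction of converged fits whose target-term Wald P value is below
#' `alpha`.
#'
#' @param cohort A `trial_cohort`.
#' @param spec An [mlm_spec()].
#' @param target_term Coefficient name to monitor, e.g.
#'   `"prs:timefollowup:armSSGT"`.
#' @param sizes Integer vector of resample sizes (each >= 20).
#' @param reps Bootstrap replicates per size.
#' @param alpha Nominal level declaring a replicate significant.
#' @param seed Integer seed; fixed seed gives an identical curve.
#' @return A `power_curve` data frame: `n`, `power`, `mc_se`
#'   (`sqrt(power (1 - power) / reps)` over converged fits), `reps`,
#'   `n_nonconverged`, `alpha`. A size with more than 20% non-converged
#'   fits carries a warning.
#' @export
bootstrap_power <- function(cohort, spec, target_term, sizes,
                            reps = 1000, alpha = 0.05, seed = 1L) {
  validate_trial_cohort(cohort)
  if (any(sizes < 20)) stop("resample sizes must be at least 20")
  set.seed(as.integer(seed))
  ind <- cohort$individuals
  out_by_id <- split(cohort$outcomes, cohort$outcomes$id)

  one_rep <- function(n) {
    pick <- sample.int(nrow(ind), n, replace = TRUE)
    new_ind <- ind[pick, , drop = FALSE]
    new_ids <- sprintf("b%05d", seq_len(n))
    reps_out <- out_by_id[new_ind$id]
    sizes_out <- vapply(reps_out, nrow, integer(1))
    new_out <- do.call(rbind, reps_out)
    new_out$id <- rep(new_ids, sizes_out)
    new_ind$id <- new_ids
    rownames(new_ind) <- rownames(new_out) <- NULL
    boot <- structure(list(individuals = new_ind, outcomes = new_out),
                      class = "trial_cohort")
    fit <- tryCatch(fit_mlm(build_design(boot, spec)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !target_term %in% names(fit$p)) {
      return(NA_real_)
    }
    unname(fit$p[target_term])
  }

  rows <- lapply(sizes, function(n) {
    ps <- vapply(seq_len(reps), function(i) one_rep(n), numeric(1))
    bad <- sum(is.na(ps))
    ok <- reps - bad
    if (bad > 0.2 * reps) {
      warning("more than 20% non-converged fits at n = ", n)
    }
    pw <- if (ok > 0) mean(ps[!is.na(ps)] < alpha) else NA_real_
    data.frame(n = n, power = pw,
               mc_se = if (ok > 0) sqrt(pw * (1 - pw) / ok) else NA_real_,
               reps = reps, n_nonconverged = bad, alpha = alpha)
  })
  structure(do.call(rbind, rows), class = c("power_curve", "data.frame"))
}
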