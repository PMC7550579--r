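#' Per-individual SRS change score
#'
#' `change = SRS(endpoint) - SRS(baseline)`; negative values mean
#' improvement. Individuals without an endpoint record are excluded and
#' counted.
#'
#' @param cohort A `trial_cohort`.
#' @param endpoint `"post"` or `"followup"` (any non-baseline timepoint
#'   label present in the cohort).
#' @return Data frame `id`, `change`, with attribute `"excluded"` listing
#'   individuals lacking the endpoint.
#' @export
delta_srs <- function(cohort, endpoint = c("post", "followup")) {
  endpoint <- match.arg(endpoint, levels(cohort$outcomes$timepoint)[-1])
  out <- cohort$outcomes
  base_tp <- levels(out$timepoint)[1]
  pre <- out[out$timepoint == base_tp, c("id", "srs_total")]
  end <- out[out$timepoint == endpoint, c("id", "srs_total")]
  if (nrow(end) == 0) stop("no individual has a record at ", endpoint)
  m <- merge(pre, end, by = "id", suffixes = c("_pre", "_end"))
  res <- data.frame(id = m$id,
                    change = m$srs_total_end - m$srs_total_pre,
                    stringsAsFactors = FALSE)
  attr(res, "excluded") <- setdiff(pre$id, end$id)
  res
}

#' Annotate variants to genes
#'
#' A variant is assigned to every gene whose extended interval
#' `[start - window, end + window]` (inclusive bounds, same chromosome)
#' contains its position; overlapping genes may share variants.
#'
#' @param variants Data frame with `id`, `chrom`, `pos` (e.g.
#'   `g$variants`).
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param window_kb Flanking window in kb added to both gene ends.
#' @return Named list: gene id -> character vector of variant ids (genes
#'   with no variant get an empty vector).
#' @export
annotate_snps <- function(variants, genes, window_kb = 0) {
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  w <- window_kb * 1000
  res <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- variants$chrom == genes$chrom[i] &
      variants$pos >= genes$start[i] - w &
      variants$pos <= genes$end[i] + w
    variants$id[hit]
  })
  stats::setNames(res, genes$gene_id)
}

#' Gene-level association statistics by permutation
#'
#' The change score is first residualized on the cohort covariates by
#' ordinary least squares. Each gene's statistic is the mean squared
#' Pearson correlation between its variants' (mean-imputed) dosages and
#' the residual; its P value comes from `n_perm` permutations of the
#' residual vector, shared across genes so the inter-gene correlation
#' structure is preserved, with the add-one correction
#' `P = (1 + #(perm >= obs)) / (n_perm + 1)`. The gene z-score is the
#' probit `qnorm(1 - P)` after clamping `P` to
#' `[1/(n_perm + 1), 1 - 1/(n_perm + 1)]`.
#'
#' This is a transparent permutation-calibrated gene statistic with the
#' same competitive downstream logic as the established gene-set tools,
#' not a re-implementation of any of them.
#'
#' @param g A [genotype_matrix()].
#' @param change Data frame from [delta_srs()] (`id`, `change`).
#' @param covariates Data frame of per-individual covariates with an `id`
#'   column; rows are matched to `change$id`.
#' @param gene_map Named list from [annotate_snps()].
#' @param genes Data frame of gene records (`gene_id`, `chrom`, `start`,
#'   `end`) supplying the length covariate.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Data frame: `gene_id`, `stat`, `p`, `z`, `n_snps`,
#'   `length_bp`. Genes with no polymorphic mapped variant are skipped
#'   and listed in attribute `"skipped"`.
#' @export
gene_stats <- function(g, change, covariates, gene_map, genes,
                       n_perm = 1000, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- change$id
  gi <- match(ids, g$individual_ids)
  if (anyNA(gi)) stop("change scores for individuals missing from genotypes")
  ci <- match(ids, covariates$id)
  if (anyNA(ci)) stop("change scores for individuals missing covariates")
  X <- stats::model.matrix(
    ~ ., data = covariates[ci, setdiff(names(covariates), "id"),
                           drop = FALSE]
  )
  resid <- stats::lm.fit(X, change$change)$residuals
  n <- length(resid)

  d <- g$dosage[gi, , drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- mu[na_idx[, 2]]
  }
  snp_sd <- apply(d, 2, stats::sd)
  poly <- snp_sd > 0
  Zs <- scale(d[, poly, drop = FALSE])
  snp_ids <- colnames(d)[poly]

  keep_gene <- vapply(gene_map, function(v) any(v %in% snp_ids), logical(1))
  skipped <- names(gene_map)[!keep_gene]
  gene_map <- gene_map[keep_gene]
  if (length(gene_map) == 0) stop("no gene has a polymorphic mapped variant")

  R <- matrix(0, n, n_perm + 1L)
  R[, 1] <- resid
  for (b in seq_len(n_perm)) R[, b + 1L] <- resid[sample.int(n)]
  R <- scale(R)
  # squared SNP-phenotype correlations, observed in column 1
  C2 <- (crossprod(Zs, R) / (n - 1))^2

  stat_mat <- t(vapply(gene_map, function(v) {
    rows <- match(intersect(v, snp_ids), snp_ids)
    colMeans(C2[rows, , drop = FALSE])
  }, numeric(n_perm + 1L)))

  obs <- stat_mat[, 1]
  exceed <- rowSums(stat_mat[, -1, drop = FALSE] >=
                      obs - 1e-12)
  p <- (1 + exceed) / (n_perm + 1)
  p_cl <- pmin(pmax(p, 1 / (n_perm + 1)), 1 - 1 / (n_perm + 1))
  n_snps <- vapply(gene_map, function(v) length(intersect(v, snp_ids)),
                   integer(1))
  glen <- genes$end - genes$start + 1
  res <- data.frame(
    gene_id = names(gene_map),
    stat = unname(obs),
    p = unname(p),
    z = unname(stats::qnorm(1 - p_cl)),
    n_snps = unname(n_snps),
    length_bp = glen[match(names(gene_map), genes$gene_id)],
    stringsAsFactors = FALSE
  )
  attr(res, "skipped") <- skipped
  res
}

#' Competitive gene-set test
#'
#' Ordinary least-squares regression of the gene z-scores on the
#' set-membership indicator, adjusting for gene size and variant count
#' (raw and log): `z ~ member + n_snps + log(n_snps) + length_bp +
#' log(length_bp)`. The membership coefficient is the set effect; a
#' positive value means genes in the set carry more association with the
#' SRS change than genes outside it (a decreased intervention response).
#'
#' @param stats_df Data frame from [gene_stats()].
#' @param collection Named list: set name -> gene ids (see [read_gmt()]).
#' @param set_name Which set to test.
#' @return One-row data frame: `set`, `beta`, `se`, `p`, `corrected_p`
#'   (`NA` until [correct_pvalues()]), `n_genes_scored`.
#' @export
competitive_test <- function(stats_df, collection, set_name) {
  if (!set_name %in% names(collection)) stop("unknown gene set: ", set_name)
  member <- as.numeric(stats_df$gene_id %in% collection[[set_name]])
  n_in <- sum(member)
  n_out <- sum(1 - member)
  if (n_in < 2 || n_out < 2) {
    stop("set '", set_name, "' needs >= 2 scored genes inside and outside ",
         "(has ", n_in, " / ", n_out, ")")
  }
  d <- data.frame(z = stats_df$z, member = member,
                  n_snps = stats_df$n_snps,
                  log_n_snps = log(stats_df$n_snps),
                  length_bp = stats_df$length_bp,
                  log_length = log(stats_df$length_bp))
  fit <- stats::lm(z ~ member + n_snps + log_n_snps + length_bp + log_length,
                   data = d)
  sm <- summary(fit)$coefficients
  data.frame(set = set_name,
             beta = sm["member", "Estimate"],
             se = sm["member", "Std. Error"],
             p = sm["member", "Pr(>|t|)"],
             corrected_p = NA_real_,
             n_genes_scored = nrow(stats_df),
             stringsAsFactors = FALSE)
}

#' Multiple-testing correction across gene sets
#'
#' @param results Data frame of stacked [competitive_test()] rows (the
#'   tested family, e.g. all sets at one endpoint).
#' @param method `"bonferroni"` or `"BH"`.
#' @return The results with `corrected_p` filled (capped at 1).
#' @export
correct_pvalues <- function(results, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (nrow(results) < 1) stop("no results to correct")
  results$corrected_p <- stats::p.adjust(results$p, method = method)
  results
}

#' Run the competitive gene-set analysis end to end
#'
#' Computes change scores at the endpoint, builds the cohort covariate
#' matrix (age group, sex, intervention arm, four ancestry PCs and the
#' chosen CNV carrier flag), annotates variants to genes, derives
#' permutation-calibrated gene statistics and tests every set in the
#' collection competitively, with multiple-testing correction across the
#' family.
#'
#' @param g A [genotype_matrix()].
#' @param cohort A `trial_cohort`.
#' @param genes Gene-location data frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param collection Named list of gene sets, optionally with a
#'   `"category"` attribute (named character vector) as from
#'   [read_gmt()].
#' @param endpoint `"post"` or `"followup"`.
#' @param cnv Which CNV carrier flag to adjust for: `"clinsig"`,
#'   `"large"` or `"none"`.
#' @param window_kb Annotation window.
#' @param n_perm,seed Passed to [gene_stats()].
#' @param method Correction method for [correct_pvalues()].
#' @return Data frame with one row per testable set: `set`, `category`,
#'   `n_genes`, `beta`, `se`, `p`, `corrected_p`, `n_genes_scored`.
#' @export
geneset_analysis <- function(g, cohort, genes, collection,
                             endpoint = "post", cnv = "clinsig",
                             window_kb = 0, n_perm = 1000, seed = 1L,
                             method = "bonferroni") {
  change <- delta_srs(cohort, endpoint)
  ind <- cohort$individuals
  cov_cols <- c("id", "age_group", "sex", "arm", "pc1", "pc2", "pc3", "pc4")
  cov_cols <- c(cov_cols, switch(cnv, clinsig = "cnv_clinsig",
                                 large = "cnv_large", none = NULL))
  covariates <- ind[, cov_cols]
  gene_map <- annotate_snps(g$variants, genes, window_kb)
  gs <- gene_stats(g, change, covariates, gene_map, genes,
                   n_perm = n_perm, seed = seed)
  categories <- attr(collection, "category")
  rows <- list()
  for (nm in names(collection)) {
    row <- tryCatch(competitive_test(gs, collection, nm),
                    error = function(e) NULL)
    if (is.null(row)) next
    row$category <- if (!is.null(categories) && nm %in% names(categories)) {
      categories[[nm]]
    } else NA_character_
    row$n_genes <- length(collection[[nm]])
    rows[[nm]] <- row
  }
  if (!length(rows)) stop("no gene set was testable")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- correct_pvalues(res, method)
  res[, c("set", "category", "n_genes", "beta", "se", "p", "corrected_p",
          "n_genes_scored")]
}
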