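---
title: "Polygenic moderation of intervention response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic moderation of intervention response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prstrial)
```

## The scientific question

Behavioural interventions for autism, such as social skills group training
(SSGT), show heterogeneous effects across individuals. One candidate source
of that heterogeneity is common genetic variation. `prstrial` implements an
analysis pipeline asking whether polygenic risk scores (PRS) for ASD, ADHD
and educational attainment — and, separately, common-variant burden in
curated gene sets — moderate the trajectory of the parent-reported Social
Responsiveness Scale (SRS, 65 items, total 0–195, higher = more severe)
across a two-arm longitudinal trial with assessments at baseline,
post-intervention and 3-month follow-up.

Because the clinical genotype and phenotype data such an analysis was
designed for are not publicly shareable, the package ships a first-class
synthetic-data generator that emulates the study design (188 genotyped
participants: 99 SSGT, 89 standard care, 13 clinical centers, dropout to
roughly 169 at post and 152 at follow-up) with known, configurable effects,
so every stage of the pipeline is testable end to end.

## The outcome model

The central model is a Gaussian linear mixed model for the SRS total
$y_{ijt}$ of individual $i$ at center $j$ and timepoint $t$:

$$
y_{ijt} = \beta_0 + \mathbf{x}_i^\top\boldsymbol\gamma
 + \beta_1 z_i + \beta_{2t}\,\mathrm{time}_t + \beta_{3}\,\mathrm{arm}_i
 + \beta_{4t}\, z_i \mathrm{time}_t
 + \beta_{5t}\, \mathrm{time}_t \mathrm{arm}_i
 + \beta_{6t}\, z_i \mathrm{time}_t \mathrm{arm}_i
 + u_j + v_i + \varepsilon_{ijt},
$$

with $z_i$ the standardized PRS, treatment-coded factors (baseline and
standard care as references), covariates $\mathbf{x}_i$ = age group, sex,
four ancestry principal components, a CNV carrier flag, and ADHD
comorbidity when the ADHD score is analysed; $u_j \sim N(0,\sigma^2_c)$,
$v_i \sim N(0,\sigma^2_i)$, $\varepsilon \sim N(0,\sigma^2_e)$. The
three-way coefficients $\beta_{6t}$ are the quantities of interest: they
read directly as "SRS points per PRS standard deviation at timepoint $t$
in the active arm relative to standard care", so positive values mean an
inferior SSGT outcome for higher-PRS individuals. The two-way variant
drops the arm factor (optionally restricting to one arm) and reports
$\beta_{4t}$.

Fits use restricted maximum likelihood via `lme4`, with Wald $z$ two-sided
P values. We deliberately use no degrees-of-freedom correction: with ~500
observations and ~15 fixed parameters the $t$ and $z$ references are
nearly identical, and the choice keeps P values well defined on resampled
and simulated data of any size. Testing three phenotype scores motivates
the family threshold $\alpha/3 = 0.0167$
(`significance_threshold(3, 0.05)`).

Singular fits (a variance component estimated at zero) are flagged but
accepted — they occur by design in the zero-variance calibration tests,
where the mixed model must collapse to ordinary least squares (the suite
checks agreement within $10^{-4}$ SRS points).

## Variance explained

For each fit, the marginal $R^2$ is
$\operatorname{var}(X\hat\beta) / (\operatorname{var}(X\hat\beta) +
\hat\sigma^2_c + \hat\sigma^2_i + \hat\sigma^2_e)$ and the conditional
$R^2$ adds $\hat\sigma^2_c + \hat\sigma^2_i$ to the numerator — the
standard fixed-versus-total decomposition for Gaussian random-intercept
models. The contribution of the PRS is reported as a difference: the full
model minus the model with *every* PRS-containing term removed (main
effect and all interactions), both fit by REML with otherwise identical
structure. We read "the model without PRS" as removing the score entirely;
an alternative reading (dropping only the interactions) would attribute
the PRS main effect to the reduced model, and is not what the reported
grids use. `r2_grid()` sweeps this difference over phenotypes and P-value
thresholds to reproduce the variance-explained report shape.

## PRS construction

Scores follow the classical clump-and-threshold recipe:

1. **Harmonization** — variants are matched to the GWAS summary statistics
   by identifier; when the genotype's counted allele equals the GWAS other
   allele the dosage is reflected ($2 - d$); strand-complement matches are
   accepted; irreconcilable allele pairs are dropped and logged.
   Palindromic (A/T, C/G) variants are kept by default because the
   simulated data carry no strand ambiguity; `palindromic_policy = "drop"`
   is available for real data.
2. **Greedy clumping** — indices are picked by ascending GWAS P (ties:
   position, then id); a variant is claimed by an index on the same
   chromosome within the window whose dosage $r^2 \ge 0.1$. "Within a
   500 kb window" is read as $|\Delta\mathrm{pos}| \le 500\,000$ bp
   (PLINK's `--clump-kb` semantics); the window and cutoff are
   configurable. LD is the squared Pearson correlation of dosages over
   pairwise-complete individuals — the study cohort itself is the LD
   reference, as no external panel is assumed.
3. **Scoring** — at each threshold $P_t \in \{0.01, 0.05, 0.1, 0.5, 1\}$
   (strict inequality, matching the "< $P_t$" definition of the
   thresholds), the score is $\sum \ln(\mathrm{OR}) \times d$ over
   retained variants with $P < P_t$; missing calls contribute the
   variant's mean oriented dosage (an `omit` mode is exposed).
4. **Standardization** — per threshold, $z = (s - \bar s)/\mathrm{SD}(s)$
   with the sample SD, on the analysed individuals. Whether one should
   standardize before or after subsetting to the analysed set is
   genuinely open; we standardize on the analysed set, which is what the
   association models consume.

## Genotype quality control

Marker QC applies, in order: individual missingness (> 0.1 removes the
individual), marker missingness (> 0.05), minor allele frequency
(< 0.05, computed on non-missing calls), and an exact Hardy–Weinberg test
(P < $10^{-6}$). Individual-level QC (failure rate > 0.03,
heterozygosity beyond 3 cohort SDs) is a separate earlier step, mirroring
per-batch then combined filtering; the order matters because it changes
the denominators of downstream rates, so every report records the order
applied and each removal carries exactly one primary reason. The
Hardy–Weinberg test is the conditional exact test (enumeration of
heterozygote counts given allele counts via the stable ratio recurrence),
not the $\chi^2$ approximation — at tail thresholds like $10^{-6}$ the
exact test is the field standard. The test suite checks it against full
direct enumeration for random tables up to 200 individuals.

## The synthetic-data generator

Genotypes come from a Gaussian-copula haplotype model: each haplotype's
latent vector is multivariate normal with compound-symmetric correlation
`within_block_r` inside LD blocks and zero across blocks; thresholding at
the MAF quantile yields allele indicators, and dosages are haplotype
sums. This gives directly controllable block LD — sufficient for
exercising clumping — at the cost of realism: no recombination-distance
decay, no allele-frequency–LD coupling, no phased output, no X
chromosome. The implied dosage correlation is the phi coefficient of the
thresholded bivariate normal, available in closed-ish form as
`expected_dosage_cor()` and used as the Monte-Carlo oracle in tests.

Reference GWAS summary statistics are simulated as
$\hat\beta = \beta + \mathrm{se} \cdot z_0$ with the balanced
case-control standard error $\sqrt{2/(N f(1-f))}$, so null variants give
exactly uniform P values and causal variants (log-OR $\sim N(0,
\texttt{effect\_sd}^2)$) concentrate at small P.

The cohort layer assigns arms (99/89 by default), centers (uniform over
13), demographics, ancestry PCs, CNV carrier flags, and an ADHD
comorbidity flag whose log-odds rise with the ADHD score
(`comorbidity_prs_shift`, default 0.4 per SD on a base rate of 0.5 —
every trial participant had at least one psychiatric comorbidity, ADHD
being the most common). The score driving the outcome model is the
genotype-derived standardized score, so the PRS engine can recover it;
the other two phenotype scores are correlated Gaussians (0.41 with ASD,
−0.22 with EA — the correlation magnitudes observed between the scores in
the cohort). Dropout is missing-completely-at-random per timepoint
(rates 19/188 and 36/188), which reproduces the reported counts but not
any informative-dropout mechanism; the mixed-model likelihood handles
the resulting unbalanced panels without imputation.

Default effect sizes place the interaction signal where the analysis
looks for it: `prs_time_arm_beta = c(0, 6.7)` puts a +6.7-point penalty
per PRS SD at follow-up in the active arm (the magnitude of the headline
three-way coefficient), on top of standard-care improvements of −4.7 and
−5.3 points per SD (`prs_time_beta`). Baseline 100 and SDs
(center 5, individual 20, residual 10) are plausible clinical SRS values
chosen once; the trial's own arm-wise means and SDs were never published,
so these are design placeholders, not calibrated targets. SRS totals are
rounded and truncated to [0, 195] *after* adding noise — the instrument
range is a hard bound — which slightly compresses extreme tails; the
variance-recovery test uses settings where truncation pressure is
negligible.

Every generator function is deterministic in its seed (bit-identical
reruns), and the `truth` record carries the generating configuration,
causal variants and variance components for parameter-recovery tests.

## Bootstrap power

Power at a target sample size is estimated by cluster bootstrap:
individuals are resampled with replacement, each carrying all their
longitudinal records, with fresh identifiers (so duplicated individuals
are distinct random-effect levels, not repeated measures of one person)
and their original center. The model is refit per resample and power is
the fraction of converged fits with the target-term P below $\alpha$
(default 1000 replicates at $\alpha = 0.05$; calibration tests use fewer
replicates with correspondingly wider binomial bands). Monte-Carlo error
is reported as $\sqrt{p(1-p)/\mathrm{reps}}$, and any size where more
than 20% of fits fail to converge is flagged.

Like any resampling power estimate, the result is conditional on the
observed data: it estimates power *at the dataset's realized effect
size*. Under a data-generating process with a truly null effect the
realized sample interaction is still $\sim$ one standard error away from
zero, which alone lifts the bootstrap rejection rate above $\alpha$
(asymptotically the bootstrap Wald statistic behaves like
$z_{\mathrm{data}} + z_{\mathrm{boot}}$, giving a marginal rate near
0.17). The suite therefore checks $\alpha$-calibration of the machinery
on a dataset whose realized target effect has been projected out, where
the rejection rate must sit in the binomial band around $\alpha$; the
frequentist type-I error of the test itself is checked separately by
simulating fresh trials (not resampling).

## Gene-set association

The gene-set stage regresses SRS *change scores* (endpoint minus
baseline) on common-variant burden. Gene-level association uses a
transparent permutation statistic rather than wrapping an external tool:
change scores are residualized on the cohort covariates (age group, sex,
arm, four PCs, CNV carrier status); each gene's statistic is the mean
squared correlation between its variants' dosages and the residual; P
values come from permutations of the residual vector *shared across
genes* (preserving inter-gene correlation), with the add-one correction
bounding attainable P at $1/(B+1)$; and the gene $z$ is the probit of
$1 - P$. The competitive set test then regresses gene $z$ on set
membership adjusting for variant count and gene length (raw and log),
exactly the covariate logic of the established competitive tools; a
positive membership coefficient means the set's genes carry more
association with the change score, i.e. a reduced intervention response.
This is documented as a defined variant of the MAGMA-style analysis, not
a clone: it is desk-scale, fully specified, and exactly testable
(uniform null P, 5% competitive type-I error, and planted-gene power are
all asserted in the suite). Family-wise correction across the tested
sets defaults to Bonferroni, with Benjamini–Hochberg available — the
correction behind published "corrected P" columns of this kind is often
unstated, so both are exposed.

## Numerical and design choices worth knowing

- **Strict thresholds.** A variant enters a score only when $P <
  P_t$; at $P_t = 1$, variants with $P = 1$ exactly are excluded.
- **Tie-breaking** in clumping is deterministic (P, then position, then
  id), so retained sets are reproducible.
- **Zero-variant thresholds** score 0 with a warning rather than
  erroring, so sparse summary statistics do not break threshold sweeps.
- **Zero-SD score columns** abort standardization with the threshold
  named, except the empty-threshold case above, which standardizes to 0.
- **Missingness injection** combines per-marker and per-individual masks
  independently; with one rate zero the realized margin is exactly
  binomial at the other rate.
- **Resampling seeds** everywhere are plain integers; all simulation
  entry points take and record them.

## Problem sizes in the test suite

The suite simulates at the trial's own scale (n = 188) for calibration
checks — 500 null datasets for the Wald type-I error, 500 bootstrap
replicates for power calibration, 500 random sets for competitive
type-I — and at n = 4000–5000 (100 seeds) for parameter recovery of the
+6.7 follow-up interaction. Oracle-equivalence properties run on small
randomized instances (≤ 50 variants × 20 individuals for clumping and
scoring, tables ≤ 200 for the exact Hardy–Weinberg test). The whole
suite, including these simulations, completes in a few minutes on one
CPU.

## Limitations

The generator's LD, dropout and covariate structures are deliberately
simple; passing calibration here demonstrates the pipeline's internal
correctness, not robustness to real-world artefacts (informative
dropout, batch effects, cryptic relatedness, imputation error — all out
of scope, as are ancestry PCA, imputation and CNV calling, whose outputs
enter as given covariates). Published headline coefficients from the
clinical cohort depend on private data and are not reproduction targets;
what the package reproduces is the full method, its analytic identities,
and its statistical calibration under known truth.
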