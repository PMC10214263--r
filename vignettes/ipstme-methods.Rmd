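---
title: "ipstme: methods, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ipstme: methods, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The analysis chain

The package derives an immunophenotypic score (IPS) for gastric-cancer
tissue in seven stages. Each stage is an exported function; the
pipeline (`run_pipeline()`) chains them with CSV intermediates so any
stage can be audited or resumed from disk.

## Immune-fraction estimation

`estimate_fractions()` solves, per sample, a non-negative least-squares
regression of linear-scale expression on a cell-type signature matrix
restricted to the signature genes, then normalizes the coefficients to
proportions. This is a deliberate linear stand-in for support-vector
deconvolution: the downstream clustering needs valid fraction
estimates, not a particular estimator, and NNLS has a transparent
optimum with no tuning parameters. The bundled `default_signature()`
is block-structured (10 genes per type, 100 vs 5 expression units);
real signatures are denser and noisier, which is one reason the
recovery figures on synthetic data are an upper bound on real-data
behavior.

*Assumptions*: expression is linear in cell proportions over the
signature genes; signature genes are not themselves
phenotype-regulated beyond composition.

## Consensus clustering and IMcluster labels

`consensus_cluster()` subsamples the cohort (default 80% of samples,
1000 draws in the reference configuration; tests and examples use
100–200 draws, which the stability analysis below justifies), clusters
each draw with Ward (D2) hierarchical clustering on Euclidean distance
— k-means is available as an alternative backend — and records, for
every sample pair, the co-clustering fraction among co-sampled draws.
One hierarchical tree per draw serves every k via `cutree`, which is
what makes a 500-sample, five-k, 1000-draw run affordable. Fractions
are z-scored per cell type first, so that cell types with small
absolute fractions (e.g. activated memory CD4) are not drowned by
abundant ones; this is a modeling choice, not an established
convention.

`select_k()` implements a Δ-area elbow: with $A(k)$ the area under the
consensus-CDF and $\Delta(k)$ the relative gain
($\Delta(2) = A(2)$, $\Delta(k) = (A(k)-A(k-1))/A(k-1)$), the chosen k
is the one *after which the relative gain drops the most*,
$\arg\max_k [\Delta(k) - \Delta(k+1)]$. The naive
$\arg\max_k \Delta(k)$ was rejected during design: $\Delta(2) = A(2)$
dominates whenever a two-way split is merely stable, which it almost
always is. A known limitation, documented rather than patched: for
single-cluster data the Δ-curve frequently still shows a spurious
elbow, because Ward's two-way split of one Gaussian cloud is itself
stable under resampling. The flat-curve warning therefore fires only
on numerically flat area curves, and an `override` argument pins k
(the pipeline default pins k = 3, mirroring the reference analysis).

`assign_imcluster()` labels the cluster with the highest mean
activation composite (CD8 T + activated memory CD4 + M1 fractions) as
the immune-activated cluster A, the rest B, C by descending composite,
with a deterministic index tie-break.

## Cross-cohort gene weighting

Per cohort, `differential_expression()` (limma moderated t, BH
adjustment; logFC = A-vs-rest mean difference in log2 units),
`gene_auc()` (rank AUC for predicting cluster A) and `gene_cox_hr()`
(univariate Cox hazard ratio per SD of cohort-standardized expression)
populate a gene-evidence table, and `eq1_weight()` combines them:

$$W(g) = \sum_i \mathrm{logFC}_i \cdot \frac{2}{1+p^{adj}_i} \cdot
\left|\mathrm{AUC}_i - 0.5\right| \cdot \log_2 \mathrm{HR}_i \cdot
\frac{n_i}{N}.$$

Each factor annihilates or attenuates exactly when its evidence is
null: an adjusted p of 1 halves the contribution, AUC = 0.5 or HR = 1
zero it, and $n_i/N$ weights cohorts by size. Genes are ranked by
$|W|$ by default so that protective and hazardous markers both
surface; a `signed` option exists because the convention is genuinely
open. Two properties pin the algebra in tests: linearity in logFC and
invariance to jointly rescaling all $n_i$.

Deconvolution-signature genes are excluded from ranking
(`exclude_genes`): they are cluster-separated *by construction of the
fraction estimates*, and letting the reference signature re-surface as
"discovered" markers would be circular.

DEG thresholds default to |logFC| > 0.5 and adjusted p < 0.05; both
are configurable since the reference analysis reports only a DEG count,
not its thresholds.

## Concordance filter

`concordance_filter()` computes per-gene Spearman correlation between
mRNA and H-score over paired samples and keeps the top m (default 8)
by ascending p, breaking ties by |rho| then gene id. The Spearman test
uses the t approximation; at |rho| = 1 the p-value is defined as 0.

## Dual selection and the IPS model

`lasso_cox_select()` (glmnet, penalty by 10-fold cross-validated
partial-likelihood deviance with seed-fixed folds) and
`rsf_importance()` (ranger: 500 survival trees, log-rank splitting,
mtry = floor(sqrt(p)), minimum node size 15, out-of-bag permutation
importance) are intersected by `select_features()`. The importance
threshold defaults to 0.01: permutation-importance scales are
implementation-specific, so the default was calibrated once on
synthetic null features (null importances stay within roughly ±0.007
at n ≈ 250) rather than imported from other software. Permutation
importance is known to split credit among correlated features; with
strongly correlated marker panels the intersection can be narrow or
empty, in which case the pipeline falls back to the lasso-selected set
and logs it.

`fit_ips()` fits multivariate Cox (Efron ties) with AIC-based stepwise
selection in both directions and defines the IPS as the *raw* linear
predictor $\sum_j \hat\beta_j x_j$ — no training-set centering — so a
serialized model scores new patients reproducibly. Features are raw
H-scores by default (per-stain-unit coefficients remain interpretable);
a standardization flag exists.

`dichotomize()` chooses the cutoff maximizing Youden's J of the score
against vital status at a horizon (default: median follow-up; the
label excludes patients censored before the horizon). Patients with
score ≤ cutoff are IPS-Low; the inequality's side is a convention the
source material does not state, chosen so that IPS-Low is the
better-prognosis class when high score is hazardous. Cutoff candidates
are midpoints between consecutive distinct scores, ties broken toward
the lower cutoff.

`biopsy_applicability()` excludes biopsy/resection pairs whose
assessable tumor area is below 0.16 mm² (strictly-below exclusion,
matching the reference rule) and reports Spearman rho, the AUC of the
biopsy score for the resection class, and the retained n; a sweep mode
scans a threshold grid and reports the AUC-maximizing threshold.

## Pathology quantification

The formulas are implemented exactly as stated in their definitions:
H-score = 1·weak% + 2·medium% + 3·strong% (range 0–300, percentages
must sum to ≤ 100); field density pools counts over areas
($\sum C_x / \sum A_x$ — a regression test pins the pooled definition
against the mean-of-ratios alternative); CPS = 100·positive/viable,
*capped at 100* per the standard clinical convention (the cap is a
design decision; the defining formula is uncapped); CT/IM ratios are
excluded (NA) when either density is below 5 cells/mm². The
inflamed/excluded/desert call uses two thresholds with a complete,
deterministic partition: core density ≥ t_high is inflamed, otherwise
margin density ≥ t_high is excluded, otherwise desert. The defaults
(t_high = 50, t_low = 10 cells/mm²) are package configuration values,
not published cutoffs, and should be set per staining protocol.

## Response evaluation

`association_report()` builds the five endpoint 2×2 tables (Response,
TRG, ypT, ypN, ypTNM) against IPS class, excluding patients missing an
endpoint from that endpoint only, and computes both the uncorrected χ²
and the point-probability two-sided Fisher test for each. The headline
p uses χ² when every expected count is ≥ 10, Fisher otherwise. The
threshold of 10 (not the textbook 5) is deliberate: it is the unique
min-expected-count rule consistent with the footnote pattern of the
published comparison table, whose Fisher-tested endpoints have minimum
expected counts between 7.3 and 8.2 and whose χ²-tested endpoints sit
above 11. Both p-values are always reported, so the choice rule only
selects the headline.

Two statistical conventions matter here and are fixed by verification
against the published values: Fisher's two-sided p is the sum of
hypergeometric probabilities of tables (same margins) with point
probability ≤ observed, and the χ² statistic carries no continuity
correction.

# The statistics core

All clinical test statistics are implemented self-contained
(hypergeometric/χ²/rank distributions from base R, Kaplan–Meier,
log-rank with multivariate hypergeometric variance, Newton–Raphson
Cox with Efron ties to gradient norm < 1e-8), and the test suite
cross-checks each against an independent route: full enumeration for
Fisher, `chisq.test`/`wilcox.test`/`kruskal.test`/`p.adjust`,
`survival::coxph`/`survdiff`, and brute-force partial-likelihood
maximization on small datasets. Conventions worth knowing:

- exact rank-test p-values are used up to 12 observations per group
  without ties, normal approximation with tie correction beyond;
- a paired test on all-zero differences returns p = 1 with a warning;
- Cox quasi-separation is flagged (non-converged, warning) when the
  coefficient path escapes |β| > 10, where the partial-likelihood
  gradient saturates numerically;
- the time-dependent AUC is the cumulative-case / dynamic-control
  estimator with Kaplan–Meier inverse-censoring weights (the estimator
  family is not specified by the reference analysis; this is the
  common default);
- logistic regression wraps the standard IRLS fit with explicit
  separation detection.

# The synthetic-data generator

`sim_config()` freezes the reference study conditions: 5 cohorts
totalling 500 patients (120/100/90/110/80), 2000 background genes, 30
planted marker genes with logFC 1.5 (cluster A vs rest), cluster
proportions (0.35, 0.35, 0.30), per-sample fractions drawn from a
Dirichlet around three cluster profiles with precision 100 (within-
cluster fraction SD ≈ 0.04, below half the between-profile gaps —
clearly separated phenotypes, which the planted-recovery tests
presuppose), exponential survival with baseline hazard 0.02/month and
censoring 0.01/month, and a Gaussian-copula mRNA–H-score link with
target Spearman rho 0.8 for the first 8 markers.

The survival law is deliberately coherent with the biology the
pipeline assumes: immune-activation markers are *protective*, so the
latent risk covariate is the negated standardized mean of the first 5
markers ("prognostic markers") with hazard ratio 2 per SD, and the
immune-activated cluster inherits its better prognosis *through* the
marker score rather than from a separate cluster effect
(`cluster_hazard` defaults to zero). This keeps the planted
coefficient identifiable from its single covariate — the
self-consistency test recovers log(HR) within 2 SE — and mirrors the
observed strong overlap between the activated phenotype and the
low-risk score class.

The neoadjuvant model draws responder status from a logistic model in
IPS class and CPS class (intercept −1.79, IPS-Low +1.8, CPS ≥ 5 +1.7 on
the logit scale — chosen to reproduce response rates of roughly 85% in
the best and 14% in the worst IPS×CPS stratum), maps it to RECIST and
Becker TRG with 15% label noise between the radiological and
pathological readouts, and gives responders a 1.2-log lower recurrence
hazard.

What the generator does **not** emulate: read-level counts and
library-size effects, gene–gene correlation beyond the planted
cluster/marker structure, informative censoring, missing-not-at-random
pathology data, inter-pathologist scoring variability, and real
signature collinearity. Passing recovery tests therefore demonstrate
implementation correctness under the planted model, not expected
field performance.

Reproducibility: one master seed expands into fixed per-stage
substreams (`stage_seed`), so cohort generation, IHC, neoadjuvant
outcomes, and clustering each see a stable stream regardless of call
order; the pipeline manifest records the config hash and output
checksums, and two runs with one configuration are byte-identical.

# Problem sizes in the test suite

Monte-Carlo test blocks use sizes chosen to give stable operating
characteristics at interactive runtimes: 200 consensus draws for the
single-seed recovery checks and 100 draws for the 20-seed k-selection
sweep; 100 replicates for coverage-style checks (bounds set three
binomial SDs below the analytic coverage); 1000 replicates where the
per-replicate cost is trivial (rank-test type-I error, neoadjuvant ORR
ordering); and a 40-gene configuration for the 100-seed end-to-end IPS
survival check, since background genes do not enter that question.

# Known limitations

- NNLS deconvolution ignores the variance structure real
  deconvolution methods model; absolute (non-proportional) scores are
  out of scope.
- The Δ-area rule inherits consensus clustering's weak behavior on
  unclustered data (spurious stable 2-splits); k should be inspected,
  and the pipeline pins k = 3 by default.
- Permutation importance under-credits correlated features; the dual
  selection is conservative by construction and the calibrated 0.01
  threshold keeps all five planted markers jointly only in about
  three-quarters of replicates at the reference effect size.
- Batch effects are handled only by per-cohort standardization
  (`zscore_by_cohort`); no empirical-Bayes harmonization is provided.
- The stepwise-AIC stage inherits the usual instability of stepwise
  selection at small event counts; the fitted model serializes its
  markers and coefficients precisely so that scoring is decoupled from
  refitting.
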