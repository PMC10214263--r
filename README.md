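# ipstme

Immunophenotypic scoring of the gastric-cancer tumor microenvironment:
from bulk expression to a pathology-applicable risk score that
stratifies prognosis and neoadjuvant anti–PD-1 response.

## The problem

Only a minority of gastric-cancer patients benefit from immune
checkpoint inhibition, and the standard companion biomarkers (PD-L1
combined positive score, MSI/EBV status, the inflamed phenotype) leave
many responders and non-responders misclassified. A line of work in TME
immunophenotyping addresses this by (i) clustering tumors on their
immune-cell composition, (ii) finding genes that track the
immune-activated cluster across independent cohorts, and (iii)
compressing a small panel of those genes — measured by ordinary
immunohistochemistry — into an **immunophenotypic score (IPS)** usable
on biopsy and resection tissue alike.

`ipstme` is a tested, self-contained implementation of that analysis
chain for R users (computational pathologists, translational
biostatisticians):

1. **Deconvolution** — non-negative least squares of bulk expression on
   a cell-type signature gives per-sample fractions of five immune cell
   types (CD8 T, activated/resting memory CD4 T, M1, M2).
2. **Consensus clustering** — resampled Ward clustering of the
   fractions; the Δ-area elbow over consensus-CDF areas picks k; the
   cluster with the highest activation composite (CD8 + activated CD4 +
   M1) is labeled **IMcluster A**.
3. **Cross-cohort gene ranking** — per cohort *i*, each A-vs-B/C
   differentially expressed gene gets the evidence weight

   $$w_i(g) = \mathrm{logFC}_i \cdot \frac{2}{1 + p^{adj}_i} \cdot \left|\mathrm{AUC}_i - \tfrac12\right| \cdot \log_2 \mathrm{HR}_i \cdot \frac{n_i}{N},\qquad W(g) = \sum_i w_i(g),$$

   combining effect size, significance, discrimination of cluster A,
   prognostic hazard, and cohort size; genes are ranked by |W|.
4. **Concordance filter** — Spearman correlation of mRNA with the IHC
   H-score keeps the genes whose protein stain tracks transcription.
5. **Dual selection and the IPS** — features surviving both L1-penalized
   Cox *and* survival-forest permutation importance enter a stepwise
   multivariate Cox model; the linear predictor
   $\mathrm{IPS} = \sum_j \hat\beta_j \cdot \mathrm{Hscore}_j$ is
   dichotomized at the Youden-optimal cutoff into IPS-Low / IPS-High.
6. **Pathology quantification** — H-score
   ($1\cdot\%_{weak} + 2\cdot\%_{med} + 3\cdot\%_{strong}$), pooled field
   density ($\sum C_x / \sum A_x$), PD-L1 CPS
   ($100 \cdot \text{positive}/\text{viable tumor cells}$, capped at
   100), CT/IM ratios, and the inflamed/excluded/desert phenotype call.
7. **Response evaluation** — ORR and Becker-TRG tabulation, a
   Table-1-style association report (uncorrected χ² or point-probability
   Fisher, chosen by expected counts), IPS×CPS Type A–D stratification,
   biomarker AUC/logistic comparison, and RFS log-rank analysis.

Patient-level data from the original seven-center study are not public,
so the package ships a **synthetic-data generator** that plants the full
ground-truth structure (3 immune clusters driving 5 fractions, marker
genes with known logFC and hazard ratio, copula-linked H-scores,
logistic response model) — every stage is validated by recovering what
was planted. The clinical test statistics are implemented from first
principles and checked against enumeration and brute-force likelihood
oracles.

## Worked example

Association of IPS class with tumor regression grade from published
counts, then immune-phenotype recovery on synthetic data:

```r
library(ipstme)

trg <- matrix(c(12, 4, 12, 22), nrow = 2,
              dimnames = list(c("IPS-Low", "IPS-High"), c("TRG 1a/1b", "TRG 2/3")))
fisher_exact_2x2(trg)
#> Fisher's exact test (two-sided)
#>   statistic = 12  p = 0.014521
#>   effect = 5.5

cfg <- sim_config(seed = 1)                      # 5 cohorts, 500 patients
sim <- generate_cohorts(cfg)
fr  <- do.call(rbind, lapply(sim$cohorts, function(co) co$fractions))
cc  <- consensus_cluster(fr, reps = 200, seed = 1)
select_k(cc)
#> [1] 3
lab <- assign_imcluster(cc$labels[, "k3"], fr)
table(planted = sim$truth$cluster[rownames(fr)], assigned = lab)
#>        assigned
#> planted   A   B   C
#>       A 172   0   0
#>       B   0 171   5
#>       C   0   0 152
```

The Fisher p of 0.015 (odds ratio 5.5) says IPS-Low patients had
substantially more major tumor regression; the confusion table shows the
consensus step recovering the planted immune phenotypes nearly
perfectly (adjusted Rand index 0.97). `run_pipeline(pipeline_config(...))`
chains every stage end to end with CSV intermediates and a checksummed
manifest.

## Vignette

`vignettes/ipstme-methods.Rmd` documents the model assumptions, every
tunable parameter with its default and rationale, what the generator
does and does not emulate, numerical conventions, and known limitations.
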