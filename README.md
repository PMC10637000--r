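# teactivity

Estimating the *cis*-regulatory activity of transposable-element (TE)
subfamilies from RNA-seq count tables alone.

## The problem

Many TE integrants carry transcription-factor binding sites and act as
*cis*-regulatory elements (CREs) for nearby protein-coding genes. Because
integrants of one subfamily are highly similar in sequence, a whole
subfamily can behave as a coordinated set of CREs. Detecting this usually
requires matched epigenomic assays (ChIP-seq, ATAC-seq). `teactivity`
implements a statistical alternative: it infers, from expression of
protein-coding genes only, which TE subfamilies gained or lost regulatory
activity between two conditions, and by how much.

## The model

Let `E'_ps` be the doubly centered log2 TPM expression of gene *p* in sample
*s*, and `N_pm` the **regulatory susceptibility** of gene *p* to subfamily
*m* — either the number of merged integrants of *m* inside the gene's
*cis*-regulatory windows (promoter TSS clusters padded by 500 bp, extended
by a 50 kb flank, excluding integrants overlapping the gene's promoters or
exons), or a sum of Gaussian kernel weights
`w = exp(-d² / (2L²))` of the integrant-to-closest-promoter center distance
*d* with bandwidth *L* (optionally zeroed across TAD boundaries).

For each treatment/control sample pair, the per-gene expression differences
are stacked and modeled as

    ΔE'_p = ΔA_0 + Σ_m N_pm · ΔA_m + ε,   ε ~ N(0, σ²) i.i.d.

and fitted by ordinary least squares. `ΔA_m` is the log2 change in a gene's
expression attributable to one integrant of subfamily *m* within regulatory
range — an interpretable per-integrant effect. Each `ΔA_m` is t-tested
against zero and Benjamini–Hochberg adjusted across subfamilies; the overall
F-test and adjusted R² summarize the fit. A 5-fold cross-validation over a
grid of bandwidths (1 kb – 10 Gb, with fixed gene and subfamily sets)
selects the bandwidth minimizing the mean validation RMSE. Subfamilies can
further be split into "functional" and "non-functional" fractions by overlap
with user-supplied intervals (e.g., differential TF-binding peaks), each
fraction fitted as its own column. A hypergeometric enrichment of
differentially expressed genes near integrants is included as the classical
baseline, with a Mann–Whitney AUC utility for method comparison.

## Worked example

The package ships a synthetic-data generator with known ground truth, so
the full pipeline runs without any download. Three subfamilies are truly
active (ΔA = −0.15, +0.1, +0.2):

```r
library(teactivity)

params <- sim_params(seed = 42)     # 500 genes, 20 subfamilies, 2 pairs
ann    <- simulate_annotation(params)
sim    <- simulate_counts(ann, params)

delta <- prepare_delta(sim$counts, sim$gene_lengths, sim$pairs)
N     <- filter_subfamilies(sim$truth$N, min_total = 150)
fit   <- fit_activities(delta, N)

fit
#> <te_activity_fit> 20 subfamilies, 934 observations (residual df 913)
#>   F-test p = 9.24e-18, adj. R^2 = 0.111, 4 subfamilies with adj. p <= 0.05

library(dplyr)
tidy(fit) |> arrange(adj_p_value) |> head(3)
#>   subfamily estimate std_error t_value  p_value adj_p_value
#> 1 subfam_01   -0.217    0.0311   -6.96 6.67e-12    1.33e-10
#> 2 subfam_03    0.180    0.0301    5.98 3.11e- 9    3.11e- 8
#> 3 subfam_02    0.122    0.0305    4.01 6.58e- 5    4.39e- 4
```

The three planted subfamilies are recovered with the right signs and
magnitudes (estimates carry sampling noise at σ = 0.5 per sample). An
estimate of −0.15 with SE 0.02 translates to a per-integrant fold-change
interval via

```r
fold_change_interval(-0.15, 0.02)
#>     low  high
#> 1 0.877 0.926
```

i.e., each nearby integrant accounts for a ~10% expression decrease.
`autoplot(fit)` draws the estimates with confidence bars;
`cross_validate_bandwidth()` + `autoplot()` show the validation-RMSE curve
over bandwidths; `split_functional()` expands the matrix into
functional/non-functional fraction columns; `hypergeom_enrichment()` and
`classification_auc()` reproduce the DE-enrichment baseline.

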