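---
title: "Modeling TE-subfamily cis-regulatory activity from expression deltas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TE-subfamily cis-regulatory activity from expression deltas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`teactivity` treats the integrants of a transposable-element (TE) subfamily
as interchangeable regulatory units: every integrant of subfamily $m$
within *cis*-regulatory range of a gene promoter is assumed to contribute
the same additive amount $A_m$ (log2 units) to that gene's expression. Log2
TPM expression of gene $p$ in sample $s$ is decomposed as

$$E_{ps} = c_p + d_s + \sum_m N_{pm} A_{ms} + \varepsilon,$$

with $c_p$ a gene-specific basal level, $d_s$ a sample-specific offset
(library scaling, batch), $N_{pm}$ the regulatory susceptibility of gene
$p$ to subfamily $m$, and i.i.d. Gaussian noise. Column-centering removes
$d_s$, row-centering removes $c_p$; differencing a treatment sample against
a control sample then yields, per gene,

$$\Delta E'_p = \Delta A_0 + \sum_m N_{pm}\, \Delta A_m + \varepsilon,$$

which is fitted by ordinary least squares with an intercept. Replicate
pairs are stacked row-wise, with the susceptibility matrix expanded to
match. The key assumptions are (i) additivity and within-subfamily
exchangeability of integrant effects, (ii) homoskedastic Gaussian noise on
the log scale, and (iii) a susceptibility geometry that reflects where
regulation can physically act. Each $\widehat{\Delta A}_m$ is t-tested
against zero; p-values are Benjamini–Hochberg adjusted across the $M$
subfamily coefficients only (the intercept is never adjusted or reported
as a subfamily), with adjusted $p \le 0.05$ flagging a subfamily as
differentially *cis*-regulatory.

Inference is classical OLS inference: standard errors from
$\hat\sigma^2 (X^\top X)^{-1}$ with $\hat\sigma^2 = \mathrm{RSS}/(n-M-1)$,
an overall F-test, and adjusted $R^2$ as the explained-variance measure.
Genuine expression data violate (ii) in the tails, so the reported
p-values should be read as well-calibrated under the model rather than
exactly calibrated for any dataset.

## Susceptibility geometries

**Hard windows.** Promoter regions are single-linkage clusters of
transcription start sites spaced by strictly less than 1 kb, padded by
500 bp on each side; *cis*-regulatory windows extend promoters by a 50 kb
flank on both sides (clipped at the chromosome origin). $N_{pm}$ counts
merged integrants of $m$ overlapping any window of $p$ by at least 1 bp.
Window membership and exclusion ignore strand; strand enters only the
fragment-merging rule (fragments of one subfamily and strand with a gap
strictly under 100 bp are chained).

**Gaussian weighting.** $N_{pm}$ sums
$w = \exp(-d^2/2L^2)$ over all same-chromosome integrants, with $d$ the
distance between the integrant center and the closest promoter center
(centers are `floor((start+end)/2)` in 0-based half-open coordinates). The
bandwidth $L$ (bp) is the kernel's standard deviation: at $d = L$ the
weight is 0.61, at $d = 2L$ it is $e^{-2} \approx 0.135$, and about 95% of
the kernel mass lies within $\pm 2L$ — so a selected $L$ is read as
"regulatory information up to roughly $2L$". With TAD intervals supplied,
a weight is zeroed when the integrant center and the closest promoter
center fall in different TADs or either falls in none; TAD membership is
decided by the center coordinate under half-open semantics, matching the
distance convention, since no finer rule is implied by the geometry.

In both modes, integrants overlapping a gene's promoters or exon union are
excluded **for that gene only** — exonic TEs would otherwise correlate
with the gene's read counts mechanically, and promoter-overlapping TEs
belong to the separately studied alternative-promoter phenomenon. The
per-gene reading means a TE inside gene A's exon may still count for a
neighboring gene B; nothing in the geometry suggests B should be
penalized for A's annotation.

Subfamily columns whose total susceptibility is below 150 are dropped
before fitting: with too few putatively regulated genes the coefficient is
unstable and its test uninformative. In weighted mode the same threshold
applies to the weighted sums.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| promoter cluster gap | 1000 | bp | strict single-linkage TSS clustering |
| promoter pad | 500 | bp | promoter half-width around TSS clusters |
| window flank | 50000 | bp | hard-mode regulatory range |
| bandwidth $L$ | CV-selected | bp | kernel standard deviation |
| merge gap | 100 | bp | strict fragment-merging threshold |
| `min_count` | 10 | reads | gene retained if reached in ≥ 1 sample |
| `min_total` | 150 | susceptibility | subfamily column filter |
| `min_fraction_total` | 100 | susceptibility | split-collapse threshold |
| significance | 0.05 | adj. p | subfamily call threshold |

Two choices were genuinely open and are resolved as follows:

* **Promoter padding vs clustering order.** TSS are clustered first, then
  padded; padded clusters that overlap *or abut* are stored as their
  disjoint union (two TSS exactly 1 kb apart yield one stored interval).
  Downstream exclusion and distance logic only consume the union, so no
  information is lost.
* **Normal vs t quantile for fold-change intervals.**
  `fold_change_interval()` defaults to the normal quantile (1.96 at 95%),
  which is what the per-integrant fold-change interpretation uses at the
  residual degrees of freedom typical here (hundreds); a t option with
  explicit `df` is exposed for small designs.

## Expression preparation

Raw counts are normalized per column: a pseudocount equal to the 5th
percentile (linear interpolation between order statistics — the common
quantile default, recorded here because conventions differ) of the
column's non-zero counts is added, counts are length-normalized to TPM
(gene length = exon-union length, matching union-based read counting) and
log2-transformed. The matrix is column- then row-centered; the model
intercept absorbs residual offsets introduced by differencing.

`prepare_delta()` composes the steps in the order: pseudocount
normalization on the **full** count table, then removal of genes below the
count filter (and of experimentally perturbed genes such as an
overexpressed transgene), then centering and pair differencing. Computing
the pseudocount before row filtering matters: the non-expressed fraction
of a count table is what keeps the 5th percentile of non-zero counts at a
few reads. On a table already restricted to well-expressed genes the
percentile rises into the expressed range and shrinks every log-ratio —
an avoidable attenuation of all activity estimates.

## Bandwidth selection

`cross_validate_bandwidth()` partitions **genes** (not stacked rows) into
5 folds — a deterministic function of the gene set and a seed — fits the
activity model on training genes for each candidate susceptibility matrix,
and averages the held-out RMSE. All candidates must share identical gene
rows and subfamily columns; the intended reference is the hard-threshold
50 kb matrix after the 150 filter, to which each weighted candidate is
subset. The default grid spans 1 kb to 10 Gb in 11 points with the
50–500 kb region densely covered; the exact grid is a package choice,
user-overridable. Predictions for held-out genes include the training-fit
intercept. Candidates that are rank-deficient in a fold — expected at
extreme bandwidths, where columns become near-constant per chromosome and
collinear — record an infinite RMSE for the affected folds and are logged
rather than silently regularized. Ties (including the degenerate
constant-response case, where all candidates reduce to the intercept) are
broken toward the smaller bandwidth, using a relative tolerance of 1e-9 so
floating-point noise cannot override the tie rule.

## Functional/non-functional splitting

Given a set of functional intervals (e.g., differential TF-binding or
accessibility peaks), integrants overlapping any interval by ≥ 1 bp form
the functional fraction of their subfamily and the rest the non-functional
fraction; each fraction becomes its own design column, so the two columns
sum exactly to the unsplit column (within 1e-9 in weighted mode, where
only summation order differs). Fractions are only formed for subfamilies
present in the filtered unsplit matrix; a subfamily with either fraction
summing below 100 collapses back to its unsplit column unless explicitly
protected. Rank deficiency is the failure mode this collapse protects
against: a fraction regulating almost no genes contributes a near-zero
column.

## The DE-enrichment baseline

The classical two-step alternative first calls differentially expressed
genes, then tests per subfamily whether DE genes concentrate among genes
within regulatory distance of its integrants ("near" = susceptibility ≥ 1
in the hard matrix, so both methods share one geometry). The
hypergeometric upper tail $P(X \ge k)$ is computed exactly via the
survival function at $k-1$; up- and down-regulated genes are tested
separately and the concatenated table is BH-adjusted once. The gene
universe is the expression-filtered set (the rows of the matrix), not all
annotated genes: genes that could never have been called DE should not
dilute the draw. DE calling itself is out of scope — the baseline consumes
labels from any external caller; in the test suite labels come from a
lenient per-gene z-test on the observed deltas at the generative noise
level, reproducing the two-step procedure's per-gene bottleneck. The
Mann–Whitney AUC (ties counted half) compares methods against a known set
of truly regulatory subfamilies, scoring each subfamily by 1 − adjusted p.

## The synthetic study

The generator emulates the structure the method consumes, not genome
realism. Defaults, fixed once: one 50-Mb chromosome; 500 genes with 1–3
TSS (mixing sub- and super-1 kb spacings) and 3–8 exons; 20 subfamilies of
200 integrants placed uniformly — enough that per-subfamily susceptibility
sums clear the method's own 150 filter, as subfamilies retained in
genome-scale analyses do; 10% of integrants emitted as two fragments with
a sub-100 bp gap to exercise merging; three active subfamilies at
$\Delta A \in \{-0.15, +0.1, +0.2\}$, spanning the per-integrant effect
sizes the method is meant to resolve; noise σ = 0.5 log2 units per sample;
two treatment/control pairs; susceptibilities generated with $L$ = 100 kb.
Counts are produced by inverting the TPM transform at a median depth of
500 reads with per-sample library sizes varying up to 2× (exercising the
$d_s$ centering), plus a 10% "silent" gene block at trace expression
(log2 TPM ≈ 1.5). The silent block plays the role of the non-expressed
fraction of real tables: it pins the per-column pseudocount at a few reads
and falls below the count filter, so retained genes are recovered to
within rounding. Noise is Gaussian on the log scale by design — the
fixtures match the model's own assumption, so calibration tests check the
inference machinery, not robustness; real counts are overdispersed
negative-binomial-like, and the suite does not certify behaviour under
that misspecification.

Test problem sizes are chosen to make the statistical checks sharp but
cheap: 200 count draws over one fixed annotation for recovery/coverage/
calibration, 50 draws for bandwidth selection (σ = 0.3, as a harder
selection problem than the standard noise would pose), 100 for the
sensitivity comparison, and brute-force oracle fixtures of ≤ 20 genes,
≤ 150 integrants, ≤ 10 design columns, where literal per-pair loops and
normal-equations solutions are feasible.

## Known limitations

* One coefficient per subfamily: antagonistic integrants within a
  subfamily average out; the functional split mitigates this only when
  external evidence identifies the active fraction.
* The linear additive model is a deliberate simplification; explained
  variance is expectedly modest, and effect sizes are per-integrant
  averages, not locus-level effects.
* Cross-subfamily sequence relatedness is not modeled; closely related
  subfamilies compete for the same signal and can split it.
* Rank deficiency is an error by design (inference requires full rank);
  no minimum-norm or ridge fallback is offered.
* The normalization's pseudocount makes low-count genes' log-ratios
  mildly attenuated; with a realistic non-expressed fraction in the table
  this is a second-order effect, but tables pre-filtered to expressed
  genes only will bias estimates toward zero (see above).
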