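---
title: "Methods: cross-tissue expression aggregation and hyaluronan sizing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue expression aggregation and hyaluronan sizing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamet)
```

## The scientific problem

Hyaluronan (HA) is an unbranched glycosaminoglycan whose biology depends
strongly on chain length: high-molecular-weight (HMW, here > 500 kDa) HA is
immunosuppressive and anti-inflammatory, while low-molecular-weight (LMW,
< 150 kDa) fragments are pro-inflammatory. Comparative studies of HA
metabolism — for example between the naked mole-rat, guinea pig and mouse —
therefore need two kinds of computation:

1. **Transcriptomic**: given per-tissue differential-expression results
   (a p-value and a log fold-change per gene per tissue), decide which genes
   are *consistently* differentially expressed across many tissues, and
   whether a whole panel of HA-related genes is shifted.
2. **Biophysical**: given size-exclusion chromatography (SEC) elution
   profiles and gel migration data, assign molecular weights by calibration
   against standards and quantify the mass balance between HMW and LMW
   chains; and given ELISA-like assay readouts, convert to tissue contents
   (µg per g dry weight) and compare groups.

`hamet` implements both, plus seeded generators that produce data of the
same shape with known ground truth, so every stage is testable end to end.

## The cross-tissue statistic

For one gene with per-tissue p-values $p_t$ and log fold-changes
$\mathrm{logFC}_t$ over $l$ tissues,

$$F \;=\; \Bigl|\, \sum_{t=1}^{l} \ln(p_t)\,\mathrm{sgn}(\mathrm{logFC}_t) \Bigr|.$$

This is Fisher's method with each log-p term signed by the fold-change
direction. Evidence pointing in opposite directions cancels; only a gene
that is small-p *and* consistently up- (or down-) regulated accumulates a
large $F$. The absolute value makes the statistic symmetric in direction, so
a globally down-regulated gene scores identically to its mirror image.
`sgn(0) = 0`: a tissue with zero fold change contributes nothing.

Because the signed sum has no convenient closed-form null (the number of
effective terms depends on the sign pattern, and real p-values are not
exactly uniform), the null is estimated empirically by resampling. Each
round draws $l$ (p, logFC) pairs with replacement from the pooled
non-missing cells of the whole matrix and recomputes $F$. This preserves the
observed marginal distributions of p and of the sign while destroying the
within-gene cross-tissue consistency that the statistic rewards. The default
is 100,000 rounds; the package also exposes a per-tissue scheme (each
resampled column drawn from its own tissue) which preserves per-tissue
marginals, and both calibrate correctly on simulated nulls.

The empirical p-value uses the add-one estimator
$\rho = (1 + \#\{F_{\mathrm{null}} \ge F\})/(1 + n_{\mathrm{rounds}})$,
standard permutation-test practice: $\rho$ can never be 0, so $\ln\rho$
stays finite for the gene-set step, and $\rho$ remains a valid (slightly
conservative) p-value. Genes are called significant at $\alpha = 0.01$ by
default.

A gene set of $k$ genes is aggregated with the unweighted Fisher statistic
$\mathcal{F} = \sum_g \ln(\rho_g) \le 0$, and $-2\mathcal{F}$ is referred to
$\chi^2_{2k}$. Treating the empirical $\rho$ as uniform under the null is an
approximation (each $\rho$ is discrete with resolution
$1/(n_{\mathrm{rounds}}+1)$, and all genes share one resampled null); with
$10^5$ rounds the discreteness is negligible at the $\alpha$ used, and the
single-gene identity ($k = 1$ returns $\rho$ itself) holds to machine
precision.

Design points that were genuinely open, and how they were resolved:

* **Resampling unit.** Cells are resampled with their (p, logFC) pairing
  intact, from the pooled background. The alternative of permuting tissue
  columns independently is exposed as `scheme = "per_tissue"`; both satisfy
  the calibration requirement, and pooled resampling is the default because
  it is the simplest scheme that uses the full background.
* **Missing tissues.** A gene not measured in some tissues is scored on its
  observed cells, with `n_tissues_used` recorded. The shared null is built
  at the full tissue count — conservative for short genes, since their $F$
  sums fewer terms. `per_gene_null = TRUE` builds one null per distinct
  tissue count instead.
* **Zero p-values** are rejected, not clamped: a 0 upstream is a bug or a
  saturated test, and silently flooring it would hide that. Callers that
  legitimately need a floor apply it explicitly before entry.

## The synthetic cross-tissue generator

The generator emulates summary-level input: ~9,600 genes × 11 tissues, null
genes with p ~ Uniform(0, 1] and logFC ~ Normal(0, `null_logfc_sd`), signal
genes with a fixed fold-change direction and p drawn from a point mass
(default, for clean recovery tests) or a Beta law (for power curves). The
per-tissue test that would have produced real p-values is deliberately not
modelled — the generator targets the (p, logFC) summary level directly.

What passing tests therefore show: the statistic, null and p-value machinery
are correct and calibrated *given* well-behaved per-tissue inputs. What they
do not show: robustness to correlated tissues (real tissues share animals),
to p-values that are miscalibrated upstream, or to dependence between p and
the fold-change magnitude. Those effects live in the upstream per-tissue
analysis, outside this package's scope.

One master seed drives a named sub-stream per generator (`derive_seed`), so
outputs are reproducible bit-for-bit and adding a generator never perturbs
an existing one.

## RPKM, fold changes and volcano tables

RPKM is computed as counts / (length in kb × library size in millions); it
is invariant under joint rescaling of counts and library sizes. Group fold
changes are reported on the ratio scale with a log2 companion; the default
pseudocount is 0 with an explicit error on a zero denominator, because real
RPKM group means in this setting are small but nonzero, and a silent offset
would bias exactly the large fold changes the analysis cares about. Display
rounding is to the nearest integer fold. Per-gene tests are Welch's t on
log2(RPKM + 1) — unequal variances by default because the group sizes of
interest are unequal (n = 4 vs 3) — with two degenerate-case conventions:
identical constant groups give t = 0, p = 1; constant-but-different groups
give the smallest representable p with a warning. The volcano table carries
−log10 p against log2 fold change and flags a highlight list (the packaged
HA-family gene list, shipped exactly as published — the source text counts
it as 38 symbols though it enumerates 39).

## SEC sizing

Calibration is piecewise-linear in log10(MW) versus elution position,
through the standards' peak fractions (2500, 500, 150 kDa), taken at
fraction centers. Log-linear interpolation is the standard working model for
both SEC columns and gel ladders; with only peak positions available,
anything more flexible would be unconstrained. Molecular weight must
decrease strictly with position — larger molecules elute first and migrate
least — and any other ordering is rejected. Outside the anchor range the map
is clamped to the terminal anchors, flagged, and never extrapolated: sample
peaks are expected to sit inside the calibrated range, and an unbounded
log-linear extrapolation would manufacture sizes the column cannot resolve.

Profiles are normalized to percent of total HA recovered (idempotent;
all-zero profiles are an error). The size-class summary places the 500- and
150-kDa boundaries on the fraction axis and splits each fraction's mass by
where its position interval (center ± 0.5) falls; a straddling fraction is
divided linearly in position. Linear-in-position (rather than linear in
log-MW) splitting was chosen because at 30 fractions the two differ by less
than the discretization error itself, and position is the axis on which the
instrument actually integrates. Class bounds are strict (> 500, < 150); the
150–500 kDa mid-mass is reported but excluded from the HMW/LMW ratio. A
profile with no LMW mass reports the ratio as `Inf` with an explicit flag
rather than an error, since all-HMW samples are a real outcome. Peak calling
returns the modal fraction's MW, breaking ties toward the earlier-eluting
(larger) fraction with a tie flag.

The elution simulator represents a sample as a mixture of lognormal MW
components, integrates the mixture over each fraction's MW interval under
the calibration, folds the out-of-window tails into the terminal fractions
(as a real collection window does), and applies mean-one multiplicative
lognormal noise per fraction. The returned truth summary is computed from
the *continuous* mixture, so recovery tests measure pure discretization
error: at 30 fractions a noise-free 70/30 split above-500/below-150
recovers its 7/3 ratio to well within 5%, and the error shrinks as the
fraction grid is refined. The simulator does not model column spreading
(band broadening), detector saturation, or inter-fraction carryover.

## HA quantification

The assay standard curve is inverted by monotone piecewise-linear
interpolation; out-of-range signals are returned as `NA` with a flag rather
than extrapolated, since an ELISA-like readout outside its standards needs
re-dilution, not arithmetic. A four-parameter logistic was deliberately not
fitted: the module's role is unit conversion against supplied standards, not
assay modelling. Tissue content is µg HA per g dry tissue.

Group comparisons implement the study designs: two-group Welch's t (a
pooled-variance option reproduces the classical Student form — with group
sizes of 3–11 the unequal-variance form is the safer default), one-way
ANOVA with Holm–Šidák (default) or Bonferroni pairwise adjustment, and
two-way species × tissue ANOVA with interaction (empty design cells are an
error). Holm–Šidák is coded directly — sorted p-values adjusted as
$1-(1-p_{(i)})^{m-i+1}$ with running maxima — because base R's `p.adjust`
does not provide it; it is uniformly no larger than Bonferroni, which the
tests verify on random p-vectors. The quantification simulator draws
lognormal values with specified group means and coefficients of variation
(CV 0 returns the means exactly); it does not model plate effects or
detection limits.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the cross-tissue calibration at
the full grid (9,600 × 11) with 20,000 resampling rounds — enough for the
3-binomial-SE calibration band at $\alpha = 0.01$ while keeping the default
check fast; the analysis drivers use the full 100,000 rounds. Oracle
equivalence of the statistic is checked to 1e-12 relative tolerance against
an independently coded brute-force sum; calibration round-trips to 1e-9;
size-class percentages conserve to 1e-6. Ratio-recovery tolerance at 30
fractions is 5%, dominated by discretization.

## Limitations

* The cross-tissue statistic treats tissues as independent pieces of
  evidence; shared animals or batch structure inflate its apparent
  consistency, and nothing here corrects for that.
* The gene-set chi-square aggregation assumes uniform, independent per-gene
  $\rho$; genes in one set sharing a null and possibly co-regulated violate
  independence mildly. A resampling-based gene-set null would be the
  conservative alternative.
* No multiple-testing correction is applied across genes at the per-gene
  stage beyond the fixed $\alpha$; the intended use is small curated panels.
* SEC sizing assigns each fraction a single MW from the calibration; real
  fractions contain a distribution, so narrow true mixtures appear slightly
  broadened and boundary mass assignment is approximate at the
  fraction-width scale.
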