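# hamet

Statistical toolkit for comparative hyaluronan (HA) metabolism studies:
cross-tissue differential-expression aggregation, RPKM/volcano tables,
size-exclusion chromatography (SEC) molecular-weight analysis, and HA
quantification with the associated group comparisons — plus seeded
synthetic-data generators so the whole pipeline is testable with known
ground truth.

## Who this is for

Comparative physiology and matrix-biology groups asking questions like
"is gene X consistently overexpressed across tissues in species A vs
species B?" and "how is the HA mass in this tissue split between high- and
low-molecular-weight chains?". The package takes summary-level inputs
(per-tissue p-values and fold changes; per-fraction HA amounts; assay
readouts) — not raw reads or chromatograms.

## The core statistic

For one gene measured in $l$ tissues with per-tissue p-values $p_t$ and
log fold-changes $\mathrm{logFC}_t$:

$$F \;=\; \Bigl|\,\sum_{t=1}^{l} \ln(p_t)\,\mathrm{sgn}(\mathrm{logFC}_t)\Bigr|$$

— Fisher's method with each term signed by the fold-change direction, so
only consistently directed evidence accumulates. The null distribution of
$F$ is estimated empirically by resampling (p, logFC) cells from the full
gene background (default 100,000 rounds), each gene gets an empirical
cross-tissue p-value $\rho$ with the add-one estimator, and a gene set is
aggregated with the unweighted Fisher statistic
$\mathcal{F} = \sum_g \ln \rho_g$ referred to $\chi^2_{2k}$.

On the physical side, SEC profiles are normalized to percent of total HA
recovered, molecular weight is assigned by piecewise log-linear calibration
against standards (2500/500/150 kDa; gel ladders likewise), and the mass
balance is summarized as the HMW (> 500 kDa) to LMW (< 150 kDa) ratio.

## Worked example

```r
library(hamet)

# lymph-node RPKM group summaries (NMR n = 4 vs mouse n = 3), packaged
tab <- lymph_node_rpkm()
fc <- fold_change_from_means(tab$nmr_mean, tab$mouse_mean)
round(fc$fold_change[tab$gene_id == "Tnfaip6"])   # 58
fc$fold_change[tab$gene_id == "Hyal3"]            # 131.37

# cross-tissue aggregation on simulated data with 2 planted genes
cfg <- cross_tissue_sim_config(n_genes = 9600, n_tissues = 11,
                               n_signal_genes = 2,
                               signal_p_law = list(type = "fixed", value = 1e-3),
                               seed = 1)
sim <- simulate_cross_tissue_table(cfg)
res <- run_cross_tissue_analysis(sim$matrix,
                                 geneset = sim$truth$gene_id[1:7],
                                 alpha = 0.01, n_rounds = 100000, seed = 1)
head(res$genes[res$genes$significant, ])
res$geneset
```

Running the drivers in `analysis/` reproduces the full workflow
(`Rscript analysis/01_simulate.R --seed 1`, then `02` ... `05`); with seed 1
they report, among other things:

```
pure null: 1.052% of genes flagged at alpha = 0.01 (expect ~1%)
planted genes recovered: 2 of 2 (rho = 1e-05, 1e-05)
7-gene set: sum(ln rho) = -28.00, p_geneset = 5.81e-07
```

i.e. the empirical null is calibrated (≈1% false positives at α = 0.01),
both planted consistent genes are recovered at the resolution floor of the
100,000-round null, and the 7-gene set containing them aggregates to a
strongly significant combined p-value. Step 4 prints the SEC size-class
table (a lymph-node-like HMW peak gives 100% mass > 500 kDa, peak at
2500 kDa; a degraded sample gives a ratio near 0.03), and step 5 the Welch /
ANOVA comparison tables.

## Layout

- `R/` — the package: simulators, cross-tissue statistics, expression
  tables, SEC sizing, quantification, plain-text I/O.
- `analysis/01_simulate.R` ... `05_ha_quant.R` — numbered drivers wiring the
  modules into a reproducible run; each writes its tables and a JSON
  provenance record under `results/`.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
- `vignettes/ha-metabolism-methods.Rmd` — the methods vignette: models,
  assumptions, design decisions, limitations.
- `inst/extdata/` — packaged plain-text fixtures (HA-family gene list,
  lymph-node RPKM group summaries).
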