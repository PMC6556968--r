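# telomark

Confounder-adjusted discovery of telomerase-associated multi-omics
signatures, and telomerase-driven tumor subtyping.

Most cancers immortalize by reactivating telomerase (TERT). Contrasting
TERT-high tumors (≥ 2 RNA-seq reads of TERT) against TERT-low tumors
(< 2 reads, no ALT-related ATRX/DAXX alteration) exposes the molecular
program around telomerase — but the contrast is observational, and
clinical covariates (age, sex, purity, ...) confound every naive
per-feature test. `telomark` implements the full analysis chain for this
setting, for computational biologists who want each stage as a tested,
reusable function:

* **Matching-weight differential screen** — propensity scores
  `e = P(Z=1|x)` by logistic regression; matching weights
  `w = min(e, 1−e) / (Z e + (1−Z)(1−e))`; covariate balance by the
  standardized difference (< 10%); the effect estimator
  `Δ_MW = Σ w Z Y / Σ w Z − Σ w (1−Z) Y / Σ w (1−Z)`; significance from
  weighted regression + BH-FDR (`q < 0.05`) jointly with a
  propensity-stratified permutation null (`p < 0.05`).
* **Co-expression network** — unsigned adjacency `|r|^β` with a
  scale-free criterion for β, topological overlap, module detection,
  eigengenes/kME, intramodular connectivity `K`, top-5% hubs, hub-strength
  tiers across conditions, and permutation `Zsummary` preservation
  (< 2 / ≥ 10 cutoffs).
* **miRNA regulation** — target aggregation (miRanda ∩ miRDB) ∪
  miRtarBase, multi-hit filtering (≥ 2 up / ≥ 4 down), PC1 coupling of
  miRNA and target sets, and the miR-17-92 cluster score (member mean)
  against groups and the tumor/normal telomere-length ratio.
* **Random-forest subtyping** — multi-omics marker profile, unsupervised
  RF dissimilarity `√(1 − similarity)` against marginally resampled
  synthetic data, PAM into two subtypes oriented by telomerase-activity
  score, compared by Wilcoxon, log-rank and Cox (Breslow ties).
* **Synthetic cohort generator** — multi-omics cohorts with planted
  confounding, differential features, modules/hubs, an anti-coupled miRNA
  cluster, and survival subtypes, so every stage is validated against
  known ground truth.

## Worked example

The `analysis/` directory holds the staged workflow
(`01_simulate.R` … `05_subtype.R`). In condensed form:

```r
library(telomark)

coh <- generate_cohort(cohort_config(seed = 42))
z      <- coh$clinical$z
covars <- coh$clinical[, grep("^conf", names(coh$clinical))]

res <- psm_differential(coh$layers$mrna, z, covars, n_perm = 499, seed = 101)
res$balance
#>   covariate std_diff_before std_diff_after balanced
#> 1     conf1            28.1           2.53     TRUE
#> 2     conf2            68.3           6.12     TRUE
#> 3     conf3            85.2           2.05     TRUE
```

The planted confounding (standardized differences of 28–85%) is reduced
below the 10% balance criterion by the matching weights. The screen then
recovers the planted differential genes (60 of 60 at these conditions)
at an empirical false-discovery proportion of a few percent.

Running the staged workflow end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential.R
Rscript analysis/03_network.R
Rscript analysis/04_mirna.R
Rscript analysis/05_subtype.R
```

prints, among other things:

```
mrna          169 significant features (FDR < 0.05 & perm p < 0.05)
resampling: Delta MW correlations 0.94-1.00 over 20 draws
intramodular K vs activity correlation: R = 0.95 (p = 5.8e-26)
miR-17-92 score: mean 4.14 (high) vs 3.63 (low), Wilcoxon p = 0.00012
cluster score vs telomere-length ratio: r = -0.85 (p = 2.1e-57)
telomerase activity: median 0.45 (RFcluster1) vs -0.39 (RFcluster2), Wilcoxon p = 3.9e-13
survival: log-rank chi^2 = 12.9 (p = 0.00032); Cox HR (cluster2 vs 1) = 1.83 (p = 0.00039)
```

— the miR-17-92 cluster is TERT-high-specific and anti-correlated with
the telomere-length ratio; intramodular connectivity in the
activity-linked module tracks the telomerase-activity score; and the two
RF subtypes differ in telomerase activity and overall survival, with
RFcluster1 the high-activity arm. Stage outputs land under `results/`.

The methods, their assumptions, and every numerically consequential
design choice are documented in
`vignettes/telomerase-multiomics.Rmd`.

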