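# mirilqtl

Expression QTL mapping for small recombinant inbred line (RIL) panels that
carry an introgressed, selected mutation — "miRILs". The motivating design is
a *Caenorhabditis elegans* panel of 33 lines from a Bristol N2 x Hawaiian
CB4856 cross, sensitized for Ras/MAPK signaling by a *let-60* gain-of-function
allele kept homozygous at IV: 11.7 Mb. The package is for geneticists who want
to run, test or scrutinize this kind of analysis end to end: every stage works
on a synthetic study with known truth, so the whole pipeline is verifiable
without any microarray download.

## What it computes

* **Expression-marker genetic map.** Strain intensities are centered on the
  parental mean, `R = Y − (Y_P1 + Y_P2)/2`, and correlated per window of 20
  consecutive reference cis-eQTL against the panel's N2-signed effects; `r >
  0.6` calls the N2 genotype, `r < −0.6` CB4856. Windows are QC'd on parental
  replicates, missing calls imputed from flanks, chromosome ends extended, and
  markers pruned to minor-genotype frequency > 15%.
* **eQTL scan.** Per spot and marker the linear model `y ~ x` (binary
  genotype), i.e. the equal-variance two-sample t-test; the genome-wide
  threshold is the smallest −log10(p) cutoff where permutations estimate
  FDS/RDS ≤ q (q = 0.1, 10 per-feature strain permutations).
* **Peaks and classes.** One peak per spot per chromosome with a 1.5-drop
  confidence interval; *cis* if the gene is within 2 Mb of the peak or inside
  the interval, else *trans*.
* **Trans-bands.** Trans spot peaks per 1-Mb bin; with λ = spots/occupied
  bins, a bin is a hotspot when the exact Poisson upper tail P(X ≥ count)
  clears the level, and adjacent hotspot bins merge. With λ = 22.10 (1149
  spots, 52 bins) the admission counts are > 30 spots at P < 0.05 and > 38 at
  P < 0.001.
* **Replication and uniqueness.** A trans gene replicates when a reference
  study maps a trans-eQTL for the same gene on the same chromosome; a band's
  uniqueness is the lower Poisson tail P(X ≤ replicated) at λ = expected rate
  x band genes (depletion = population-specific band).
* **Power.** Simulated QTL at every marker for explained variance 20–80%
  (5% steps, 10 reps, N(0,1) noise), scored at −log10(p) > 3.2, with a
  noncentral-F closed form as cross-check; `effect_size_for_r2()` maps
  explained variance to effect size (1 noise-SD ⇔ 20%).
* **Enrichment and concordance.** Hypergeometric over-representation with
  Bonferroni < 0.05, category size > 3, overlap > 2; and sign-concordance of
  eQTL effects with transgenic allelic differences at a modifier locus.

## Worked example

The numbered scripts under `analysis/` run the whole study; each one prints
what it found and writes tables under `results/`. With the default seed:

```sh
$ Rscript analysis/01_simulate_study.R
Simulated 33 lines x 498 raw markers (232 informative after pruning).
P1 frequency: 1.00 at the selected locus, 0.58 genome-wide.
Planted effects: 1400 cis, 250 trans, 380 in 3 trans-bands.

$ Rscript analysis/02_expression_map.R
Windows: 61 formed, 48 passed QC, 44 informative after pruning.
Call accuracy vs truth: 100.00% for made calls, 96.81% after imputation/extension.

$ Rscript analysis/03_scan_threshold.R
Scanned 5000 features x 232 markers.
Selected threshold -log10(p) > 3.560 at q = 0.10 (RDS = 1840, FDS = 184.0).

$ Rscript analysis/04_eqtl_tables.R
1892 eQTL records at -log10(p) > 3.560.
  class direction genes spots
1   cis P1_higher   823   830
2   cis P2_higher   380   388
3   cis     total  1193  1218
4 trans P1_higher   271   272
5 trans P2_higher   399   401
6 trans     total   665   670
69% of cis genes have the higher expression on the N2 allele (planted: 70%).

$ Rscript analysis/05_hotspots_replication.R
674 trans spots in 86 occupied bins: lambda = 7.84 per bin.
Bins with > 18 spots reach P < 0.001; 3 merged trans-bands detected.

$ Rscript analysis/06_power.R
Detection of QTL explaining 40% of variance: 74% on this map.
Analytic balanced-marker power at 40%: 80%; family-wise false-positive rate on null phenotypes: 0.059.
```

Reading the output: selection fixes the P1 allele at the introgressed locus
and drags the genome-wide P1 frequency to 0.58; pruning removes most of the
selected chromosome because its markers fall under 15% minor-genotype
frequency. The permutation threshold lands near 3.6 on this data set (1840
spots discovered against a mean of 184 permutation discoveries = estimated
FDR 0.1). The cis gene counts recover the planted 70% N2 bias, the three
detected trans-bands coincide with the three planted regulator bins, and
detection power at 40% explained variance sits in the mid-70s percent — below
the 80% balanced-marker closed form because real markers are unbalanced and a
detection must also localize the simulated marker inside the peak's 1.5-drop
interval.

The same stages are available programmatically (`simulate_miril_study()`,
`center_on_parents()`, `call_expression_markers()`, `eqtl_scan()`,
`permutation_threshold()`, `call_peaks()`, `classify_cis_trans()`,
`detect_trans_bands()`, `simulate_power()`, `enrich()`,
`allelic_concordance()`), or as one call through `run_pipeline(miril_config())`.
The methods vignette (`vignettes/miril-eqtl-methods.Rmd`) explains the models,
parameter choices and limitations.

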