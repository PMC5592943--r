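---
title: "eQTL mapping in mutation-introgressed RILs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eQTL mapping in mutation-introgressed RILs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirilqtl)
```

## The design this package analyses

A miRIL (mutation-introgressed recombinant inbred line) panel is a set of
homozygous lines derived by selfing from a cross of two parents — here
Bristol N2 ("P1") and the Hawaiian isolate CB4856 ("P2") — in which a single
induced mutation (a gain-of-function Ras allele at IV: 11.7 Mb in the
motivating design) is kept homozygous from the F2 generation on. Selection at
the introgressed locus fixes the P1 allele there and skews allele
frequencies along the whole selected chromosome; everywhere else the two
parental genomes segregate at roughly 1:1. The population is small (33
lines), which shapes every statistical choice below.

The pipeline covers six stages: (i) simulation of the design, (ii)
construction of a dense genetic map from the expression data themselves,
(iii) a single-marker linear-model eQTL scan with a permutation FDR
threshold, (iv) cis/trans classification with drop-based confidence
intervals, (v) Poisson trans-band (hotspot) detection with replication and
uniqueness tests, and (vi) enrichment and modifier-allele concordance. The
numbered scripts under `analysis/` run these stages in order on the default
synthetic study and write their tables under `results/`.

## The synthetic study and what it does (and does not) emulate

`simulate_miril_genotypes()` models meiosis with a Poisson number of
crossovers per chromosome (mean 1) at uniform positions, selfing for 10
generations, rejection of F2 individuals that are not homozygous P1 at the
selected locus, and forcing of residual heterozygous runs to a random
parental segment. Defaults were fixed once, before any downstream result was
inspected, to match the design's stated conditions:

* 6 chromosomes with *C. elegans*-like lengths; selected locus IV: 11.7 Mb.
* a 200-kb marker grid (~500 raw markers), which after informative-marker
  pruning yields ~200–300 markers — the range the real map occupies (247).
* 33 lines, 5000 array spots at test scale (the full 45,220-spot scale is a
  configuration choice, not a different code path).
* planted architecture: ~1200 strong cis effects (|a| in 2–4 noise-SD units,
  70% with the higher expression on the N2 allele, echoing the observed
  71% N2 bias), 200 weaker cis effects (0.5–2.5), 250 isolated trans
  effects, and three trans-bands of 200/120/60 spots — sizes chosen to
  bracket the observed band sizes (56–205 spots) — each driven by one
  regulator marker placed in a single 1-Mb bin, with 70% of band effects
  higher on the P2 allele.
* unit Gaussian noise; effect sizes are in noise-SD units, so at a balanced
  marker an effect of 1 explains 20% of the variance
  (`effect_size_for_r2()` inverts R² = a²/4 / (a²/4 + 1)).

The generator does not emulate microarray artifacts (dye bias, probe
cross-hybridization, intensity-dependent variance), heterozygosity,
segregation distorters other than the selected locus, or crossover
interference. Passing tests on this generator therefore demonstrate that the
statistical machinery recovers a known architecture under idealized noise;
they do not validate normalization choices or probe-level error models,
which are upstream of this package's inputs.

The reference cis-eQTL panel used for genotyping is derived from the
planted strong-cis genes with jitter (SD 0.25) on the effects, emulating a
prior experiment that measured the same cis effects. Its effect range
(|a| ≥ 2) reflects that a genotyping panel is built from a study's
*strongest* cis-eQTL; with weaker panels the windowed correlations fail the
parental QC far more often than the real design's 424 → 204 attrition.
Reference eQTL tables for the replication stage are synthesized directly
from the truth table (75%/60% of cis genes shared, 23.8%/15% of trans genes
replicated on the same chromosome, plus unrelated background genes) rather
than by scanning a second simulated population; this makes the expected
replication rates exact and the stage cheap to test. Both constructs are
synthetic stand-ins and are labelled as such in their documentation.

## Expression-marker genotyping

Strain intensities are first centered on the parental mean,
R = Y − (Y_P1 + Y_P2)/2, with parental values averaged over their replicate
arrays. For a gene with a cis effect, R is about +e/2 for a strain carrying
the P1 allele and −e/2 for P2, so across a window of cis genes the centered
profile correlates positively with the panel's N2-signed effects when the
local genotype is P1 and negatively when it is P2.

Windows are 20 consecutive panel genes, formed per chromosome
(floor(n/20) windows per chromosome) so no window straddles a chromosome
end; the window's representative position is the median position of its
genes, since nothing in the procedure pins a sharper location. Pearson
correlation is used (the effects are continuous); calls need |r| > 0.6,
QC requires each parental replicate to call its own genotype and more than
half the strains to reach |r| > 0.5. Missing calls flanked by equal calls
are imputed; chromosome ends copy the distal-most call; discordant flanks
stay missing and are flagged as crossover intervals — these are *excluded*
per strain from the scan rather than guessed, to avoid fabricating
genotypes at crossovers.

Accuracy has two distinct meanings here. The accuracy of *made* calls
(provenance "correlated") is essentially perfect at the default scale
(>99.9%, matching the sub-1%-per-strain error the procedure is designed
for). Point accuracy *after* imputation and end extension depends on window
density: each imputed or extended call asserts a genotype over the bp span
of a window, and the probability that a crossover hides inside that span
grows with it. At the 5000-feature test scale (~60 windows) post-imputation
accuracy is ~96%, with errors confined to imputed/extended positions; at
the full design scale (45,220 features, 8480 panel genes, ~325 QC windows)
it exceeds 99.5%. The genotype-recovery property test asserts ≥99% at the
full-design density for exactly this reason.

Pruning keeps markers whose minor-genotype frequency exceeds 15% — which
removes most of the selected chromosome, as in the real design — and then
collapses adjacent markers with identical genotype columns to the first of
each run, so every retained marker marks a crossover border.

## The scan and its threshold

The model is a per-feature, per-marker ordinary least-squares fit of
expression on the binary genotype; with one binary predictor this is the
equal-variance two-sample t-test, and the implementation (vectorized group
sums) is property-tested against `t.test()` to 1e-10. Missing genotypes are
excluded pairwise; markers left with fewer than two strains per class are
skipped with a flag; perfect separation is capped at −log10(p) = 320 to
keep the matrix finite.

The genome-wide threshold comes from permutations: each feature's strain
labels are shuffled independently, the full scan re-run 10 times, and
discoveries counted as features whose genome-wide maximum reaches a
candidate cutoff. The selected threshold is the smallest observed cutoff t
with FDS(t)/RDS(t) ≤ q, q = 0.1 — the plain permutation estimator of the
FDR with m0/m = 1. The criterion family is configurable (`m0_ratio`,
`log_m_correction` ∈ {none, multiply, divide}) because published variants
of this estimator differ in whether they scale q by m0/m or log(m); the
plain ratio is the default because it is the standard estimator and the
most conservative of the readings consistent with the design. The candidate
grid is the set of observed per-feature maxima, since values between
observed maxima change no count. On the default study this selects a
threshold near 3.5 (the real data's analogous cutoff was 3.2); realized FDR
measured against the planted truth stays well below 2q across replicate
studies.

## Peaks, intervals, classification

One peak is reported per feature per chromosome (the chromosome maximum,
leftmost on ties, for determinism); multi-peak splitting within a
chromosome is deliberately not attempted — with 33 lines the scan has no
power to resolve linked QTL, and the motivating analysis does not define a
splitting rule. The confidence interval is the contiguous marker run around
the peak with −log10(p) strictly above peak − 1.5 (">" rather than "≥",
configurable; the boundary convention is unstated in the source analysis
and the choice never matters on continuous data). A record is cis when its
gene lies on the peak chromosome within 2 Mb of the peak *or* inside the
interval; the wide 2-Mb window reflects the small number of unique
recombinations in 33 lines. Counts are reported at both gene and spot
level, deduplicating spots to genes per class and direction, so a gene
represented by spots of opposite sign appears in both direction rows.

## Hotspots, replication, uniqueness

Trans spot peaks are binned per 1-Mb half-open bin (position p is in bin
floor((p−1)/1e6), so Mb boundaries are unambiguous and no spot is counted
twice). The expectation per *occupied* bin is λ = total trans spots /
occupied bins; a bin is significant when the exact upper Poisson tail
P(X ≥ count) is below the level (0.001 by default), and adjacent
significant bins merge into bands. The admission convention "more than c
spots" ⇔ P(X ≥ c+1) < α reproduces both published admission counts (>30 at
0.05 and >38 at 0.001 for λ = 22.10). Counting uses spots, not genes,
matching how the expectation was derived; gene deduplication applies only
to band membership reporting.

Replication of a trans gene requires a reference trans-eQTL for the same
gene on the same chromosome (cis replication needs only the same gene).
Band uniqueness is the lower Poisson tail P(X ≤ replicated) at
λ = expected rate × band genes, i.e. a depletion test: a small p says the
band's genes replicate less often than the genome-wide trans rate, so the
band is specific to this population. The expected rate defaults to the
genome-wide trans replication rate computed from the supplied reference
sets and is overridable.

## Power simulation

For each informative marker and each explained-variance level from 20% to
80% in 5% steps, ten phenotypes are drawn as a·genotype + N(0,1) with
a = 2·sqrt(r²/(1−r²)), scanned genome-wide, and scored. "Detected
correctly" is not self-defining; the default requires the genome-wide peak
to clear the threshold, sit on the simulated marker's chromosome, and hold
the simulated marker inside its 1.5-drop interval. This is the main lever
behind any single headline power number: looser location criteria raise the
rate by several points. The simulation is cross-checked against the closed
form — at a balanced marker the test statistic is noncentral F(1, n−2) with
ncp = n·r²/(1−r²), giving 79.6% at n = 33, r² = 0.40 and the 3.2 cutoff —
and agrees within Monte-Carlo error; on the realistic map, where minor
allele frequencies run down to 15% and the location criterion bites, the
rate at r² = 0.40 lands in the mid-70s. Estimated explained variance at
detected peaks is reported with its winner's-curse bias (strong at low
power, shrinking toward r² = 0.8); no correction is applied.

## Enrichment and concordance

Enrichment is an upper-tail hypergeometric test on unique genes with three
filters: Bonferroni-corrected p < 0.05, category size > 3, overlap > 2.
The Bonferroni denominator counts only categories that survive the size
filter — only hypotheses actually tested — a choice the source analysis
leaves open; with the alternative (all catalogue categories) corrected
p-values scale by a known constant, so either reading is recoverable from
the raw p. The universe defaults to all genes on the platform present in
the annotation.

Modifier-allele concordance compares, for genes whose trans-eQTL colocalize
with a candidate locus, the signed eQTL effect with the expression
difference between transgenic lines carrying the two alleles: Pearson
correlation, R², and the fraction of sign-concordant genes (zero
differences count as discordant). At least three shared genes are required;
when a gene has several spots the strongest effect represents it.

## Numerical and engineering choices

* All stochastic operations take explicit seeds and restore the caller's
  RNG state; sub-seeds are derived arithmetically and stay below 2³¹.
* Poisson and hypergeometric tails use the exact distribution functions of
  the stats package (stable in log space); tests verify them against direct
  pmf summation.
* TSV outputs are written at 6 significant digits so reruns diff clean;
  coordinates are 1-based inclusive bp, bins half-open in Mb.
* Problem sizes in the test suite and analysis scripts (5000 features, 33
  lines, 10 permutations, 10 reps/marker, 50 replicate studies for the FDR
  check, 45,220 features for the one full-density genotyping check) are the
  package's standing choices for a laptop-scale run of the full design.

## Known limitations

* One peak per feature per chromosome; linked or opposite-sign QTL on one
  chromosome are reported as a single peak with a wide interval.
* The permutation threshold treats features independently; correlated
  features (co-expressed genes) make FDS slightly optimistic, which is why
  realized FDR is verified against planted truth in the tests.
* Post-imputation genotype accuracy is window-density dependent (above);
  at coarse density the imputed/extended calls carry most of the error.
* The uniqueness test conditions on the expected replication rate as a
  known constant; uncertainty in that rate is not propagated.
* The synthetic reference panels share provenance with the simulated
  expression data (same planted effects); cross-study heterogeneity is
  emulated only through effect jitter and partial sharing.
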