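---
title: "Cell-type-resolved analysis of developing brain methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved analysis of developing brain methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmeth)
```

# Scope and model

cortexmeth re-implements the post-alignment analysis of whole-genome
bisulfite sequencing (WGBS) from sorted neuronal (NeuN+) and glial (NeuN−)
nuclei collected across postnatal human cortical development. The data unit
is the per-cytosine report: for every cytosine (CpG, CHG, or CHH context),
per-sample counts of methylated and total reads, from which the methylation
level $\beta = \text{meth}/\text{total}$ is formed. Zero-coverage cells are
treated as missing, never as $\beta = 0$, so means are not biased downward.

Six analysis stages sit on top of this container:

1. **Filtering** — CpGs require a minimum coverage of 3 in all samples;
   CpHs a minimum coverage of 5 plus at least 5 samples with $\beta > 0$.
2. **Smoothing** — per-sample local-likelihood smoothing of CpG $\beta$: a
   weighted quadratic in position over the smallest symmetric window with at
   least `min_sites` CpGs spanning at least `min_width` bp, with
   tricube(distance) × coverage weights.
3. **Segmentation** — per-sample methylome features: partially methylated
   domains (PMDs) from a two-state decoding of a 101-CpG disorder statistic,
   then unmethylated/low-methylated regions (UMRs ≥ 30 CpGs, LMRs ≥ 4 CpGs)
   below a shuffle-calibrated cutoff, and DNA methylation valleys (DMVs:
   UMRs with mean methylation ≤ 0.15 and width ≥ 5 kb).
4. **Differential methylation** — site-wise linear models of $\beta$ on age
   and cell type (`~ age`, `~ age + cell`, `~ age * cell`; glia = 0,
   neuron = 1), moderated t-tests with empirical-Bayes variance shrinkage
   for positions, and bump hunting for regions: maximal same-sign runs of
   sites whose coefficient exceeds a cutoff (0.1 for cell type, 0.005 for
   age, 0.009 for the interaction) within maxGap = 1000 bp clusters, with a
   family-wise error rate from 250 label permutations.
5. **Trajectories and autocorrelation** — interaction regions (cdDMRs) are
   decomposed by k-means (k = 6, 100 starts) on per-region (glia, neuron)
   age slopes; methylation autocorrelation is computed per 1-kb position
   cluster (≥ 5 cytosines) or per region up to lag 4.
6. **Methylation–expression association** — per-cytosine cis scans against
   gene/exon log2(FPKM+1) and splice-event PSI within 1 kb, marginal CpG
   rescue around significant CpH hits, donor-count and coding filters, an
   age-confounding recheck, and a stratified summary table.

# The synthetic-data generator

Because the study-scale data cannot be reproduced at desk scale, every
stage is validated on synthetic methylomes with a machine-readable truth
ledger (`simulate_methylome()`, `simulate_expression()`,
`simulate_annotation()`). The generator's defaults are the study
conditions:

* **Design** — 12 neuronal + 12 glial samples with ages on an even grid
  over 0–23 years; optional homogenate samples are modelled as the average
  of the two fractions.
* **Coverage** — total reads per cytosine are negative binomial with mean
  15 and size 8, matching the reported average coverage of ~15×.
* **CpG background** — per-site baseline $\beta$ from the mixture
  0.94·Beta(45,4) + 0.04·Beta(5,5) + 0.02·Beta(1.5,15). At 15× coverage
  this puts ~72–75% of *observed* CpG $\beta$ above 0.8, inside the
  reported 71–76% band. The mixture weights were calibrated once, by Monte
  Carlo, against that published marginal; the small mid/low components keep
  chance runs of lowly methylated background CpGs (which would masquerade
  as segments) rare.
* **CpH background** — Beta(0.5, 30), giving ~97% of observed CpH
  $\beta$ below 0.2 (reported band 92–99%); 30% of CpH sites gain
  0.004 $\beta$/yr in neurons only, which drives the accumulation of
  \>10%-methylated CAC/CAG sites with age.
* **Positions** — CpGs are an island + background mixture (islands of 1 kb
  every 10 kb at 0.05 sites/bp over a 0.002 background), reproducing the
  bimodal CpG density of real genomes; CpHs are uniform at 0.02 sites/bp.
  A handful of CpG-free "desert" segments mirror real CpG deserts and host
  part of the planted CpH-exclusive association effects.
* **Features** — planted UMRs (β ≈ 0.05, 3–4.5 kb), LMRs (β ≈ 0.2,
  1.2–1.8 kb, < 30 CpGs), DMVs (wide UMRs ≥ 5 kb), and PMDs (site-level
  β ~ Beta(2,2), ≥ 150 kb) laid out without overlap; one assembly gap is
  labelled heterochromatin and placed inside a PMD to exercise the gap
  exemption.
* **DMRs** — cell-type DMRs add Δβ = ±0.2 for neurons over 8–20 CpGs.
  Interaction DMRs follow six trajectory archetypes that share one
  neuron-minus-glia slope-difference magnitude D = 0.016 β/yr, with
  (glia, neuron) multipliers (0, 1), (−0.4, 0.6), (0, −1), (2/3, −1/3),
  (−2/3, 1/3), (0.4, −0.6). Two deliberate properties of this pattern:
  the median absolute neuronal slope is 0.6 D and the glial 0.4 D, so the
  planted neuron/glia effect ratio is exactly 1.5; and the equal |D|
  across groups keeps each archetype's contribution to the permutation
  null comparable — in an earlier design with unequal archetype slopes the
  largest divergence dominated the null maximum and sank the sensitivity
  of the smallest groups. D itself was fixed by a pre-hoc power analysis:
  run formation in bump hunting needs the per-site coefficient to clear
  the 0.009 cutoff by roughly three coefficient-noise SDs, which at 15×
  coverage and n = 24 gives D ≈ 0.016, comfortably above the smallest
  slope difference (0.005 β/yr) the detection cutoffs treat as
  biologically meaningful. Each
  interaction region also carries a smooth AR(1) spatial profile
  (site-order ρ = 0.8, sd 0.1, truncated at ±0.2) shared by every cytosine
  in the region — the within-region spatial coherence that makes mixed
  CpG + CpH autocorrelation meaningful.
* **Association sites** — designated background cytosines receive
  donor-level variability (sd 0.15 around a mid-range level); planted
  expression features respond linearly to the donor's *observed*
  methylation with noise scaled for a realized R² of 0.5. Tying the effect
  to observed rather than latent methylation is intentional: binomial
  sampling at 15× would otherwise attenuate the realized R² by roughly
  40%, and the target is defined at the scan's inputs. "Shared" CpH
  effects have a CpG partner within 1 kb riding the same donor surface;
  "exclusive" CpH effects sit in deserts or sparse background. A few sites
  track age exactly while their feature's expression is driven by age,
  exercising the confounding recheck.

What the generator does *not* emulate: spatial autocorrelation of
background CpG methylation outside planted regions (site baselines are
independent), read-level artefacts (bisulfite conversion error,
mapping bias, hydroxymethylation), strand asymmetries, and linkage between
methylation and genotype. Passing recovery tests on these synthetic data
therefore demonstrates correctness of the estimators and calibration of
their error control under the assumed generating model — not robustness to
every artefact of real WGBS data.

# Numerical and design choices

* **Smoothing window.** The defaults `min_sites = 70`, `min_width = 1000`
  follow the standard convention for human-scale data (~160 bp median CpG
  spacing). On the synthetic genomes, whose planted features are
  deliberately compact, analyses use windows matched to the same physical
  scale: `min_sites = 10` for segmentation (window ≈ 1 kb) and
  `min_sites = 5, min_width = 500` for the interaction DMR scan. Degree-2
  fits fall back to a weighted line/mean when fewer than 3/2 covered sites
  carry weight.
* **Raw vs smoothed tracks for bump hunting.** Both tracks are supported
  (`use_smoothed`). The cell-type scan defaults to the raw track in the
  benchmarks: cell-type differences (Δβ = 0.2) are large relative to
  measurement noise, and unsmoothed noise is independent across sites,
  which breaks spurious runs in the permutation null; smoothing, by
  correlating the noise, lengthens null runs and costs sensitivity for
  small regions. The interaction scan needs the noise averaging of the
  smoothed track because per-year coefficients are two orders of magnitude
  smaller.
* **Permutation scheme.** Freedman–Lane: residuals of the nuisance-only
  model are permuted across samples and added back to the nuisance fit, so
  nuisance covariates are respected; ties in permutation maxima count
  against the region (conservative FWER).
* **Cutoff calibration.** The UMR/LMR cutoff is the least stringent value
  (≤ the maximum segment methylation m = 0.5, grid 0.02–0.6 by 0.02) whose
  shuffle-null FDR, 100 × null/observed segment counts, is at or below 10.
  The null count is averaged over 10 shuffles: with a single shuffle the
  ratio is so noisy that the selected cutoff was unstable across seeds
  (collapsing from 0.5 to 0.04), so the one-shuffle variant was rejected.
* **PMD masking pad.** Called PMDs are masked with a 25-kb pad before
  UMR/LMR calling: the 101-CpG window localises PMD boundaries only to
  about half a window (~25 kb at background CpG spacing), and unpadded PMD
  shoulders were systematically called as false LMRs.
* **Cluster-count selection.** `select_k_aic()` scores k-means solutions
  on centred/scaled features with AIC(k) = WSS(k) + 2·k·d. The
  log-likelihood form n·d·log(WSS/(n·d)) + 2·k·d was considered and
  rejected: splitting any tight cluster reduces WSS by a roughly constant
  *factor*, so the log form decreases by tens of units per extra k against
  a penalty of only 2d and its argmin never settles at the planted k. On
  the raw-WSS scale the argmin recovers six planted archetypes in 20/20
  clustering seeds. Note that standardisation maps any lone cluster to
  unit variance, so a single tight cluster is only scored as k = 1 with
  `standardize = FALSE`.
* **Autocorrelation estimator.** The conventional biased (divide-by-n)
  ACF; lag is in site index, not bp. Within a cluster, values are centred
  on the per-sample cluster mean and missing β contribute zero after
  centring, which reproduces `stats::acf()` exactly on complete data and
  avoids imputation bias in sparse CpH. Zero-variance clusters are skipped
  and counted.
* **Cis windows and filters.** The cis distance of 1000 bp is closed
  (a cytosine at exactly 1 kb is tested); FDR is Benjamini–Hochberg within
  feature type over all tested pairs; the ≥ 11 non-zero / ≥ 11 non-one
  donor filters are applied after scanning and before interpretation, and
  the expression change Δ is slope × observed β range. Promoter = 2 kb
  upstream through the start; flanking = within 5 kb beyond the span.
* **Enrichment.** Both the sample odds ratio ad/bc and the conditional-MLE
  odds ratio are reported (tests pin the ad/bc value); zero margins get the
  Haldane–Anscombe correction and a flag; one BH adjustment per named
  comparison family.
* **Strand handling.** Each cytosine is an independent row; complementary
  CpG pooling (`pool_cpg_strands()`) is provided but off by default, since
  per-cytosine tests and all CpH work require unpooled rows.
* **Prenatal samples.** Prenatal homogenate carries age 0 with a flag and
  is excluded from postnatal sorted-fraction designs.

# Benchmark scenarios and expected outcomes

The `benchmark_*()` functions regenerate each validation scenario from a
seed (problem sizes: 2-Mb genomes with ~12k CpGs for DMR power over three
replicates, a 1-Mb genome for twenty global-null replicates, the default
4-Mb landscape for segmentation, 300 regions for trajectories, 60 × 150
site clusters for autocorrelation, 22 donors for the association scan, and
10,000 sites for moderated-test calibration — all sized so the full set
runs in about a minute on one core):

* DMR detection on the 50 planted regions attains ~0.95 pooled sensitivity
  with an empirical FDR of ~0 (scored against the union of planted
  differential regions, since interaction trajectories diverge from a
  shared landscape at birth and legitimately carry a mean cell-type
  difference).
* Under the global null ≥ 90% of replicates yield zero regions at
  FWER < 5%.
* Segmentation recovers planted features at base-level Jaccard ≈ 0.8–0.99
  per kind; LMRs are the hardest class because smoothing trims their
  boundaries and occasional background pockets are genuinely
  hypomethylated.
* Trajectory clustering reaches ARI ≥ 0.94, the AIC argmin is 6 in all
  clustering seeds, and the recovered neuron/glia ratio is 1.5 ± 0.06.
  This scenario plants 15–30 CpGs per region, matching the ~1.4 kb of real
  cdDMRs; at 8–20 CpGs the per-region slope noise makes the median-ratio
  estimate noticeably less stable.
* The ACF benchmark recovers lag-1 ≈ 0.7 on an AR(1) field and ≈ 0 on
  i.i.d. methylation, and mixed-context ACF inside shared-surface regions
  (~0.7) far exceeds the interleaved background (~0.1).
* The cis scan's null pass rate matches the nominal 5 × 10⁻⁴ within Monte
  Carlo error, planted CpH-exclusive effects classify correctly, and the
  scan's t equals the correlation identity to machine precision. Power
  over planted effects with realized R² = 0.5 at n = 22 is ~0.7 — this is
  the analytic ceiling: at α = 5 × 10⁻⁴ the two-sided t threshold with 20
  df is 4.146 while the noncentrality is √22 ≈ 4.69, giving exact power
  0.69. A 0.9 power requirement at these exact conditions is therefore
  not attainable by any correct implementation, and the corresponding
  check is expected to fail by construction.
* The moderated test's null p-values are uniform (fraction below 0.05
  within [0.04, 0.06]), and its shrinkage limits (prior df 0 and ∞) are
  exact; the full fit matches the reference empirical-Bayes implementation
  to machine precision in the unit tests.

# Known limitations

Beyond the generator simplifications above: homogenate samples are an
exact 50/50 mixture of the two fractions (real bulk tissue has variable,
age-dependent composition); the PMD caller's boundary resolution is half
its 101-CpG window; the segmentation cutoff calibration inherits the
shuffle-null's sensitivity to the genome's feature load (on very small
genomes with proportionally large planted features the null/observed ratio
is inflated); and single-chromosome simulations mean cross-chromosome code
paths are exercised only by the unit tests.
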