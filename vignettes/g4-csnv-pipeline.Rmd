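---
title: "Quantifying the spatial association of G-quadruplexes with cancer SNVs"
author: "g4snv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial association of G-quadruplexes with cancer SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4snv)
```

## The scientific question

G-quadruplexes (G4s) are four-stranded DNA secondary structures formed by
stacked guanine quartets in G-rich sequence. They stall replication forks,
nucleate R-loops and attract error-prone repair, and are therefore
candidate drivers of localized genomic instability. This package
implements a quantitative pipeline for asking whether somatic
single-nucleotide variants observed in cancer exomes (cSNVs) accumulate
near G4 loci, whether that accumulation scales with local G4 content,
whether it is confounded by GC content, and whether a patient's exposure
to G4-rich mutated regions predicts survival. Common population variants
(dbSNVs, minor allele frequency above 1%) serve as the contrast class
throughout: they share the genomic substrate but not the somatic
mutational process.

Every stage is exercised end-to-end on synthetic studies with *planted*
structure, so each statistical claim the pipeline makes can be checked
against known ground truth.

## Coordinate conventions

All intervals are 0-based half-open (BED dialect); SNVs are length-1
intervals. The signed distance of a query to its closest reference follows
`bedtools closest -d` gap semantics: 0 on overlap or book-ended contact,
otherwise the number of base pairs strictly between the closest edges.
The sign is taken in reference-genome orientation — negative when the
query lies 5' (upstream) of the reference, positive when 3' (downstream)
— with an optional mode that flips the sign at minus-strand references.
Ties go to the genomically leftmost reference, making results
deterministic. Chromosome names compare as exact strings.

Window tiling follows the `bedtools makewindows` dialect (fixed-end tiles
with a truncated final tile; sliding tiles truncated at the region end),
so window counts line up with window sets prepared by that tool.

## The analysis chain

1. **Cohort preprocessing.** cSNVs coinciding with a dbSNV coordinate are
   removed (germline contamination); cancer types with fewer than 10
   patients are excluded (strictly fewer — exactly 10 is kept). The
   accounting is conserved: input = germline-removed + type-excluded +
   retained.
2. **Window construction.** Analysis windows (default 5 kb, fixed-end)
   are tiled over genes extended by a 2 kb flank (5 kb optional). A
   window is dropped when it overlaps no exon or when the gap between
   consecutive exons overlapping it exceeds the window size. Only
   features inside exonic sequence are counted, and windows with more
   than 15 G4s (strictly more) are removed as statistically thin.
3. **Distance metaprofiles.** Signed distances of every SNV to its
   closest G4 are binned (default ±5000 bp, 50 bp bins) and the binned
   density is fitted with a single Gaussian
   `a · exp(−(x−μ)²/2σ²)` by Levenberg–Marquardt least squares,
   initialised from the empirical moments. The positional 95% interval is
   `μ ± 1.96σ`; comparing two fits yields the fold-compression
   `σ_B/σ_A`. The fit is on the binned density, not a maximum-likelihood
   fit to raw distances, because the object of interest is the shape of
   the profile; μ and σ are invariant to the normalization choice
   (`unit_area` vs `max_one`).
4. **Window enrichment.** Windows are stratified by G4 content (0, 1+,
   10+, or per exact count); Welch's two-sample t (the unequal-variance
   form of the independent t-test) compares the zero stratum against the
   others, with a chi-squared test on SNV presence/absence as the
   secondary test. The per-window Pearson correlation and the first-order
   partial correlation controlling for GC fraction
   (`r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))`, t-test on n−3
   df) separate the G4 effect from base composition.
5. **Incomplete categorical bootstrapping.** Window counts per G4
   category are wildly unbalanced, so each category contributes exactly
   `N` points to the regression: each point is the mean of `I` windows
   resampled with replacement from that category. Averaging shrinks
   within-category variance like `s²/I`, so as `I` grows the fit
   converges to the regression through the category means and r² rises
   toward its structural value. The sweep runs `I` from `i_step` to
   `i_max` over several cycles; three presets bundle the published
   parameter lists (250/500/1000 permutations, 10/20/50 cycles, steps
   10/5/1). The x-value is the raw G4 count, not a category index.
   Analytic OLS standard errors are not valid on resampled points, so
   quantiles over cycles summarise uncertainty.
6. **Patient-level statistics.** For each patient, windows holding at
   least one of their cSNVs define the exposure set: the G4-average is
   the mean G4 count over that set, the normalized G4-average divides by
   the summed G4 count (note this equals 1/k for k selected windows
   whenever the sum is positive — the normalization is a window-count
   penalty), and the cSNV-average is the mean per-window cSNV count.
   Intra-cancer heterogeneity is the group sd divided by the group mean.
7. **Survival.** Patients who died of their cancer (event) or remained
   alive (censored) form the cohort; non-cancer deaths and incomplete
   records are dropped. Cox's proportional-hazards model is fitted on the
   G4-average and cSNV-average by partial-likelihood maximisation with
   the Breslow treatment of ties (Efron available); covariates enter
   unstandardised so a coefficient reads as log-hazard per one-unit
   increase. Both the coefficient and the hazard ratio are reported,
   since "relative hazard" phrasing is ambiguous between the two scales.
   Model discrimination is Harrell's concordance over comparable pairs.

## The synthetic-study generator

`synthetic_config()` fixes the study conditions; `simulate_study()` draws
a complete dataset deterministically from the seed.

* **Genome and genes.** Random DNA at a configurable GC fraction
  (default 0.5); non-overlapping genes with tiled exons
  (default 60 genes, 8 exons of 1500 bp, 500 bp introns, on 2 chromosomes
  of 2 Mb).
* **G4 map.** G4s (30 bp) placed inside exons. A clustering knob sends a
  chosen fraction of G4s into a "cancer" gene class; the default
  (41.2% of G4s into 20% of genes) plants a 2.8-fold per-gene enrichment
  in cancer genes.
* **SNV cohorts.** A two-layer model. Per SNV, with a per-patient
  association propensity (Beta-distributed around `assoc_fraction`,
  default 0.5) the SNV anchors to a G4 and is offset by a Gaussian draw —
  cSNVs downstream (+200 ± 150 bp), dbSNVs upstream with a broader
  spread (−1300 ± 780 bp; the anchor is the G4 end for non-negative
  offsets and the start for negative ones, so the signed nearest-distance
  equals the rounded draw when G4s are sparse). Otherwise the SNV is
  background, allocated to exons in proportion to the planted window rate
  `a + b · g4_count` (defaults a = 2, b = 3) for cSNVs and uniformly for
  dbSNVs. Two scales are planted by two mechanisms because a single
  mechanism cannot fix the offset profile and the window-level line
  independently. The σ ratio 780/150 = 5.2 mirrors the fold-compression
  scale the method is meant to resolve.
* **Survival.** Event times are exponential with hazard
  `h₀ · exp(β · G4-average)` (defaults h₀ = 0.01, β = 0.32), with
  independent exponential censoring calibrated to a target censored
  fraction (default 30%), a small rate of non-cancer deaths (5%) and
  missing records (2%) to exercise the cohort filter.

Two presets cover two regimes. The *default* preset uses clustered G4s,
which is what the enrichment, bootstrap and gene-class stages need. The
*spatial* preset (`synthetic_config_spatial()`) is a single exon-dense
10 Mb chromosome with 300 G4s at a minimum spacing of 15 kb — sparse
enough that every planted SNV's nearest G4 is its anchoring G4, which is
the condition under which the Gaussian offset parameters are identifiable
from the nearest-distance profile. The spacing keeps the placement well
below the random-sequential-adsorption jamming density, and the maximum
plausible offset (≈4 kb) is well inside the half-spacing.

**What the generator does not emulate:** trinucleotide mutational
signatures, chromatin state, replication timing, copy-number structure,
non-uniform gene architecture, or imperfect G4 maps. Passing tests
therefore demonstrate that the *statistical machinery* recovers planted
truth under its own assumptions — not that real cancer genomes satisfy
those assumptions.

## Numerical choices and edge cases

* Gaussian fitting requires at least 5 non-empty bins; an all-in-one-bin
  profile is rejected with a pointer toward smaller bins. If the
  Levenberg–Marquardt path ends on a rank-deficient Jacobian (symmetric
  multimodal profiles do this), a direct Nelder–Mead RSS minimisation
  supplies the parameters; any fit explaining less than half the profile
  variance is flagged `poor_fit` and warned about.
* Profile bins are uniform over `[−range, +range)`; out-of-range
  distances are excluded from the density but counted in `n_total`.
* The germline filter matches on coordinates only (the paper-style
  intersection), not alleles.
* Windows with zero GC base pairs are flagged and excluded from
  GC-normalised analyses rather than silently producing infinities.
* PQS scanning is greedy left-to-right (maximal G-runs, minimal loops,
  non-overlapping hits); `N` never matches inside a hit unless
  explicitly allowed into loops. The consensus motif
  `G₃₊N₁₋₇G₃₊N₁₋₇G₃₊N₁₋₇G₃₊` is the package's PQS source; score-based
  scanners that tolerate imperfections (bulges, long loops) find
  substantially more loci and are deliberately out of scope.
* Bootstrap cycle seeds derive deterministically from the config seed, so
  sweeps are exactly reproducible; sampling is with replacement, and a
  without-replacement mode exists for categories larger than `I`.
* The Cox fit refuses cohorts with fewer than 2 events or constant
  covariates; monotone-separable toy data (risk order equal to time
  order) have no finite maximiser and are excluded from oracle
  comparisons.

## Design decisions taken where the methods were open

* **Signed distances.** The methods describe absolute distances, but the
  results report upstream/downstream asymmetry, which requires a sign.
  We sign in reference-genome orientation by default and expose a
  strand-aware flip, since strand handling is not specified.
* **"Indirect t-test"** is read as the independent two-sample t-test;
  Welch's form is the default because variance heterogeneity across G4
  strata is certain, with Student's pooled form behind a flag.
* **Chi-squared test** is operationalised on the presence/absence
  contingency (SNV = 0 vs ≥ 1 per window) across strata, the table not
  being specified; raw and BH-adjusted p-values are both emitted.
* **Bootstrap output size.** The resampling description reduces each
  permutation to a single average, which yields `N` points per category;
  the `N · I` phrasing elsewhere is not realizable after that reduction
  and is not implemented.
* **Gene G4 content** is reported both raw and per kbp of gene length,
  the normalization target being unspecified.
* **Gaussian scope.** One Gaussian is fitted to the full signed range
  rather than one per side; with a unimodal planted offset this is the
  identified model, and the `poor_fit` flag reports when it is not.
* **Window flank** defaults to 2 kb with 5 kb as an option; which flank
  produced which published figure is not stated.

## Problem sizes used in validation

The bundled validation (test suite and `scripts/acceptance.R`) runs, per
choice, at: 1000 random interval instances (≤ 200 intervals each) against
exhaustive oracles; 50,000 SNVs of each class for Gaussian recovery;
100,000 background SNVs against 50 random 200-bp references for the
flatness control (±6 kb, 2 kb bins — bin width chosen so that expected
counts per bin are ≈1000 and the overlap bin's geometric excess stays
around 10%); 16 G4 categories × 400 windows with Poisson noise for the
bootstrap sweep (250 permutations, 10 cycles, I up to 100); 100,000
observations for partial-correlation recovery; and 3000 patients per
cohort with 100 independent cohorts for Cox coverage. These sizes give
sampling errors comfortably inside the assertion tolerances (e.g. the
Gaussian μ standard error at n = 50,000 is ≈0.7 bp against a ±10 bp
assertion).

## Known limitations

* The nearest-G4 distance identifies the planted offset distribution only
  when G4 spacing is large relative to the offsets; in G4-dense regions
  the profile mixes anchor and non-anchor distances and σ is biased
  downward. This is a property of nearest-distance profiling itself, not
  of the implementation.
* The normalized G4-average collapses to 1/k (k = number of
  cSNV-bearing windows) whenever any G4 is present; it is therefore a
  mutational-burden penalty rather than an independent G4 signal, and
  values above 1 are impossible under this definition.
* Synthetic survival covariates are realised G4-averages; their spread
  in the default study is modest, so the end-to-end Cox fit on the small
  default cohort is illustrative, while parameter-recovery claims are
  validated on the dedicated survival cohort generator.
* The regex PQS scanner is a consensus-motif instrument; its counts are
  not comparable to imperfection-tolerant scanners.

## A minimal run

```{r, eval = FALSE}
library(g4snv)

ds <- simulate_study(synthetic_config(seed = 42))
res <- run_analyze(ds, bootstrap_profile = "small", seed = 1)
res            # fits, correlations, Cox coefficients
tables <- run_report(res)
autoplot(res$profile_csnv, fit = res$fit_csnv)
autoplot(res$sweep_csnv)
```
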