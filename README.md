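# g4snv

Quantifying the spatial association of G-quadruplex (G4) loci with
somatic single-nucleotide variants in cancer cohorts.

## What it is for

G-quadruplexes are four-stranded DNA secondary structures that form in
G-rich sequence, stall replication, nucleate R-loops and attract
error-prone repair — all mechanisms that can concentrate mutations around
them. `g4snv` is an analysis package for genomicists who want to test,
on a cohort of tumor exomes, whether somatic SNVs (cSNVs) cluster near
G4s, whether the local mutation load scales with local G4 content
independently of GC composition, and whether a patient's G4 exposure in
mutated regions carries prognostic information. Common population
variants (dbSNVs) serve as the contrast class throughout.

The statistical core:

* **Distance metaprofiles with Gaussian fits.** Signed distances of SNVs
  to their closest G4 (negative = upstream) are binned and the density is
  fitted with `a·exp(−(x−μ)²/2σ²)`; the positional 95% interval is
  `μ ± 1.96σ`, and the ratio `σ_dbSNV / σ_cSNV` measures how much more
  tightly cSNVs hug G4s (fold-compression).
* **G4-stratified window enrichment.** Exonic feature counts in 5 kb
  gene-anchored windows, Welch t / chi-squared tests across the 0 / 1+ /
  10+ G4 strata, Pearson and GC-controlled partial correlation
  `r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))`.
* **Incomplete categorical bootstrapping.** Each G4-count category
  contributes exactly N points — means of I windows resampled from that
  category — so category-size imbalance cannot dominate the regression;
  sweeping I shows r² converging to the structural category-mean fit.
* **Patient-level G4 statistics and survival.** Per-patient G4-average
  over cSNV-bearing windows (with its normalized variant and the
  cSNV-average), intra-cancer variance (sd/mean), and a Cox
  proportional-hazards model (partial likelihood, Breslow ties) with
  Harrell's concordance.
* **A synthetic-study generator** that plants every effect the pipeline
  estimates — Gaussian offsets (+200 ± 150 bp downstream for cSNVs,
  −1300 ± 780 bp upstream for dbSNVs), a linear window relation
  `E[cSNV | g4 = c] = a + b·c`, a 2.8-fold G4 enrichment in cancer-class
  genes, and a log-hazard coefficient on the G4-average — so every stage
  is validated against known truth.

Native genomic-interval arithmetic (BED I/O, signed closest distances
with bedtools `-d` gap semantics, overlap counting, `makewindows`-dialect
tiling, masked random intervals) and a consensus PQS motif scanner
(`G₃₊N₁₋₇G₃₊N₁₋₇G₃₊N₁₋₇G₃₊`) round out the toolkit.

## Worked example

```r
library(g4snv)

ds  <- simulate_study(synthetic_config(seed = 42))  # complete synthetic study
res <- run_analyze(ds, bootstrap_profile = "small", seed = 1)
res
#> <g4_analysis>
#>   windows: 240 (after G4 cap)
#>   cSNV Gaussian:  mu    69.0  sigma   173.5  CI [-271, 409]
#>   dbSNV Gaussian: mu   -70.4  sigma   458.9  CI [-970, 829]
#>   fold-compression (cSNV vs dbSNV): 2.65
#>   Pearson r (cSNV ~ G4): 0.956;  partial r | GC: 0.956
#>   Cox: beta(G4-average) = 0.168 (HR 1.18, p = 0.283), C = 0.519
```

Reading this: in the default study half of all SNVs are background, so
the fitted centres shrink toward zero relative to the planted offsets,
but the signs (cSNV downstream, dbSNV upstream) and the σ ordering
survive; the Pearson r is essentially unchanged by GC control because the
generator plants no GC confounding; the Cox fit on 300 patients is
underpowered and says so. The stratified table shows the planted
window-level gradient:

```r
res$enrichment_csnv[, c("group", "n_windows", "mean_snv", "median_snv")]
#>  group n_windows mean_snv median_snv
#>      0        25     5.56          5
#>     1+       215    51.26         34
#>    10+         3   312.67        303
```

On the sparse-G4 preset — the regime where the nearest G4 *is* the
anchoring G4 — the planted offsets are recovered almost exactly:

```r
cfg <- synthetic_config_spatial(n_patients = 300, csnv_per_patient_mean = 50000/300,
                                n_dbsnv = 50000, seed = 7)
ds <- simulate_genome(cfg) |> place_g4s(cfg) |>
  place_snvs(cfg, "cSNV") |> place_snvs(cfg, "dbSNV")
fit_gaussian(distance_profile(ds$csnvs, ds$g4s, range = 5000, binwidth = 50))
#> <Gaussian fit>
#>   mu     =    200.9 bp
#>   sigma  =    150.7 bp
#>   95% CI = [-94, 496] bp
#>   r^2    = 0.9999
```

with the dbSNV fit at μ = −1291, σ = 786, i.e. a fold-compression of
5.21 against the planted 780/150 = 5.2. `autoplot()` methods exist for
profiles and bootstrap sweeps, and `tidy()`/`glance()` for fitted
objects. A thin CLI (`inst/cli/g4snv.R`) exposes
`simulate` / `analyze` / `report` subcommands.

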