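# dimerFLIM

Quantifying receptor dimerization in tissue by fluorescence lifetime
imaging, and relating it to patient outcome.

HER2-HER3 is the most mitogenic dimer of the HER/ErbB receptor family and a
drug target in breast cancer, yet standard HER2 immunohistochemistry
measures receptor *abundance*, not dimer *formation*. FLIM-FRET measures
formation directly: when a Cy5-labelled anti-HER2 antibody sits within
~10 nm of an Alexa546-labelled anti-HER3 antibody, energy transfer shortens
the donor's fluorescence lifetime. Comparing the donor lifetime with
(τ_DA) and without (τ_D) the acceptor gives the FRET efficiency

    E = 1 − τ_DA / τ_D,

a per-core dimerization readout that can be dichotomized and carried into
survival models. `dimerFLIM` is for image-analysis and biostatistics
developers who need this chain as tested, reusable components rather than
a one-off analysis: every stage is driven by a synthetic-data generator
with a fully stated generative model, so the whole pipeline is verifiable
without access to patient data.

The package provides:

- **TCSPC simulation** — Poisson photon-count cubes with donor, FRET and
  autofluorescence components, spatial texture and serial-section pairing
  (`decaySimConfig`, `simulateCorePair`).
- **Decay fitting** — per-pixel mono-/bi-exponential Poisson maximum
  likelihood, lifetime maps, lifetime filtering of short-lifetime
  autofluorescence, ROI averaging, FRET efficiency (`buildLifetimeMap`,
  `lifetimeFilter`, `coreFret`).
- **HER network model** — mass-action dimerization equilibrium for the
  simple (HER1-3) and detailed (HER1-4) networks, with an ODE steady-state
  cross-check and 400-patient population simulations reproducing the
  regimes in which dimer level decouples from total receptor expression
  (`equilibriumState`, `steadyStateODE`, `simulatePopulation`,
  `regimeReport`).
- **Cohort statistics** — synthetic proportional-hazards cohorts, ROC with
  Youden-optimal cutpoint, Kaplan-Meier, univariate/multivariate Cox at 5-
  and 10-year horizons, Fisher exact associations (`simulateCohort`,
  `youdenThreshold`, `coxFit`, `runCohortAnalysis`).
- **Pipeline & I/O** — TIFF+JSON cube container, CSV cohort tables, and a
  deterministic end-to-end run with a checksum manifest (`runPipeline`).

## Worked example

Simulate one tissue-core pair with 25% of the donor population FRETing and
20% autofluorescence contamination, then recover the FRET efficiency:

```r
library(dimerFLIM)

cfg <- decaySimConfig(tauDonor = 2.8, tauFret = 1.4, fretFraction = 0.25,
                      autoFraction = 0.2, photonsPerPixel = 800,
                      imageShape = c(64, 64), seed = 7)
pair <- simulateCorePair(cfg)
pair$donor
#> TCSPCCube: 64 x 64 pixels, 256 time bins over 12.5 ns (bin 0.04883 ns)
#>   total photons: 3.276e+06 (mean 799.9 / pixel)

coreFret(pair$donor, pair$donorAcceptor)
#> FretResult: tauD = 2.307 ns (4096 px), tauDA = 2.09 ns (4011 px)
#>   FRET efficiency = 0.0940 (9.40%)
```

The donor map keeps all 4096 pixels; 85 contaminated pixels of the
donor+acceptor map were removed by the lifetime filter (window
[1.2, 4.0] ns). τ_D sits below the pure-donor 2.8 ns because moderately
contaminated pixels stay inside the window; in a contamination-free
acquisition this FRET population would read E ≈ 13.9% (the apparent-mixture
fixed point), so the residual autofluorescence compresses the measured
contrast to 9.4% — which is why the filter's job, asserted in the tests, is
to move the estimate *closer* to truth, and why contamination makes such an
assay conservative rather than anticonservative.

Simulate a 131-patient cohort with a strong dimer→hazard link
(log HR = log 3.91 per SD of log dimer level) and run the full analysis:

```r
tab <- simulateCohort(cohortSimConfig(nPatients = 131,
                                      logHrPerDimerSd = log(3.91), seed = 2))
runCohortAnalysis(tab)
#> CohortReport
#>   FRET threshold: 9.132 (Youden, AUC 0.833); high/low = 45/86
#>   patients: 131 total, 104 complete cases
#>   multivariate Cox, 5yr horizon:
#>     FRET high vs low: HR 9.00 (2.64-30.73), p = 0.000453 [n = 104]
#>   multivariate Cox, 10yr horizon:
#>     FRET high vs low: HR 8.22 (2.98-22.65), p = 4.68e-05 [n = 104]
```

The threshold is chosen by ROC/Youden against event-within-10-years, the
multivariate Cox model adjusts for HER2 IHC status, HER3 localisation,
ER/PR, size, grade and nodal group on complete cases, and the FRET term
stays independently prognostic — the property the pipeline is built to
measure. (At n = 131 the point estimate of the high-vs-low HR is noisy;
its calibration is quantified in the acceptance checks below.)

Receptor-network regimes (Pearson r of the HER2-HER3 dimer level against
total HER2 / HER3 across 400 simulated patients):

```r
print(regimeReport(seed = 1)[, 1:3], digits = 2)
#>            regime rPearsonHER2 rPearsonHER3
#> 1         regimeC        0.105        0.139
#> 2         regimeD        0.211        0.183
#> 3        her2Over        0.068        1.000
#> 4        her3Over        0.995        0.083
#> 5        isolated        0.695        0.682
#> 6 regimeCDetailed        0.508        0.539
```

An abundant competing receptor (regimes C/D: HER1 ≫ HER2, HER3) erases the
correlation between the dimer and its constituents' totals — the network
explanation for why HER2-HER3 dimer levels need not track HER2 expression —
while overexpressing one partner couples the dimer tightly to the *other*
partner only. The isolated-dimer baseline shows the strong correlation
expected when binding is an isolated event.

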