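---
title: "Methods: FLIM-FRET dimer quantification, receptor-network equilibrium and survival modelling"
author: "dimerFLIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FLIM-FRET dimer quantification, receptor-network equilibrium and survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`dimerFLIM` implements a complete, testable analysis chain for quantifying
HER2-HER3 receptor dimerization in tissue by FLIM-FRET and relating it to
patient outcome:

1. a **synthetic-data generator** for TCSPC photon-count cubes and patient
   cohorts, with fully stated distributions;
2. **per-pixel decay fitting** by Poisson maximum likelihood, lifetime
   filtering against autofluorescence, and ROI-level FRET efficiency;
3. a **mass-action equilibrium model** of the HER1-4 dimerization network
   with population simulation;
4. a **survival layer**: ROC/Youden dichotomization, Kaplan-Meier curves,
   univariate and multivariate Cox models, Fisher exact associations;
5. an **end-to-end pipeline** with a reproducibility manifest.

Patient imaging and outcome data of the kind this pipeline targets are not
publicly deposited, so the package is organized around its generator: every
stage is exercised and validated on synthetic data whose generative model is
written down completely. What passing tests do and do not imply about real
tissue data is discussed at the end.

# TCSPC forward model

A FLIM acquisition records, per pixel, a histogram of photon arrival times
over `nBins` equal bins spanning a window $T$ (default 256 bins over
12.5 ns, the standard frame of an 80 MHz pulsed laser; acquisition hardware
reports bins, not window length, so $T$ is configurable). A fluorophore
population with lifetime $\tau$ contributes to bin $[t_{lo}, t_{hi})$ with
probability

$$p_{bin}(\tau) = \frac{e^{-t_{lo}/\tau} - e^{-t_{hi}/\tau}}{1 - e^{-T/\tau}},$$

i.e. an exponential decay truncated to the window. Counts are Poisson with
expectation `photons * sum_k w_k p_bin(tau_k)` for mixture weights $w_k$
(photon fractions). The instrument response is a delta function by default,
which keeps every fitting oracle closed-form; a Gaussian response of width
`irfSigma` can be convolved in for robustness studies. Deconvolution of a
measured instrument response is out of scope.

A simulated tissue core mixes three components per pixel:

* the unperturbed donor, lifetime `tauDonor` (default 2.8 ns, the
  Alexa546 band);
* a FRET-shortened donor, lifetime `tauFret` < `tauDonor`, in a fraction
  `fretFraction` of the donor population;
* an autofluorescence contaminant, lifetime `tauAuto` (default 0.6 ns),
  contributing a fraction `autoFraction` of total photons image-wide.

Spatial structure: per-pixel photon budgets follow a smooth log-normal
texture (log-sd `sigmaTexture`, default 0.3) obtained by bilinear
interpolation of coarse lattice noise, so intensity thresholding is
exercised. The autofluorescence intensity follows its **own, much patchier**
field (log-sd `sigmaAuto`, default 1.5): in fixed tissue, autofluorescence
concentrates in stromal pockets (collagen, elastin) rather than scaling
with the specific stain. This patchiness is what lifetime filtering
exploits — without it, every pixel would carry the same contamination
fraction and no per-pixel filter could help. Both fields are normalized to
mean 1, so the image-wide expected count per pixel stays `photonsPerPixel`.

The donor and donor+acceptor members of a core pair are **independent
draws sharing tissue-level parameters** — they model serial sections of the
same core, which are different physical slices; no pixel registration
exists or is simulated. Per-core photon budgets are not reported for the
reference acquisitions ("100 frames over 300 s"), so the default
(several hundred photons per pixel) is a package choice surfaced in the
configuration.

# Decay fitting

Counts are photons, and with 256 bins the per-bin counts are small, so
fitting maximizes the **Poisson likelihood**, not least squares. For the
mono-exponential model the amplitude profiles out (its MLE is the total
count), leaving a multinomial likelihood over a truncated-geometric bin
distribution whose score equation reduces to matching the model's mean bin
index

$$m(\rho) = \frac{\rho}{1-\rho} - \frac{n\rho^{\,n}}{1-\rho^{\,n}},
\qquad \rho = e^{-\Delta t/\tau},$$

to the observed photon-weighted mean bin index. The MLE is therefore the
root of a monotone one-dimensional equation, solved by 64 bisection steps
on $\log\tau$ over a fixed bracket — deterministic, tolerance-free in the
user-facing sense, and fast enough to fit every pixel of a frame at once
through the sufficient statistic. Histograms whose mean arrival time falls
outside the attainable range (e.g. everything in the first bin) hit the
bracket bound and are returned `converged = FALSE`, which makes the pixel
invalid downstream. Pixels need `minPhotons` (default 100) to be fitted.

The bi-exponential fit maximizes the same multinomial likelihood over
(short lifetime, long lifetime, photon fraction) with BFGS from fixed
starting values derived from the mono fit. Three guards keep the
decomposition honest: a fitted fraction below 0.01 falls back to the mono
fit; lifetimes within 5% of each other are ill-conditioned and collapse to
mono (flagged `degenerate`, still converged); and a second component is
only reported when it improves the Poisson log-likelihood over the nested
mono model by more than `max(1, 1e-6 N)` — on the flat ridge of a
near-mono histogram the two-component decomposition is arbitrary even when
the lifetimes differ numerically.

# Lifetime filtering and FRET efficiency

The reference analysis suppresses autofluorescence with a lifetime
filtering algorithm whose internals are published separately and are not
restated here; this package implements a clearly labelled two-stage
surrogate. **Window mode** (default): fit each pixel mono-exponentially and
invalidate pixels whose apparent lifetime leaves an acceptance window
(default [1.2, 4.0] ns, bracketing the donor band — contaminant-dominated
pixels fit short and are removed). **Two-component mode**: fit each pixel
bi-exponentially with the short component bounded to a contaminant band
(default [0.2, 1.2] ns) and report the long component. Window mode removes
contaminated pixels; it cannot correct pixels with moderate contamination,
which pull the ROI mean down but stay inside the window. The paired-seed
test asserts only the property that matters operationally: the filtered
ROI estimate is closer to the clean-tissue truth than the unfiltered one.

ROI lifetime is the **photon-weighted mean** of valid pixel lifetimes
(pooling all ROI photons implies photon weighting; plain averaging is
available via `weighting = "uniform"` since the reference method says only
"average lifetime"). FRET efficiency is

$$E = 1 - \tau_{DA}/\tau_D$$

with $\tau_D$ from the donor-only section and $\tau_{DA}$ from the
donor+acceptor section. Because the two sections are independent tissue
samples, sampling noise can produce $\tau_{DA} > \tau_D$; negative $E$ is
**reported and flagged, never clipped**, so the downstream ROC sees the
full scale. In a mixed population (fraction $f$ FRETing at $\tau_F$), the
mono fit estimates the apparent lifetime $\tau^\ast$ solving
$m(\tau^\ast) = (1-f)\,m(\tau_D) + f\,m(\tau_F)$ — the tests use exactly
this closed-form fixed point as the oracle for mixed-decay recovery.

# The HER dimerization network

Receptors $E_1..E_4$ dimerize pairwise by mass action: at equilibrium
$[E_{ij}] K_{ij} = [E_i][E_j]$, with the statistical-factor convention
$[E_{ii}] = [E_i]^2/K_{ii}$ and conservation counting $2[E_{ii}]$. The
**simple model** is the 3-receptor reduction (pairs E12, E13, E23 — HER2-HER3
dimerization plus competitive binding of both partners to HER1); the
**detailed model** enables all 10 homo- and heterodimer pairs of HER1-4
(a configuration toggle can disable questioned pairs such as the
kinase-dead HER3 homodimer). The model is a closed binding system: ligand
binding, synthesis/degradation fluxes, trafficking and downstream signalling
are deliberately excluded — the argument being made is purely a binding-
equilibrium one.

Substituting the equilibrium relations reduces the steady state to the free
concentrations: $f_i\,(1 + \sum_{j\ne i} f_j/K_{ij} + 2f_i/K_{ii}) = t_i$.
The solver runs a damped fixed-point iteration (geometric damping,
globally convergent for this monotone system) followed by Newton
refinement, and **errors out rather than returning silently** if the
conservation residual cannot reach 1e-12 relative; every
`EquilibriumState` object re-asserts conservation and equilibrium residuals
in its validity method. An independent **dynamic route** integrates
$d[E_{ij}]/dt = k_{on} f_i f_j - k_{off,ij}[E_{ij}]$ with `deSolve` from
all-monomer initial conditions until the mass-action residual of every pair
passes the same invariant; algebraic and dynamic routes are cross-checked
against each other on random 3- and 4-receptor instances to 1e-6 relative.

The exact rate values and abundance distributions behind the published
population simulations are in supplementary material not available to this
implementation, so the defaults are package choices, stated once: all
enabled pairs share $K_d = 1$ in normalized concentration units, abundances
are truncated normals (rejection sampling, no point mass at zero) with
CV = 0.3, and populations have n = 400. A pre-build calibration confirmed
these defaults reproduce the qualitative regime structure:

* **Abundant competitor** (HER1 100x HER2 ~ HER3, and the variant with
  HER2 scarce): the HER2-HER3 dimer level decorrelates from both totals
  (|r| well under 0.3). Mechanism: both free partners are suppressed by the
  shared factor $1/(1+f_1/K)$, so $[E_{23}]$ inherits a $1/t_1^2$
  dependence on the fluctuating competitor that dominates its variance.
* **HER2 overexpression**: $[E_{23}]$ saturates in HER2 and tracks the
  scarce partner almost perfectly (r > 0.9 with total HER3, near zero with
  total HER2); HER3 overexpression mirrors it.
* **Isolated dimer** (only E23 enabled, comparable abundances): strong
  positive correlation with both totals. Note a structural ceiling: with
  $[E_{23}]$ depending symmetrically on two *independent* totals, the
  Pearson correlation with either cannot exceed $1/\sqrt{2} \approx 0.707$
  (for the bilinear weak-binding limit it is $1/\sqrt{2 + cv^2}$, and
  saturation only lowers it). Observed values sit at 0.66-0.71 depending on
  seed — "strong" here means near the ceiling, not near 1.
* **Detailed model, abundant HER1**: correlations drop relative to the
  isolated baseline but less sharply (r ~ 0.5) than in the simple model,
  because the HER1 homodimer buffers free HER1 ($f_1 \propto \sqrt{t_1}$,
  halving its competitive elasticity). Reproducing the near-complete
  decorrelation reported for the detailed model would require weaker
  homodimerization or wider abundance distributions than these defaults;
  with all 10 pairs at a common $K_d$ the package reports the qualitative
  ordering rather than forcing the magnitude.

Correlations are Pearson on raw concentrations (matching how such
simulations are scatter-plotted), with Spearman reported alongside.

# Synthetic cohorts and the survival layer

Each simulated patient receives receptor abundances (default regime:
abundant HER1, the decorrelated scenario), a HER2-HER3 dimer level from the
detailed network, and:

* **FRET efficiency** = `fretMean + fretPerSd * z + noise`, where `z` is
  the standardized log dimer level — a stated monotone map; defaults
  (7.7% mean, 3.2%/SD, 1.5% noise) put the cohort mean near 7.7% and the
  spread near the reported 0-22% range. The log-scale standardization
  keeps simulated hazards bounded; the latent `z_dimer` column is kept in
  the output so effect recovery can be tested against the truth.
* **HER2 IHC** scored 0-3 by cutpoints on total HER2 (defaults give ~17%
  positive = scores 2-3), with 11% not assessable; **other covariates**
  (ER 84% positive, PR 59%, size >20 mm 60%, grade 3 50%, nodal groups
  39/44/16%, HER3 localisation 50/26/20%) are drawn independently from
  marginals matching a reference TMA cohort table. Joint dependence beyond
  HER2<-total-HER2 and hazard<-dimer is deliberately not invented.
* **Outcome**: event time ~ Exp(`baselineHazard * exp(beta z)`), censoring
  ~ Exp(`censoringRate`) capped at `followupCap`. Defaults (0.035/yr,
  log 2 per SD, 0.05/yr, 15 yr) put the median event-or-censoring
  follow-up near 7.6 years and the 131-patient event count in the
  mid-thirties, matching the reference cohort's scale.

The analysis layer mirrors standard practice: the ROC outcome label is
*distant metastasis (or disease-specific death) within the horizon*
(default 10 years); patients censored earlier without an event carry no ROC
label but stay in every survival model. The Youden-optimal threshold scans
all midpoints between sorted unique scores, maximizes sens + spec - 1 and
breaks ties toward the lower threshold; dichotomization is strict `>` at
the threshold (the boundary value is "low" — the reference tables write the
boundary ambiguously, so the convention is documented here). Kaplan-Meier
and Cox fits go through the `survival` package (Efron ties, Wald 95% CIs);
the multivariate model is complete-case; univariate models use all rows
available per covariate; no multiple-testing adjustment is applied
(matching the reference analysis). Fisher tests use the package's own
hypergeometric enumeration for 2x2 tables (cross-checked against
`stats::fisher.test`), and the generalized exact test for multi-level
covariates.

One calibration subtlety: selecting the threshold by ROC on the *same*
cohort that is then tested inflates the FRET term's type-I error — that is
a property of the exploratory-threshold design, not of the Wald test. The
null-calibration check therefore fixes the threshold at the generator's
FRET mean, isolating the test's size; the power check uses the full
auto-threshold pipeline as deployed.

# Numerical and design choices

* Mono-MLE bisection: 64 steps on $\log\tau$ over [bin width / 50,
  50 x window]; bounds hit => not converged. Bi-exponential BFGS:
  `reltol = 1e-12`, fixed starts from the mono fit.
* Equilibrium: fixed point (<= 400 damped iterations) + Newton
  (<= 50, step-halving to stay positive), target residual 1e-12 relative,
  hard failure above 1e-8. Zero totals are solved exactly (free = 0).
* Tie-breaks: Youden ties toward the lower threshold; Cox ties by Efron.
* Degenerate inputs: zero-variance populations report NA correlations with
  an explanatory note; all-censored cohorts refuse the Cox fit ("no
  events"); empty lifetime maps raise "no evaluable pixels"; monotone
  likelihood in Cox is flagged `unreliable`.
* Seed discipline: every generator takes an explicit integer seed; the
  pipeline derives stage seeds from the master seed by a documented
  additive rule modulo 2^31 - 1, and its manifest records seeds and
  per-file checksums, making runs reproducible bit-for-bit.
* Problem sizes: the validation suite uses 200 fit replicates at 1e4
  photons for estimator calibration, 100 paired seeds at 32x32 px for the
  filter benefit, 100 random network instances for solver cross-checks,
  populations of 400, and cohort studies of 200 replicates at n = 500
  (effect) and 500 replicates at n = 300 (null); the demonstration
  pipeline images 20 cores at 64x64 px within a 300-patient cohort. These
  sizes were chosen so the full suite runs comfortably on a laptop while
  keeping Monte Carlo standard errors small relative to the asserted
  margins.

# What the synthetic data do not capture

The generator emulates Poisson photon statistics, lifetime mixing,
spatially patchy contamination, serial-section independence and
proportional-hazards outcomes. It does **not** emulate: a measured
instrument response and detector afterpulsing; donor/acceptor spectral
bleed-through; acceptor photophysics; staining heterogeneity correlated
with pathology; informative censoring; or correlations among
clinico-pathological covariates. Passing tests therefore demonstrate that
the estimators and the analysis chain are correct and calibrated *under the
stated generative model*, not that the biological effect sizes would be
reproduced in tissue. The network model likewise supports a qualitative
claim — competition in a dimerization network can erase the correlation
between a dimer and its constituents' totals — not quantitative rate
inference.
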