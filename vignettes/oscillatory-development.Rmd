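---
title: "Modelling developmental change in resting-state oscillatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental change in resting-state oscillatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscdev)
```

## The analysis problem

Between adolescence and adulthood, resting-state cortical oscillations
reorganise in two distinct ways: the *phase coupling* between regions in
the slow theta range (5–9 Hz) weakens, most strongly for anterior
(frontal) regions, while *spectral power* shifts from slow delta
oscillations (1–3 Hz) toward faster beta oscillations (14–16 and
22–26 Hz). `oscdev` implements the full analysis chain that quantifies
these changes from source-space region-by-time recordings over a cortical
parcellation, together with a synthetic cohort generator that plants
known effects so that every stage can be validated by parameter recovery
and null calibration.

The two core measurements are:

* **Phase-locking value (PLV).** For regions $a, b$ at frequency $f$,
  $\mathrm{PLV} = \frac{1}{N}\left|\sum_{n=1}^{N}
  e^{i(\theta_a(n) - \theta_b(n))}\right|$, the modulus of the mean unit
  phasor of the phase difference. PLV is 1 when the two signals keep a
  constant phase separation and falls to a chance floor
  $\sqrt{\pi/(4N)}$ for unrelated phases. The recording is cut into
  non-overlapping 3-s epochs (100 epochs for a 300-s recording) and each
  epoch is tapered with the first three discrete prolate spheroidal
  (DPSS) sequences at time–bandwidth product 2; the $N$ phase samples
  are the cross-spectral phasors of each (epoch × taper) combination, so
  $N = n_\mathrm{epochs} \times 3$. Frequencies are analysed at 1–49 Hz
  in 1-Hz steps.
* **Relative power.** Welch's method on 3-s Hamming-windowed segments
  with 50% overlap; periodogram bins are aggregated into 1-Hz intervals
  by summing bins whose centre falls in $[f-0.5, f+0.5)$, then each
  region's spectrum is normalised by its total power over 1–49 Hz, so
  relative power is a proportion and every region's values sum to 1.

Both estimators are hand-implemented (no installed package provides DPSS
tapers or Welch spectra in R); the DPSS tapers come from the standard
symmetric tridiagonal eigenproblem, and both were checked against
independent reference implementations during development.

## Age models

* **Global mixed model.** Per subject and frequency, PLV is averaged
  over all unordered region pairs. `fit_global_interaction()` fits a
  linear mixed model by maximum likelihood with per-subject random
  intercepts, treating frequency as a 49-level categorical factor, and
  tests the age × frequency interaction by a likelihood-ratio test
  (48 interaction parameters, so the LRT has 48 df). Frequency is
  categorical because a continuous frequency term would give a 1-df
  test, inconsistent with testing *where* in the spectrum age acts.
* **Per-frequency regressions.** OLS of the global metric on age at each
  of the 49 frequencies (motion as covariate by default), corrected with
  Benjamini–Hochberg FDR across frequencies. There is no single
  conventional covariate set for the global analysis, so it is an
  argument.
* **Edgewise band regression.** For each of the $n(n-1)/2$ region pairs,
  band-averaged PLV (theta by default) is regressed on age. The full
  nuisance set is head motion, the band relative power of each endpoint
  region, their product, the log powers (floored at $10^{-12}$, since
  relative power can be numerically tiny), and the interaction of the
  log powers. We use $(\log p_i)(\log p_j)$ for the log-interaction
  nuisance term: the alternative reading $\log(p_i p_j)$ is exactly
  collinear with the two log main effects and would make every edge
  design rank-deficient. Rank deficiency is still detected and reported
  with the offending columns.
* **Regional composites.** The symmetric matrix of edgewise age betas is
  summed down its columns (diagonal excluded), giving one composite rate
  of developmental change per region; regionwise power-on-age betas are
  summed over each band's 1-Hz bins (8 bins for the split beta band).

## Anatomical gradients

`gradient_fit()` regresses the per-region composite effect on an MNI
coordinate (+y anterior), controlling for each region's mean Euclidean
distance to all other regions (a proxy for distance-dependent coupling
artifacts) and its surface area. Lateral gradients are fit per
hemisphere on $|x|$ so that "medial" is a consistent direction (signed
x is available). The frequency-resolved profile repeats the edgewise
regression in 5-Hz bins (1–5, 6–10, …, 46–49 Hz; the last bin is 4 Hz
wide) and compares each bin's coordinate slope $\beta_2$ with the
reference bin's $\beta_1$ (6–10 Hz by default, where the developmental
decoupling is strongest) via

$$z = \frac{\beta_1 - \beta_2}{\sqrt{SE_{\beta_1}^2 + SE_{\beta_2}^2}},$$

with $|z| > 1.645$ corresponding to one-tailed $p < 0.05$. The reference
is configurable (5–9 Hz is the band where the age effect itself lives;
6–10 Hz is the profile bin that contains it).

## Network-level statistics

Regions carry one of 13 functional network labels. The heatmap cell for
networks $A, B$ is the mean edgewise age beta over all edges with one
endpoint in each (within-network cells use the $i<j$ pairs inside the
network and are undefined for networks with fewer than two members).
The one-way ANOVA groups the per-region composite effects by network
(13 groups over 333 regions give df 12, 320) with Tukey HSD post hoc
contrasts; an edge-level variant is available because the grouping unit
is ambiguous in the field's usage. The association-vs-processing
contrast is a pooled-variance two-sample t test on within-network edge
betas, with association = {DM, FP, SAL, VA, DA, CO, CP, RST} and
processing = {AUD, VIS, SMM, SMH} by default — the partition (in
particular RST) is not standardised, so it is an argument. Developmental
hubs are the `floor(0.05 n)` regions with the most negative composite
effects (16 of 333), and each hub retains its `floor(0.05 n)` most
negative edges (16 × 16 = 256 entries, duplicates across hubs counted
per hub); ties break deterministically by region id.

## Confirmatory inference

* **Network-based statistic (NBS).** Edgewise test statistics (two-sample
  t for a group contrast such as an age median split, or the t of a
  continuous predictor with covariates), a primary two-tailed threshold
  (default p < 0.01; the primary threshold is a free parameter of NBS,
  so it is an argument and is recorded in the result), breadth-first connected
  components of the suprathreshold graph, and a permutation null of the
  maximal component edge count obtained by permuting the predictor or
  labels (covariates stay attached to subjects). Component significance
  uses the $(b+1)/(n_\mathrm{perm}+1)$ estimator, avoiding p = 0.
  Component size is edge extent, the canonical NBS measure.
* **Bootstrap mediation.** Single-mediator OLS paths: $a$ (mediator on
  age), $b$ and $c'$ (outcome on mediator and age), $c$ (total effect);
  indirect effect $ab$ with a percentile CI over case-resampled refits
  (5,000 draws by default). For identical covariate sets
  $c = c' + ab$ exactly, which is asserted in the tests.
  `mediation_screen()` applies this over candidate mediators and reports
  both each candidate's own CI and BH-adjusted q values across
  candidates, since a per-candidate link that is individually
  significant may not survive the global correction.
* **Median split.** Deterministic: subjects ordered by value (ties by
  id), lower `ceiling(n/2)` form the low group, so the median-valued
  subject goes to the low group and group sizes differ by at most one.

## The synthetic cohort generator

The generator is the package's test-bed: it emulates a cross-sectional
resting-state cohort (defaults: 40 subjects aged 14–31, 64 regions, 60 s
at 250 Hz; `full_scale = TRUE` gives 68 subjects, 333 regions, 300 s —
the desk-scale defaults keep the full validation suite in minutes while
preserving epoch structure and estimator behaviour).

**Parcellation.** Region centres are sampled on an ellipsoidal shell
(roughly MNI extents, y ∈ [−80, 80] mm), hemispheres by the sign of x,
and network labels drawn with anterior regions enriched for association
networks and posterior regions for processing networks, mirroring the
real topography; every label is guaranteed at least two members when
there is room, so the network ANOVA's degrees of freedom are stable.

**Signal model.** Each band bin $f$ carries a shared phase
$\Phi_f(t) = 2\pi f t +$ a small random walk; region $r$ perturbs it
with its own stationary Ornstein–Uhlenbeck phase jitter $\eta_r(t)$
(equilibrium sd 2.2 rad, correlation time 0.4 s) attenuated by the
mixing weight $\kappa_r$:

$$x_r(t) = \sum_b A_{b,r}\sum_{f \in b}
\cos\!\big(\Phi_f(t) + (1-\kappa_{b,r})\,\eta_{b,r}(t)\big) +
\mathrm{noise\_floor} \cdot \xi_r(t),$$

with $\xi_r$ a 1/f (power exponent 1) background. A *stationary* jitter
(rather than an unbounded walk) was chosen deliberately: it makes the
κ → PLV map smooth and monotone and the PLV estimator ergodic, so
planted targets are achieved with small realization variance. The pair
phase difference still scrambles completely at κ = 0 and locks at κ = 1.

**Calibration.** Because achieved PLV is a nonlinear function of κ, all
coupling targets are specified on the *achieved PLV scale* and inverted
through a calibrated curve: a seeded Monte-Carlo sweep of two-region
simulations over a κ grid, fit with the smooth monotone form
$\mathrm{PLV}(\kappa) = p_0 + (p_1-p_0)e^{-c(1-\kappa)^2}$ (the
Gaussian-phase-jitter prediction). A parametric fit, rather than
interpolation through the noisy grid estimates, keeps the inversion
smooth so that a planted linear PLV-in-age trajectory stays linear. The
curve is cached per band and acquisition configuration with a fixed
internal seed, making it a property of the generator, not of the cohort
seed.

**Planted effects.** Per band, the regional PLV target is
$\mathrm{clip}(p_\mathrm{base} + (s + g\,y_r)(\mathrm{age} -
\mathrm{mid}),\ 0.02,\ 0.98)$: the y-gradient parameter $g$ modulates
the *age slope* itself, which is what produces an anterior-to-posterior
gradient of the age effect (a main effect of y on coupling would leave
the age beta constant across the cortex and nothing for the gradient
regression to find). Defaults plant a theta decline of −0.010 PLV/year,
steeper anteriorly (−8×10⁻⁵ per mm of y), no coupling change elsewhere;
band amplitudes plant the delta-down/beta-up power redistribution
(±1.5%/year with a small anterior modulation). A per-subject,
per-region coupling jitter (sd 0.02 PLV) models individual differences
and keeps edge-level residuals genuinely independent. Head motion is
log-normal and independent of age by default; `motion_age_slope`
switches on confounding for sensitivity analyses.

**Mediation structure.** Three disjoint edges among the six most
anterior regions follow the PLV trajectory
$p_\mathrm{base} + a(\mathrm{age}-\mathrm{mid})$; impulsivity is
generated from the *achieved* edge PLVs,
$\mathrm{imp} = 2.0 + c'(\mathrm{age}-\mathrm{mid}) +
\sum_e b_e(\mathrm{PLV}_e - p_\mathrm{base}) + \varepsilon$, clipped to
the 1–4 scale range, so the planted indirect effect of edge $e$ is
$a\,b_e$. By default only the first edge mediates ($b = 1.5$, with
$c' = 0$, full mediation); the other two are null candidates, giving the
screen something to reject. Disjoint endpoints matter: mediators sharing
a region (or several active mediators at once) make the single-mediator
path-b estimate absorb its correlated neighbours, which is a property of
single-mediator analysis itself, not of the estimator.

**What the generator does not emulate:** sensor-space acquisition and
source leakage (so PLV here has no volume-conduction bias and no need
for leakage correction), artifacts (cardiac, ocular, movement
transients), task structure, spatially correlated noise, and realistic
network topology beyond the anterior/posterior label gradient. Passing
recovery tests therefore validates the *estimators and inference
machinery*, not claims about real recordings.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles
(brute-force loops, hand arithmetic, closed forms, igraph for graph
components) and the whole chain by calibration and recovery, at sizes
chosen to keep the default run in minutes:

* null calibration: 200 replicate null cohorts of 30 subjects ×
  32 regions × 60 s; raw per-frequency false positives ≈ 5% and NBS
  family-wise error ≈ 5% (200 permutations per replicate);
* recovery: one cohort of 60 subjects × 64 regions for the theta age
  slope (within 2 mean SE of the planted value), the gradient sign and
  significance, and the power slopes; 20 replicate 8-region cohorts of
  60 subjects for mediation CI coverage of the mediated edge (the
  planted $ab$ inside the 95% percentile CI in ≥90% of replicate fits,
  800 bootstrap draws). Coverage is assessed where an effect is planted;
  for the null candidate edges the same check would measure the
  percentile bootstrap's type-I behaviour on products, which is known to
  be mildly anti-conservative, so their role is the specificity of the
  mediation screen instead;
* chance-level PLV against $\sqrt{\pi/(4N)}$ on 190 white-noise pairs ×
  49 frequencies.

`scripts/acceptance.R` re-runs a condensed version of the same
computations from scratch at a caller-supplied seed and writes the
headline numbers as JSON.

## Numerical and degenerate-input choices

* PLV phasors with exactly zero spectral amplitude contribute a zero
  phasor (this only occurs for analytically zero signals).
* Regressions whose response is numerically constant report beta 0,
  t 0, p 1 rather than a 0/0 statistic.
* Relative power is undefined (error) for an all-zero region.
* `select_hubs`/`hub_edges`/`median_split` break all ties by region or
  subject id, making every selection deterministic.
* A single pipeline seed expands into fixed per-stage seeds, so
  re-running any stage reproduces the full-run result; identical config
  and seed give byte-identical output tables.

## Known limitations

* The κ → PLV calibration is Monte-Carlo based; a residual bias of a few
  percent in planted slopes is possible (the recovery criterion of 2 SE
  absorbs it at the tested sizes).
* Edge regressions are mass-univariate with no spatial shrinkage, by
  design parity with the field's standard approach.
* The mixed model treats frequencies as exchangeable levels; no
  smoothness across frequency is exploited.
* Mediation here is a statistical decomposition on cross-sectional
  data; no causal identification is claimed.

## A worked mini-example

```{r example, eval = FALSE}
cfg <- cohort_config(n_subjects = 20, n_regions = 24, duration_s = 30,
                     seed = 1)
cohort <- generate_cohort(cfg)
res <- run_pipeline(pipeline_config(cohort = cfg, nbs_n_perm = 200,
                                    mediation_n_boot = 1000,
                                    run_mixed_model = FALSE, seed = 1))
res$gradients$y          # anterior-posterior gradient of the age effect
res$network$anova$F      # between-network differences
res$mediation            # age -> theta PLV -> impulsivity screen
```
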