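---
title: "Linking multi-parametric MRI to disc biomechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking multi-parametric MRI to disc biomechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discmech)
```

## The problem

Degeneration of the intervertebral disc (IVD) changes its compressive
stiffness and its hydraulic permeability, but those mechanical properties
can only be measured destructively. Quantitative MRI offers non-invasive
surrogates: the relaxation times T1 and T2, the magnetization transfer
ratio (MTR), and the diffusion-tensor scalars ADC (mean diffusivity) and FA
(fractional anisotropy). `discmech` implements a complete, testable pipeline
for studying how well a linear combination of those five imaging biomarkers
predicts five mechanical properties — the Young's modulus E, the zero-strain
aggregate modulus H_A0, and the radial (k_r), zero-strain axial (k_0) and
directly measured axial (k_a) permeabilities — in a four-group design
(healthy *in-situ* discs plus 6 h, 18 h and 24 h trypsin digestion) with two
regions per disc (nucleus pulposus NP, annulus fibrosus AF, n = 15 per
group).

Because no raw data from such a study are publicly deposited, the package
pairs every estimator with a seeded generator that shares its forward model
exactly. Every stage is therefore verifiable by parameter recovery: simulate
with known ground truth, fit, compare.

## Quantitative MRI models

**T1 (inversion-recovery TSE).** The signed signal at inversion time TI is

$$SI(TI) = S_0\left[1 - (1-\cos\alpha)\,E_{TI}\left(1 - E_{TW}\,f(N)\,(1 - E_{TE}/2)^2\right)\right],$$

with $E_x = e^{-x/T_1}$, $f(N) = 1 - E_{TE}^N$, refocusing angle
$\alpha = 180^\circ$, N = 8 refocusing pulses, and
$TW = TR - TI - N\,TE$ (clamped at zero), the recovery interval between the
last refocusing pulse and the next inversion. The default protocol uses 15
inversion times from 50 to 1900 ms at TR/TE = 2100/6.3 ms. Published
renderings of this readout-train correction differ typographically; the
parenthesisation above is fixed as this package's single shared forward
model, which is what the round-trip guarantee requires. The correction term
is small (< 1% of $S_0$ for disc-like T1), so the model behaves like
standard inversion recovery. Fitting is variable-projection nonlinear least
squares: $S_0$ is solved in closed form for each candidate T1, and T1 is
located by a coarse log-spaced grid on [10, 5000] ms refined by golden-section
search. Noiseless recovery is exact to well below 0.5% across T1 from 200 to
3000 ms. A magnitude mode restores polarity by choosing, per point, the sign
with the smaller residual.

**T2 (multi-echo).** $SI(TE) = SI(0)\,e^{-TE/T_2}$, ten echoes every 15 ms.
The fit is log-linear least squares (T2 = −1/slope), which is exact on
noiseless data, deterministic and has no tuning parameters. Non-positive
intensities (possible under noise) are excluded with a warning.

**MTR.** $MTR = (M_0 - M_S)/M_0$ from the saturated/unsaturated pair. The
generator treats the tissue MTR as a free ground-truth fraction; the MT
pulse parameters (1100 Hz offset, 620° flip) are carried as metadata only,
since no quantitative MT model links them to the ratio within scope.

**Diffusion.** One b = 0 image plus 15 diffusion-weighted directions at
b = 1000 s/mm²; $SI = SI_0\,e^{-b\,g^T D g}$. The direction set is a fixed
Fibonacci-hemisphere construction — deterministic, near-uniform, rank 3.
The six unique tensor entries are solved by ordinary least squares on
$\ln(SI/SI_0)$; eigenvalues give $ADC = \bar\lambda$ and

$$FA = \sqrt{\tfrac{3\sum_i(\lambda_i - \bar\lambda)^2}{2\sum_i \lambda_i^2}}.$$

Eigenvalues are deliberately not clipped before the metrics (noise-induced
negative eigenvalues propagate transparently); FA is clipped to [0, 1]
afterwards with the event logged. `tensor_from_md_fa()` builds axially
symmetric ground-truth tensors with exactly prescribed (MD, FA), which makes
the metric round trip a machine-precision identity.

**Noise.** Magnitude-MRI noise is Rician:
$v \mapsto \sqrt{(v+n_1)^2 + n_2^2}$ with $n_i \sim N(0, \sigma)$. Mechanical
force channels receive additive Gaussian noise. All draws flow through
explicit seeds and restore the caller's RNG state.

## Mechanical test models

Units: moduli in MPa, permeabilities in the reporting unit
$10^{-15}\,\mathrm{m^4/(N\,s)}$, specimen geometry in mm (5 mm diameter,
1.6 mm thick plugs by default); conversions to SI live in one place in the
code.

**Confined compression.** One-dimensional biphasic consolidation between an
impermeable moving platen and a free-draining support, with strain-dependent
laws

$$H_A(\epsilon) = H_{A0} e^{\beta\epsilon}, \qquad k(\epsilon) = k_0 e^{M\epsilon},$$

with compressive strain negative internally. (With this sign convention a
positive β softens the modulus under compression; the convention and the
laws are fixed jointly as the package's constitutive definition, and the
equilibrium stress is their quadrature
$\sigma_{eq} = H_{A0}(e^{\beta\epsilon}-1)/\beta$.) The solver is an exactly
mass-conserving finite-volume method of lines on 101 nodes integrated by
`deSolve` (lsoda, banded Jacobian). For β = M = 0 it reproduces the
closed-form consolidation series (the classical ramp response
$\sigma = H_A V t/h + (Vh/k)[1/3 - (2/\pi^2)\sum n^{-2} e^{-n^2\pi^2 H_A k t/h^2}]$,
implemented with a theta-function small-time branch) to ≤ 1% on the default
grid and ≤ 0.1% on refined grids. Fitting is three-stage: the equilibrium
staircase pins (H_A0, β) through the quadrature law (an offset absorbs the
small unrelaxed transient left when the stopping criterion ends a hold), the
first relaxation's time constant $h^2/(\pi^2 H_A k)$ initialises k_0, and
bounded Levenberg–Marquardt refines all four parameters against the full
force trace, with fallback starts (β = M = 0 and a perturbed point) if the
residual stays large.

**Unconfined compression.** A biphasic cylinder (radius a) between
frictionless impermeable platens, free-draining laterally. The radial
problem reduces to $\phi_t = H_A k_r\,(1/r)(r\phi_r)_r - \dot\epsilon_z$
for $\phi = (1/r)\,\partial(ru)/\partial r$ with an elastic boundary
condition at r = a derived from $\sigma_{rr} = 0$, $p(a) = 0$. The spatial
operator is discretized once (40 cells) and the response evaluated in closed
form by eigendecomposition — no time stepping — because each ramp's forcing
is linear in t. The discrete scheme reproduces both continuum limits
*exactly*: the instantaneous (incompressible) stiffness $3\mu_s\epsilon$ and
the drained equilibrium $E\epsilon$; its characteristic equation converges
to the classical unconfined-compression transcendental equation
$J_1(\beta) = \frac{1-\nu}{1-2\nu}\beta J_0(\beta)$. The viscoelastic
parameters (c, μ) enter as a quasi-linear multiplicative overlay
$1 + c\,e^{-(t - t_{ramp})/\tau_v}$ on each strain increment's relaxation,
with $\tau_v = \mu/E$ (standard-linear-solid convention: μ is the Maxwell-arm
viscosity for an arm of modulus E). This is the minimal construction that
yields exactly the two reported viscoelastic parameters. Fitting is
two-stage: equilibrium staircase → E and an SLS fit of the first relaxation
→ μ initialisation; then bounded quasi-Newton refinement of (E, k_r, ν, c, μ)
against the full trace from three starts. Stage 2 refines E because the
0.1 g/min stopping rule leaves a small, nearly ramp-independent unrelaxed
force at each "equilibrium" point; the staircase slope is still used as the
initial value and is reported separately.

**Stress-relaxation protocol.** Five successive ramps of 5% compressive
strain. The ramp rate is not part of the published protocol; the default is
5% over 60 s, configurable. Each relaxation ends when a centered 5-minute
rolling slope of the force falls below 0.1 g/min (1 g = 9.80665e-3 N), the
same criterion the equilibrium detector applies during analysis; the
recording extends half a window past the stopping point so the criterion is
re-detectable from the stored curve.

**Permeametry.** Darcy's law $k = Q\,l\,\mu/(\Delta P\, S)$ at a 40 kPa
pressure difference. Generator and estimator are exact inverses. (At the
stated geometry, published flow rates of ~20 µl/h imply permeabilities
orders of magnitude below the reported ~10×10⁻¹⁵ m⁴/(N s); the package
computes the law as written and does not attempt to reconcile that
inconsistency in the source material.)

## The cohort generator

`simulate_cohort()` emulates the study design: per region and group it draws
the five MRI variables from Gaussians with the published group means and SDs,
then produces each mechanical property from the linear linkage

$$MP = a_0 + a_1 T_1 + a_2 T_2 + a_3 MTR + a_4 ADC + a_5 FA + \varepsilon,$$

$\varepsilon \sim N(0, \sigma_{MP})$. The default coefficients are the
minimum-norm solution (computed on standardized predictors and mapped back
to raw units) of the 4-equations-in-6-unknowns system that maps the group
mean MRI vectors onto the group mean mechanical values — so group means of
the generated mechanical properties match the published tables exactly in
expectation. Two consequences are deliberate and documented rather than
hidden:

* the published group SDs of the mechanical variables cannot be imposed at
  the same time (the linkage propagates MRI scatter into the mechanical
  values); they inform the default residual scale
  ($\sigma_{MP}$ = 10% of the property's across-group mean) but are not
  enforced. A `mech_mode = "direct"` option draws mechanical values straight
  from the published Gaussians when marginal fidelity matters more than the
  linkage (e.g. for clustering studies);
* physically positive quantities are truncated at zero (count reported).
  Truncation breaks exact linearity, so the regression-recovery tests
  disable it; under default settings roughly 10–15% of values are affected,
  chiefly MTR and FA draws whose published SDs are large relative to their
  means.

What the generator does *not* emulate: nonlinear MRI–mechanics
relationships (the study itself reports R² of only 0.45–0.80, i.e. the real
data are far from exactly linear), inter-variable correlations within the
MRI block beyond those induced by group structure, scanner artifacts,
segmentation error, or digestion chemistry. Passing recovery tests therefore
demonstrates the correctness of the estimators, not the biological validity
of a linear MRI→mechanics model.

## Statistics layer

* **ANOVA / post hoc.** One-way ANOVA per variable over the four groups,
  then all 6 pairwise pooled-variance t tests with the Dunn–Šidák
  adjustment $p' = 1-(1-p)^m$. The exact post-hoc statistic of the original
  commercial software is unknowable; pooled-variance t + Šidák is the
  standard reading and is what the tests verify.
* **Regressions.** OLS per group and response, with
  $SEE = \sqrt{SSE/(n-6)}$, overall-F power from the noncentral F
  distribution (noncentrality $\lambda = n R^2/(1-R^2)$ by default; a
  residual-df convention is selectable and recorded in the output), and VIF
  per predictor. `vif_eliminate()` removes the highest-VIF predictor while
  max VIF > 10 (configurable), logging ΔR² — mirroring the observation that
  T2 carries the highest inflation and its removal barely moves R².
* **PCA.** Centered-reduced variables, eigendecomposition of the
  correlation matrix, deterministic sign convention (largest-magnitude
  loading positive). Run per mechanical property on the six variables (that
  property + the five MRI parameters), matching the study's
  correlation-circle layout; eigenvalues sum to 6 and cumulative
  variability is reported for F1–F3.
* **Clustering.** Ward agglomerative clustering on the first three
  principal-component scores of the mechanical (or MRI) block. Merge
  heights are the ESS increments themselves (Lance–Williams recurrence on
  $d^2/2$), so they sum to the total sum of squares — the conservation the
  tests check — and `stats::hclust` on the same dissimilarities is the
  independent oracle. The informal "compare each link with the links below"
  rule is formalised as: over the last 10 merges, cut where the ratio
  $h_i/h_{i-1}$ is maximal; the full ratio table is returned so users can
  override k. Ties in merging are broken by lowest node index.

Whether PCA should pool the four groups is not specified in the source
design; the package pools the 60 samples per region (the per-group
alternative is a one-line subset).

## Numerical choices and problem sizes

* Confined solver: 101 nodes (fit-time tolerance 1e-7, generator 1e-8);
  halving the grid spacing moves curves by < 0.2%.
* Unconfined solver: 40 radial cells; refinement to 120 moves curves by
  < 0.5%; the two elastic limits are exact identities of the discrete
  scheme, independent of the grid.
* Series truncation (linear consolidation): terms to a 1e-10 relative
  change, with the theta-function asymptotic below τ = 0.05 where the
  direct sum converges slowly.
* Optimisation: bounded Levenberg–Marquardt (confined) and `nlminb`
  (unconfined) on log-transformed positive parameters, ν bounded in
  [0.001, 0.49] with at-bound flagging, fixed multi-start perturbations
  (no randomness inside fitters).
* Test and acceptance problem sizes: phantoms of 4–16 voxels, cohorts of
  8–60 rows per region (4000–15000 only for law-of-large-numbers checks),
  mechanical round trips with 2 ramps/coarser grids in unit tests and the
  full 5-ramp, 101-node protocol in the acceptance checks. These sizes were
  chosen so the full suite runs in minutes while every tolerance retains a
  safety margin of at least 2x.

## Known limitations

* The equilibrium-criterion stopping rule interacts with very soft nucleus
  pulposus specimens: at E ≈ 0.02 MPa the force slope can fall below
  0.1 g/min long before true drained equilibrium, which is why the
  unconfined fitter refines E on the full transient rather than trusting
  the staircase alone.
* β and M of the confined model are weakly identified from force data alone
  (a long, flat valley trades them against H_A0 and k_0); the equilibrium
  staircase initialisation resolves this in the noiseless setting, but
  noisy single-specimen fits should expect wide intervals on β and M.
* The MT pulse parameters do not modulate the synthetic MTR; tissue MTR is
  a free parameter.
* No registration, segmentation, bias-field or eddy-current modeling; ROI
  masks are inputs.
* No shear or tensile testing, swelling pressure, or specimen-level finite
  element geometry.
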