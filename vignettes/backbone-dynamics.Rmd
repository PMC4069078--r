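---
title: "Backbone dynamics from NMR relaxation, H/D exchange and RDCs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone dynamics from NMR relaxation, H/D exchange and RDCs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nmrdyn` analyzes the backbone dynamics of a protein observed by
solution NMR in two states (ligand-free and ligand-bound) at elevated
temperature. This vignette is the package's own account of the models
it fits, the assumptions behind them, the tunable parameters and their
defaults, the synthetic-data generator used to validate every stage,
and the numerical and design choices that were genuinely open.

## The relaxation model

¹⁵N longitudinal (R1) and transverse (R2) relaxation rates and the
{¹H}–¹⁵N heteronuclear NOE report on reorientational dynamics of each
backbone amide N–H bond vector. The package evaluates the standard
dipolar + chemical-shift-anisotropy expressions at the five
eigenfrequencies {0, ωN, ωH−ωN, ωH, ωH+ωN} from a model-free
spectral density

$$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
\frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right],\qquad
\tau^{-1} = \tau_m^{-1} + \tau_e^{-1},$$

with the squared generalized order parameter S² (amplitude of ps–ns
internal motion; 1 = rigid), the effective internal correlation time
τe, and the overall tumbling time τm. For an axially symmetric
diffusion tensor the single overall-tumbling term becomes the familiar
three-term sum with coefficients A₁ = (1.5cos²α−0.5)²,
A₂ = 3sin²α·cos²α, A₃ = 0.75·sin⁴α (α = angle between the N–H vector
and the symmetry axis) and correlation times 1/τ₁ = 6D⊥,
1/τ₂ = 5D⊥+D∥, 1/τ₃ = 2D⊥+4D∥; the coefficients sum to one for every
α, which the test suite asserts on an (α, ω) grid together with the
exact collapse to the isotropic form when D∥ = D⊥. A
conformational-exchange term Rex adds to R2 and scales with the square
of the static field; fitted Rex values are referenced to 800 MHz, the
field at which the package reports results.

Physical constants default to the conventions of the established
model-free tools — r(N–H) = 1.02 Å, ¹⁵N CSA = −172 ppm, CODATA
gyromagnetic ratios — and are overridable through the `constants`
argument everywhere they enter, because reported S² values shift
systematically (by a few percent) under alternative constant sets.

## Two-stage protocol and assumptions

The analysis is deliberately two-stage, as is standard: the rotational
diffusion tensor is estimated first from residues assumed rigid, then
held fixed during per-residue model-free fitting.

*Stage 1 assumptions.* Local correlation times are obtained by
inverting the rigid-rotor (S² = 1, τe = 0, Rex = 0) isotropic R2/R1
ratio, which is monotone in τm on 0.5–50 ns — the inversion window the
package enforces; ratios outside the attainable range are flagged and
excluded rather than clamped. The "rigid subset" is selected by two
thresholds: residues with hetNOE < `noe_min` (default 0.65) are
excluded as internally mobile, then residues whose R2/R1 deviates from
the mean by more than `sd_multiple` (default 1) standard deviations
are excluded in a single iteration — one iteration, not to
convergence, so that a genuinely broad distribution cannot be trimmed
to an artificially tight core. The global τc is the mean ± s.d. of the
surviving local values; fewer than five survivors is an error, not a
silent answer.

*Stage 2.* Each residue is fitted against all of its observables
(R1, R2, NOE at one or two fields) by χ² minimization over the model's
parameters with physical bounds (0 ≤ S² ≤ 1, τe ≥ 0, Rex ≥ 0). Five
nested parameterizations are available: S²; S²,τe; S²,Rex; S²,τe,Rex;
and the extended two-timescale form Sf²·Ss² with τs. Optimization uses
a coarse grid of starting points (best three refined by L-BFGS-B with
internal rescaling of τe to O(1) units); the test suite checks the
optimizer against an exhaustive grid (S² step 0.001, τe step 1 ps) on
synthetic residues.

*Model selection* uses the small-sample corrected information
criterion AICc = χ² + 2k + 2k(k+1)/(n−k−1) rather than stepwise
F-tests. The F-test path depends on the order in which nested pairs
are visited, which the package cannot pin down from the original
tooling; an information criterion is order-free, gives the same
parsimony behaviour on clean data (a larger model is never selected
when data were generated noiselessly from a smaller one — a test
asserts this), and is swappable. Parameters absent from the selected
model are reported as absent (NA), never as zero with an uncertainty.

*Uncertainties* come from `n_mc` Monte-Carlo resamples (default 500;
tests and the demo use smaller values) of the observables within their
stated errors, refitting the selected model from the best-fit starting
point. The resampling is seeded and reproducible.

## Rotational diffusion tensor

The axially symmetric tensor is fitted by minimizing the χ² of
observed versus back-calculated R2/R1 over (D⊥, D∥, θ, φ) with rigid
local dynamics, from a multi-start grid over the axis angles and both
anisotropy branches. The oblate (D∥/D⊥ < 1) and prolate (> 1) branches
produce near-degenerate χ² minima — a structural property of
ratio-based tensor fits, not an implementation artifact — so
`fit_axial_tensor()` always reports both, labelled first/second
minimum by χ². At realistic noise the *global* minimum can hop between
branches across noise realizations; the stable quantity is the
anisotropy of a fixed branch, which is what the stability tests
measure (s.d. < 0.05 across 100 repeats at study noise with 51
residues, the subset size the analysis uses). Noiseless recovery of a
synthetic oblate tensor (anisotropy 0.90) is exact to 10⁻³ including
the axis orientation (< 1°, modulo the director symmetry α ↔ π−α).

Three independent τc estimates contextualize the fitted value:

* η/T extrapolation: τc is proportional to η(T)/T for
  Stokes–Einstein–Debye tumbling, so a least-squares line through the
  measured (T, τc) points evaluated at the target temperature
  extrapolates τc. The water-viscosity correlation is a Vogel form
  η(T) = A·exp(507.88/(T−149.3)) with A anchored so
  η(298.15 K) = 0.8900 mPa·s; the extrapolated room-temperature value
  is mildly sensitive (±0.3 ns) to the viscosity table chosen, which
  is why the correlation is centralized in `water_viscosity()`.
* the empirical molecular-weight correlation
  τc[ns] = 0.5998·MW[kDa] + 0.1674;
* the Stokes–Einstein hard sphere τc = 4πηr³/(3k_BT) with
  r = (3·MW·v̄/(4πN_A))^{1/3} + hydration shell. The partial specific
  volume defaults to v̄ = 0.73 cm³/g, the standard globular-protein
  value, with hydration 3.2 Å; both are arguments, not constants.

## Conformational entropy

Per-residue entropy differences between states use the
diffusion-in-a-cone relation
ΔS = R·ln[(3−√(1+8S²_B))/(3−√(1+8S²_A))] in J·mol⁻¹·K⁻¹ (per mole,
as the units imply), with A the free and B the bound state so a
negative sum is entropy lost on binding. The formula is exactly
antisymmetric under swapping states, zero for equal S², additive over
disjoint residue sets (all tested), and singular at S² = 1 — residues
at the bound are rejected with a message rather than clipped, because
a clipped value would silently dominate the sum. Only residues with
data in both states enter the sum.

## H/D exchange

Build-up curves are fitted to the three-parameter form
I(t) = I(∞) + I(0)·(1−exp(−k_ex·t)) exactly as the generator emits it.
Two censoring rules bracket the measurable window:

* residues already at their full intensity by the first spectrum are
  "fast"; their rate is bounded below by
  k_min = −ln(1−completeness)/t₁. The completeness default 0.926 is a
  documented reconstruction: it reproduces the conventional fast-group
  bound of 2.9×10⁻³ s⁻¹ at t₁ = 900 s, and then implies a second
  spectrum near 25.5 min for the second-group bound of 1.7×10⁻³ s⁻¹ —
  consistent with, but not stated by, the experimental schedule.
* series that never recover an appreciable fraction (< 0.3) of the
  full peak intensity and show no rise beyond the residual noise are
  "slow/unexchanged". This guard exists because an unconstrained
  three-parameter fit of a noise-only series can extrapolate a large
  build-up *below* the first time point and report a spurious rate;
  the classification therefore looks at the observed rise within the
  sampled window, not the fitted amplitude.

Every residue receives exactly one category (measured, fast,
second-fastest, slow, no-data); the censored categories carry the
conventional log P display codes 2.5 / 2.8 / 7.0 / −0.1 and no point
estimate. Intrinsic rates k_int are poly-alanine reference rates for
the acid-, base- and water-catalyzed pathways with log-additive
nearest-neighbour corrections, terminal-group factors, Arrhenius
scaling (14/17/19 kcal/mol from 293 K) and a van't Hoff water-ion
product; sample pH and temperature are required inputs with no silent
default, because the base-catalyzed pathway moves an order of
magnitude per pH unit. The first residue and prolines have no amide
contribution and report NA. Tryptophan side-chain Nε1 entries can be
carried alongside but are excluded from backbone summaries.

## Structure and RDC quantities

Ensemble precision uses iterative mean-structure superposition: models
are superposed onto the current mean by the SVD (Kabsch) solution with
a reflection guard, the mean is recomputed, and the cycle repeats to
convergence (10⁻⁸ Å on the mean). Cross-RMSD to a reference structure
requires an explicit atom pairing and reports the pair count so
selections are auditable. β-strand residue spans and the
five-residues-per-terminus trim are configuration, not hard-coded.

Apparent splittings from spin-state-selective spectra convert to total
couplings by the linear contract J+D = 2·apparent/((1−κ)+λ), anchored
exactly at the two operating points used experimentally (κ = λ = 0.5:
apparent = (J+D)/2; κ = 0, λ = 1: apparent = J+D); the interpolation
between anchors is inferred, and flagged as such here. The alignment
tensor is the linear least-squares (SVD) solution for the five
independent components of the traceless symmetric tensor from
D = vᵀAv; the design-matrix condition number is reported and
rank-deficient vector geometries are an error. Q = rms(D_obs−D_calc)/
rms(D_obs) and Pearson r are the fit diagnostics; eigenvalues are
ordered |Azz| ≥ |Ayy| ≥ |Axx| with Da = Azz/2 and
R = (2/3)(Axx−Ayy)/Azz.

When amide protons are missing from coordinates, H is placed on the
bisector convention — opposite the bisector of N→CA and N→C(i−1) at
1.02 Å — and flagged; against explicitly protonated test geometries
the reconstructed vectors agree within a few degrees, which is
adequate for tensor work but the flag lets a user exclude them.

## The synthetic-data generator

The generator is the package's substitute for spectrometer output and
defines the conditions under which the pipeline is validated:

* per-residue truths: strand S² ~ N(0.89, 0.02) truncated to [0, 1],
  loop S² ~ N(0.75, 0.08) (free-state preset: 0.87/0.74), τe tens of
  ps in strands and up to 2 ns in loops, a small fraction of residues
  with Rex in the observed 1.6–5.1 s⁻¹ range, and optionally one
  low-S² (≈0.2) hinge residue. The class means are anchored to the
  reported secondary-structure averages; the dispersions are a
  modelling choice, since no per-residue table is printed anywhere to
  calibrate them against.
* noise: independent Gaussian, with per-observable σ set to the
  reported average measurement errors per condition (800 MHz/58 °C
  bound: 0.04 s⁻¹ R1, 0.40 s⁻¹ R2, 0.04 NOE; the other conditions use
  their own printed values). σ is recorded as the error column, so
  χ² fitting is calibrated by construction.
* schedules: the T1 grid (10…3500 ms), T2 grid (10…110 ms) and H/D
  grid (first point 900 s, last 96 h) reproduce the experimental
  sampling; duplicate time points are flagged replicates.
* residue numbering carries the two-residue sequence gap after
  position 54, so identifiers are labels and never array indices.

What the generator does **not** emulate: spectral lineshapes and peak
overlap, correlated noise between observables, temperature-dependent
S², anisotropic-tumbling cross-talk into the T1/T2 schedules, EX1
exchange kinetics, or real β-barrel N–H geometry (the `barrel_like`
vector mode concentrates polar angles but is not a structure). Passing
tests therefore demonstrate correctness of the estimators under the
assumed statistical model, not robustness to spectral artifacts.

## Numerical choices

* Exponential and build-up fits: Levenberg–Marquardt (`minpack.lm`)
  started from a log-linear regression (decays) or a half-rise
  heuristic (build-ups); ftol/ptol 10⁻¹². Replicate time points are
  averaged before fitting (their pairwise differences estimate the
  noise floor), making the time grid strictly increasing.
* Jackknife errors: delete-one over merged time points,
  σ² = (n−1)/n·Σ(θᵢ−θ̄)²; verified against brute-force enumeration.
* local τm inversion: `uniroot` to 10⁻¹⁵ s on the monotone window.
* Tensor fit: Nelder–Mead on (log τc, log ξ, θ, φ) — logs keep the
  positivity constraints implicit — from a pre-screened angle×branch
  grid, refining the best two starts per branch, with a second
  refinement pass; angles are reported modulo the director symmetry.
* Model-free χ²: observables enter with their recorded σ; missing
  observables are simply absent from χ² (never imputed).
* Degenerate inputs are errors or flags, not numbers: constant decay
  series are flagged `flat`, unattainable R2/R1 ratios are excluded
  with a warning, S² = 1 is rejected by the entropy formula,
  collinear vector sets are rejected by both tensor fits.

## Problem sizes

The test suite and acceptance script validate at deliberately small,
fixed sizes chosen to make the statistical checks sharp on one CPU:
24-residue two-state demo (16 strand + 8 loop, two fields), 51
residues for tensor-stability repeats (the subset size the real
analysis used), 200 synthetic strand residues for the S²-recovery
statistic, 100 noisy repeats for the anisotropy spread, and 10⁴ draws
for noise-calibration checks. These sizes are the package's own
validation choices; all are arguments that scale up.

## Known limitations

* The fully anisotropic (rhombic) diffusion tensor is out of scope;
  the axial model is the terminal point of the hierarchy here.
* Intrinsic-rate correction tables are transcribed from the cited
  poly-alanine parameterization; the package's tests pin the
  reference-rate arithmetic (dual implementation), pH/temperature
  behaviour and proline/terminus handling, but individual
  neighbour-factor entries inherit the transcription.
* The deposited experimental structures are not shipped; ensemble
  statistics on them require network access, and the package's own
  validation of the superposition machinery uses synthetic ensembles
  and an independent-implementation cross-check (`bio3d`).
* Rex is modelled as purely quadratic in the field (fast-exchange
  limit); no attempt is made to resolve exchange timescales.
* H/D analysis stops at protection factors; EX1/EX2 discrimination and
  ΔG_HX thermodynamics are not computed.
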