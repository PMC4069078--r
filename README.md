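# nmrdyn

Backbone dynamics of proteins from solution-state NMR observables.

`nmrdyn` implements, as a tested R package plus a set of analysis
scripts, the complete workflow used to characterize the picosecond- to
millisecond-timescale backbone motions and solvent protection of a
large, thermostable β-barrel protein in its ligand-free and
ligand-bound forms:

* **¹⁵N relaxation rates** — non-linear least-squares fitting of peak
  intensity decays to I(t) = I₀·exp(−R·t) with delete-one jackknife
  uncertainties, and hetNOE ratios I_sat/I_unsat with rms-noise error
  propagation.
* **Rotational diffusion** — residue-wise correlation times from the
  rigid-rotor R2/R1 ratio (bisection on the monotone window), the
  trimmed global τc, an axially symmetric diffusion-tensor fit over
  (D⊥, D∥, θ, φ) reporting both the oblate and the prolate minimum,
  inertia-tensor moments, η/T temperature extrapolation of τc, and the
  empirical-MW and Stokes–Einstein τc estimates.
* **Lipari–Szabo model-free analysis** — spectral densities
  J(ω) = (2/5)[S²τm/(1+(ωτm)²) + (1−S²)τ/(1+(ωτ)²)] (and the
  three-term axially symmetric generalization), back-calculation of
  R1/R2/NOE from dipolar + CSA expressions, per-residue fitting of the
  five standard models (S²; S²,τe; S²,Rex; S²,τe,Rex; extended
  Sf²,Ss²,τs) with small-sample-corrected information-criterion model
  selection and Monte-Carlo errors.
* **Conformational entropy** — per-residue
  ΔS = R·ln[(3−√(1+8S²_B))/(3−√(1+8S²_A))] from the free/bound order
  parameters, summed over residues observed in both states.
* **H/D exchange** — three-parameter build-up fits
  I(t) = I(∞)+I(0)(1−exp(−k_ex t)), censored lower bounds for residues
  exchanged before the first spectrum, sequence-specific intrinsic
  rates (poly-alanine reference rates with nearest-neighbour
  corrections, Arrhenius temperature and pH dependence), and protection
  factors P = k_int/k_ex with the standard plotting categories.
* **Structure & RDCs** — multi-model PDB ensembles, iterative
  mean-structure superposition (Kabsch/SVD) with RMSD statistics,
  cross-RMSD to a reference structure with auditable atom-pair counts,
  N–H bond-vector extraction with geometric amide-proton
  reconstruction, scaled-splitting coupling arithmetic
  (J+D = 2·apparent/((1−κ)+λ)), and SVD alignment-tensor fits with
  Q-factor and correlation diagnostics.

A first-class synthetic-data module (`gen_truth()`,
`simulate_relaxation()`, `simulate_decay_series()`,
`simulate_hdx_series()`, `gen_bond_vectors()`) generates ground-truth
parameter sets and noisy observations with the statistical structure
the analysis assumes, so every stage is testable without spectrometer
data.

## Worked example

The numbered scripts under `analysis/` run a two-state synthetic study
shaped like the real experiment (two fields, 58 °C, a loop that
rigidifies on ligand binding, H/D exchange for both states):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_relaxation_rates.R
Rscript analysis/03_diffusion.R
Rscript analysis/04_modelfree.R
Rscript analysis/05_entropy.R
Rscript analysis/06_hdx.R
Rscript analysis/07_structure_rdc.R
```

Representative output (seed 20260):

```
free  800 MHz: R1 = 0.765 +/- 0.169  R2 = 19.09 +/- 1.86  NOE = 0.67 (n = 24)
free : global tau_c = 12.91 +/- 0.16 ns from 15 residues
eta/T extrapolation 58+40 C -> 25 C: 25.2 ns
empirical MW formula (56 kDa):      33.8 ns
Stokes-Einstein (r_hydr 3.2 A):     21.0 ns
largest rigidification on binding (delta S2 > 0):
 residue   S2_free  S2_bound  delta_S2
      19 0.6894883 0.8384110 0.1489227
      25 0.7504462 0.8893429 0.1388967
conformational entropy change on binding (24 residues):
  dS = -28.6 J mol^-1 K^-1  (T dS = -9.5 kJ mol^-1 at 331 K)
fast-exchange lower bound at t1 = 900 s: 2.9e-03 s^-1
matched residues (n = 8): mean k_ex free 5.95e-04, bound 3.14e-04, offset 2.81e-04 s^-1
```

Reading these numbers: the recovered global correlation time (~13 ns at
58 °C) extrapolates along η/T to ~25 ns at room temperature — between
the hard-sphere Stokes–Einstein estimate (21.0 ns) and the empirical
molecular-weight correlation (33.8 ns) for a 56 kDa protein. The
model-free stage finds exactly the four loop residues whose S² was
raised by 0.15 in the generating truth, the entropy sum over shared
residues is negative (net loss of backbone conformational entropy on
binding), and the matched-residue exchange-rate offset recovers the
seeded 0.28×10⁻³ s⁻¹ faster exchange of the free form.

The same run is available as a single call:

```r
library(nmrdyn)
demo <- make_demo(seed = 1)
demo$entropy$dS_J_mol_K   # negative: entropy loss on binding
head(demo$delta_S2[order(-demo$delta_S2$delta_S2), ])
```

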