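---
title: "Methods: unfolding kinetics, state assignment and cryptic APR detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unfolding kinetics, state assignment and cryptic APR detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticfold)
```

# The scientific problem

Computationally stabilized enzymes sometimes pay for their extra
conformational stability with poor solubility: stabilizing substitutions
tend to be hydrophobic, and sequence stretches that are safely buried in
the native fold can become solvent-exposed during partial unfolding. If
such a stretch is also aggregation-prone, it acts as a *cryptic
aggregation-prone region* (cryptic APR): invisible to aggregation
predictors applied to the native state, yet decisive for what happens the
moment the protein starts to unfold.

`crypticfold` implements the complete computational chain needed to
diagnose this failure mode for a protein system such as the haloalkane
dehalogenases: (i) global kinetic analysis of thermal unfolding
experiments, (ii) assignment of folded / intermediate / unfolded
conformational ensembles from simulation feature series via Markov state
models (MSMs), (iii) detection of residues whose solvent exposure status
changes between states, and (iv) intersection of those residues with
aggregation-score profiles, plus mutation-level surface-hydrophobicity
accounting.

# The three-state irreversible unfolding model

Thermal unfolding of kinetically stabilized proteins is scan-rate
dependent and poorly reversible, so it is modeled as a sequence of
irreversible first-order steps

$$ N \xrightarrow{k_1} I \xrightarrow{k_2} D $$

with temperature-dependent rate constants parametrized as

$$ k_i(T) = \exp\!\left[\frac{E_{a,i}}{R}\left(\frac{1}{T^{*}_{i}} -
\frac{1}{T}\right)\right] \quad (\mathrm{min}^{-1}), $$

where $E_{a,i}$ (kJ/mol) is the activation energy and $T^{*}_i$ (K) is
the temperature at which step $i$ proceeds at 1 min$^{-1}$. This
parametrization is numerically benign (both parameters have natural
scales and direct data support) and is convertible to Gibbs activation
energies by Eyring inversion, $\Delta G^{\ddagger}_i(T) = -RT \ln [k_i h
/(k_B T)]$, reported by default at 40, 60 and 80 °C
(`barrier_at()`).

Signals are linear observations of the state fractions
$x_N, x_I, x_D$:

* DSC excess heat capacity: $C_p^{exc}(T) = [\Delta H_{cal,1} k_1 x_N +
  \Delta H_{cal,2} k_2 x_I]/v$ for scan rate $v$. No $\Delta C_p$ term is
  included; the data contract is baseline-subtracted thermograms, which
  also means barriers are not extrapolated far below the transition.
* Spectroscopic melt curves (nanoDSF barycentric mean, CD):
  $y(T) = \sum_s (a_s + b_s (T - T_{ref}))\, x_s(T)$ with per-state
  linear baselines.
* Isothermal traces: $y(t) = \sum_s a_s x_s(t)$ with per-state
  *constants*. At a fixed temperature there is no instrumental reason
  for a per-state drift, and the time-slope columns $t\,x_s(t)$ are
  nearly collinear with the kinetics themselves — including them makes
  the second unfolding step practically unidentifiable (we verified this
  directly on the Fisher information of the design).

## Global fitting

`global_fit()` shares the four kinetic parameters across all curves and
keeps baselines per dataset. It exploits the model's structure by
variable projection: for any trial of $(E_{a,1}, T^*_1, E_{a,2}, T^*_2)$
the enthalpies and baselines enter linearly and are solved exactly by
weighted linear least squares (enthalpies constrained non-negative by
column dropping), so the outer bounded Levenberg–Marquardt
(`minpack.lm`) works in only four dimensions. The outer optimizer is
restarted from a Latin-hypercube design (`lhs`), 20 starts by default,
seeded; ties are broken by start order, and restarts stop early only
when a residual is already at exact-fit level.

Weights make techniques with different units commensurable: each
dataset is weighted by the inverse variance of its noise, estimated from
residuals around a linear trend through the pre-transition points for
scans, and from second differences for isothermal traces (which have no
pre-transition region). Both estimates are floored at 0.1 % of the
curve amplitude.

Following the model-selection protocol for this data class, the
calorimetric enthalpy of one of the two steps can be fixed to zero;
`constraint = "auto"` fits both choices and keeps the lower-residual
one, recording both residuals in the result.

## Numerical integration of the scan equations

The scan-mode equations $dx_N/dT = -k_1 x_N / v$, $dx_I/dT = (k_1 x_N -
k_2 x_I)/v$ are advanced by an exponentially fitted scheme (in Rcpp) on
a refined internal grid (default maximum step 0.01 K; 0.05 K inside the
fit): $x_N$ decays by the trapezoid-averaged rate, and the linear $x_I$
equation is advanced by its integrating-factor closed form. The scheme
is exact for piecewise-constant rates and unconditionally stable, so the
extremely fast post-transition rates cannot destabilize it — an adaptive
explicit solver would need tiny steps exactly where nothing interesting
happens. Mass conservation $x_N + x_I + x_D = 1$ holds to machine
precision by construction; the tests verify agreement with a 10^-3^ K
explicit-Euler brute force and with `deSolve::lsoda` at rtol 10^-10^.
Isothermal fractions use the analytic solution with a series branch for
$|k_2 - k_1| t$ small and an `expm1`-safe form elsewhere.

# Markov state models of unfolding ensembles

The feature is the Cα RMSD to a native reference after optimal
(Kabsch, SVD-based) superposition, by default over residues 12–285 to
exclude the flexible dehalogenase termini. Frames are discretized by
1-D k-means (`stats::kmeans`, seed-controlled, centers relabeled in
ascending order; the desk-scale default is 50–100 microstates rather
than the 1000 used on production-scale trajectory sets). Transition
counts are collected by sliding window at the chosen lag within each
trajectory, restricted to the largest strongly connected state set
(`igraph`), and row-normalized; the stationary distribution is the
leading left eigenvector. A detailed-balance-enforcing (symmetrized)
estimator is available behind a flag, since reversibility enforcement is
an open modeling choice for this data.

Coarse graining is PCCA-style: microstates are embedded in the top
$n$ right eigenvectors and grouped by seeded k-means; a degenerate
spectral gap (eigenvalue tie within 10^-10^) is broken by microstate
index and flagged. Macrostates are labeled folded / intermediate /
unfolded by ascending stationary-weighted mean RMSD, and with four
requested macrostates the two middle ones are merged into a single
intermediate, mirroring the consistency convention for protein variants
whose MSMs resolve two intermediate substates.

The Chapman–Kolmogorov test compares $T(f\tau)$ against $T(\tau)^f$ in
max norm. Because *both* matrices are estimates, the reported sampling
bound is $3\sqrt{(1+f)\,p(1-p)/n}$ at worst-case $p = 1/2$: the extra
$f$ accounts for the error of the short-lag estimate propagated through
the $f$-th matrix power. With the naive single-matrix bound even data
simulated from an exact Markov chain fails the test at $f = 5$.

Per-residue B-factors use the standard isotropic fluctuation formula
$B = (8\pi^2/3)\langle|\mathbf r - \langle\mathbf r\rangle|^2\rangle$
after two-pass superposition onto the state-mean structure (align to the
first frame, form the mean, re-align to the mean); residue values are
means over the four backbone atoms.

# Solvent exposure and its changes

Per-residue SASA uses the Shrake–Rupley construction: 960 evenly
distributed test points (deterministic golden-section spiral) on each
atom's solvent-expanded sphere (probe 1.4 Å), occluded by neighboring
expanded spheres, with Bondi van der Waals radii bundled. The algorithm
is deterministic for a fixed point count and converges to well under
0.5 % by 960 points on desk-scale structures. Relative accessibility is
rASA = SASA / SASA^max^ with the theoretical maxima of Tien et
al. (2013); a residue is *exposed* iff rASA ≥ 0.25 (inclusive, matching
the convention "exposed for rASA ≥ 0.25"). rASA slightly above 1 is
flagged, not rejected — extended conformations can exceed the tabulated
maxima.

Ensembles are summarized by the per-residue mean rASA over frames
(default), with an alternative "exposed in ≥ 50 % of frames" mode, since
whether thresholding should precede or follow frame averaging is not
uniquely determined by the protocol this package follows. Exposure
changes between a native and a comparison state are pure threshold
crossings: `newly_exposed` = below 0.25 in the native profile and at or
above it in the other.

# Aggregation-prone regions and mutations

APR segmentation takes a per-residue aggregation-score profile (from any
external predictor; predictors themselves are out of scope) and returns
maximal runs of residues whose score *strictly exceeds* 0.25 — regions
that merely reach the threshold are non-APR, whereas the rASA exposure
rule is inclusive; the asymmetry follows the two conventions' own
wording and both thresholds are configurable. The headline statistic is
the percentage of newly exposed residues inside the APR union
(`overlap_exposed_aprs()`); an empty exposed set reports `NA` with a
flag rather than 0. An APR is flagged *cryptic* when a majority of its
residues are natively buried and it contains at least `min_hits`
(default 2) newly exposed residues.

Mutation strings such as `"E20S + F80R"` are parsed with tolerance for
stray internal whitespace (as appears in published variant tables, e.g.
`"D166 K"`), validated against the sequence when one is supplied, and
classified surface/buried by native rASA at the site. Surface
hydrophobicity change sums a min–max-normalized hydrophobicity value
over surface residues for wild-type and mutant sequences, holding the
exposure status fixed at the wild-type structure (no mutant structure
prediction is attempted — a stated limitation). Two classical scales
are bundled, Kyte–Doolittle and Eisenberg consensus; because the scale
identity behind any particular published percentage is generally
unknown, percent changes are comparative diagnostics, not reproduction
targets.

# The synthetic-data generators

Every analysis stage has a generator producing its inputs with known
ground truth, which is what the test suite and the acceptance script
exercise:

* `gen_thermal_datasets()` / `gen_isothermal_traces()` forward-model
  melt curves and isothermal traces and add i.i.d. Gaussian noise scaled
  to each curve's amplitude. The default truth
  ($E_{a,1} = 400$, $T^*_1 = 337$ K, $E_{a,2} = 300$, $T^*_2 = 342$ K,
  $\Delta H_{cal,1} = 450$ kJ/mol, $\Delta H_{cal,2} = 0$) puts DSC
  peaks near 333–337 K with a 1–2 K shift per scan-rate doubling across
  the default 0.5 / 1 / 2 K/min set — the qualitative signature of
  kinetically controlled dehalogenase unfolding; it is illustrative, not
  fitted to any particular protein. Isothermal defaults hold at 50, 65
  and 80 °C with *rate-matched* durations (240, 60 and 1 min): an
  acquisition window matched to the relaxation time at each temperature,
  the same logic that motivates stopped-flow temperature-jump
  instruments at the hot end. With rate-mismatched windows the second
  step's activation energy is barely identifiable at realistic noise.
* `gen_markov_feature_series()` samples hidden-Markov RMSD series with
  Gaussian emissions (defaults in the tests: means 2 / 8 / 14 Å, sd
  1 Å, self-transition 0.98) and stores true labels.
* `gen_toy_ensemble()` builds one-bead-per-residue conformers on a
  compact cubic-lattice blob whose innermost beads (the planted patch)
  are translated far outside the blob in the "opened" state; the patch
  is the ground-truth newly-exposed set. Its rASA maxima are the
  isolated-bead areas, appropriate to the toy geometry.
* `gen_profiles_and_sequences()` plants APR score runs well above
  threshold on a background well below it, plus random sequences and
  mutation strings guaranteed to validate.

All generators are bit-reproducible given a seed and restore the
caller's RNG state. What passing the synthetic round trips does *not*
show: real melt curves have correlated, heteroscedastic noise and
baseline curvature; real RMSD series are not hidden-Markov with
Gaussian emissions; real proteins are not bead lattices; and real
aggregation profiles have soft APR boundaries. The generators validate
the machinery, not the biology.

# Problem sizes and runtimes

The shipped tests and the acceptance script use desk-scale sizes chosen
as reasonable defaults for a laptop-class analysis: 20 replicate global
fits of 12-curve bundles (9 scans of 151 points, 3 traces of 121
points), hidden-Markov series of 10^5^ frames with 50 microstates, toy
ensembles of 60 beads and 6 frames per state, and 10^3^ random fixtures
for the counting properties. The full suite runs in a few minutes on
one CPU.

# Known limitations

* The kinetic model is strictly irreversible and three-state; partially
  reversible systems are fitted only in the sense that the reverse rate
  is unresolved, and $\Delta C_p$ is deliberately omitted, so barrier
  extrapolation far below the transition is unsupported.
* MSM quality depends on the feature: a 1-D RMSD collapses distinct
  conformations; the package assigns states, it does not verify that
  the feature separates them (the CK test is the provided diagnostic).
* LCPO-based SASA pipelines will differ slightly from Shrake–Rupley
  values; downstream results depend on SASA only through the 0.25
  threshold crossing, which buffers small algorithmic differences.
* Mutant surface hydrophobicity holds exposure fixed at the wild-type
  structure; a mutation that itself buries or exposes its site is
  outside the accounting.
* Equilibrium populations from short, high-temperature unfolding
  simulations are not equilibrium observables of the folded protein at
  ambient conditions; the MSM module is therefore validated by
  synthetic recovery, not against any published population table.
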