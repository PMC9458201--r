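---
title: "Models, estimators and design choices in cdbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in cdbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbind)
```

`cdbind` implements the full estimation chain behind a host–guest binding
study of quercetin (QUE) in two β-cyclodextrin derivatives: alchemical
free-energy estimation with restraint corrections, conformational
clustering with MM/GBSA bookkeeping, and the spectroscopic estimators
(fluorescence titration, T1 relaxation, DOSY diffusion, chemical-shift
perturbation).  This vignette explains each model, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open.  It states no empirical result that the test suite or the acceptance
script does not itself compute.

## Units and constants

Energies are in kcal/mol throughout, with k~B~ = 1.987204 × 10⁻³
kcal/(mol·K) and a default temperature of 298 K (the production
temperature of the alchemical simulations being emulated).  Distances are
in Å, angles in degrees at the user surface and radians internally.
Gradient strengths enter in gauss/cm and are converted to T/m (× 10⁻²)
before any diffusion arithmetic.  The standard-state volume is V° =
1660.539 Å³ (one molecule per liter at 1 mol/L); the study being emulated
is silent on this, and 1 M is the universal convention.

## Bidirectional free-energy estimation

For non-equilibrium transitions between two end states, the Crooks
fluctuation theorem links the forward and reverse work densities to the
equilibrium free-energy difference: P~F~(W)/P~R~(−W) = e^{β(W−ΔG)}.  The
maximum-likelihood estimator for ΔG given n~F~ forward and n~R~ reverse
work values is the root of the Bennett self-consistency equation, which
`cft_ml_estimate()` solves by bracketed root finding on
[min(W) − 50 kT, max(W) + 50 kT] to 10⁻¹⁰ kcal/mol.  The residual is
monotone in ΔG, so bracketing is safe; robustness was preferred over
speed, since desk-scale inputs are thousands of numbers at most.  If the
bracket shows no sign change (numerically degenerate, non-overlapping
inputs) it is widened tenfold once and then the estimator fails with a
diagnostic pointing at the overlap statistic.

Reverse works are stored in the *reverse-direction convention*: each value
is the work done along the reverse transition, so −W^R^ is the one-sided
estimate of the forward ΔG from that side.  Files written by the package
state the convention in their header.  Two properties pin the sign
bookkeeping down: swapping the two lists negates the estimate, and adding
a constant c to all forward works while subtracting it from all reverse
works shifts the estimate by exactly c.  Both are asserted to 10⁻⁹.

Uncertainties come from a stratified bootstrap: the forward and reverse
lists are resampled independently with replacement (the two directions are
independent sets of simulations), and the standard deviation of the
estimator over the resamples is reported.  The companion one-sided
Jarzynski estimator (ΔG = −kT ln⟨e^{−βW}⟩) is provided as a convergence
diagnostic only; it is biased at finite n by approximately βσ²/2 for
Gaussian work and the package documents it as such.

Overlap of the forward and mirrored-reverse distributions is summarized by
the Bhattacharyya coefficient Σ√(p~i~q~i~) on shared histogram bins
(Freedman–Diaconis on the pooled sample by default, overridable).  The
histogramming behind the original study's overlap plots is not published,
so this coefficient is a reimplementation choice and output that includes
it says so.

## Boresch restraints

Absolute binding free energies require the guest to be restrained while
decoupled, and the cost of imposing the six harmonic restraints (one
distance, two angles, three dihedrals between three guest and three host
anchor atoms) on a non-interacting guest has the closed form implemented
by `boresch_analytical()`.  The formula assumes the stiff-spring (Gaussian)
limit; `boresch_quadrature()` evaluates the restrained configuration
integral exactly (the six terms separate, so the 6-D integral factorizes
into 1-D quadratures with the r² sinθ~A~ sinθ~B~ Jacobian), and the two
agree within 0.02 kcal/mol whenever every angular width √(kT/K) stays
below ~10°.  At K = 10 kcal/(mol·rad²) the width is 13.9° and the
Gaussian approximation error reaches ~0.03 kcal/mol — outside the stiff
regime, and the test suite deliberately checks the formula only inside
it.  Each quadrature integrates over a ±12σ window clipped to the physical
domain so that adaptive quadrature cannot step over a narrow stiff peak.

Restraint *selection* follows the published recipe in its most literal
reading: each candidate restraint set is scored by the sum of its
per-degree-of-freedom standard deviations, distance in Å and angles in
radians, and the lowest total wins; the reference frame is the frame
nearest (in z-scored Euclidean distance) to the candidate's mean.  Whether
the original selection tool normalizes the per-dof dispersions before
summing is not documented, so both readings sit behind a `normalize`
switch, with the unnormalized sum as default.  Dihedral statistics are
circular (mean by resultant vector, dispersion of wrapped deviations):
traces wrap at ±180° and naive means are simply wrong at the wrap point,
which a dedicated test demonstrates.

`derive_force_constants()` inverts a trace into a usable restraint by
equipartition, K = kT/var(x).  A constant trace implies an infinite force
constant and is rejected rather than silently clipped.

The cycle assembles as ΔG~bind~ = ΔG~solv~^elec+vdw^ + ΔG~solv~^restr^ −
ΔG~prot~^elec+vdw^ − ΔG~prot~^restr^, with leg errors combined in
quadrature, and replicas aggregate as the arithmetic mean with
root-sum-square error propagation.  That propagation convention reproduces
the published ±0.76 kcal/mol exactly for the 2HP-β-CD system; for
2,6Me-β-CD the RSS of the *printed* per-replica errors is 0.7549, so the
published 0.76 must have been propagated from unrounded values — the
acceptance test therefore pins that row to ±0.01, the rounding resolution
of its inputs, and the discrepancy is documented rather than absorbed.

## Clustering and MM/GBSA bookkeeping

Pairwise RMSD uses least-squares superposition (centering plus the optimal
SVD rotation with the determinant constrained to +1), making the matrix
invariant to rigid motion of either frame.  Atom masking (e.g. host heavy
atoms only) is the caller's responsibility through an index vector;
the default is all atoms.

Clustering is the greedy neighbor-count algorithm used by `gmx_cluster`'s
gromos method: the unassigned frame with the most unassigned neighbors
within the cutoff becomes a center, its neighborhood is removed, and the
process repeats.  Neighbor-count ties are broken by the lower frame index
— the reference tool's tie behavior is unspecified, so the package picks
the deterministic choice and documents it.  A brute-force reference that
recounts neighbors from scratch each round must produce the identical
partition on random instances, and does.

MM/GBSA bookkeeping is exact arithmetic on per-structure component tables:
each binding component is complex − host − guest, the total is the sum of
the six components, and summaries are means with sample (n−1) standard
deviations over the representative structures — five structures are a
sample, not a population.  The package's contract is *closure* (component
means sum to the mean total to 10⁻⁹).  Note that one published component
table does not close under naive summation for the methylated system;
whether that reflects per-cluster weighting or a transcription issue
cannot be resolved from the printed numbers, so the package documents the
contract and does not attempt to reproduce the non-additive column.

## NMR estimators

**Inversion recovery.**  The three-parameter model B + F·e^{−xG} with
T1 = 1/G is fitted by nonlinear least squares.  The printed description of
B and F ("magnetic induction field", "spectral width") is physically
implausible for a recovery curve; they are implemented as what the
functional form makes them — baseline and amplitude, with F ≈ −2B after a
clean 180° pulse.  Initialization uses the signal at the longest delay for
B₀, the inverted amplitude for F₀, and a log-linear regression of
|signal − B₀| for G₀, with up to five seeded, jittered restarts.  Because
exact synthetic data make the residual identically zero — which the
standard NLS iterator treats as failure — fits are accepted when they
either converge or leave a residual that is zero to machine precision.
Flat series are rejected (G is unidentifiable), and the fit is invariant
to intensity rescaling to 10⁻⁹.

**Percentage change.**  The published T1 tables' "Percentage Change"
column is |T1~free~ − T1~complex~| × 100 of the values *in seconds* — an
absolute difference dressed as a percentage, but the only convention
consistent with every scalar row (e.g. 1.36 s → 1.12 s prints 24%).
`t1_percentage_change()` adopts it for table comparison, rounds half-up,
and always reports the conventional relative change alongside, clearly
labelled.  Ranged (multiplet) rows are excluded from exact reproduction:
their printed convention is ambiguous.

**Diffusion.**  Stejskal–Tanner attenuation is fitted as ordinary least
squares of ln I against γ²g²δ²(Δ−δ/3) in SI units; −slope is D.  The pulse
constants δ and Δ are not printed in the study being emulated, so the
generator documents defaults (δ = 2 ms, Δ = 100 ms, ¹H γ =
2.6752218744 × 10⁸ rad s⁻¹ T⁻¹) rather than inferring them; any consistent
(δ, Δ) pair leaves a noise-free recovery exact, since D multiplies the
whole known b-factor.  A direct nonlinear exponential fit agrees with the
log-linear estimate to 10⁻⁹ on noise-free data.

**Shift perturbations.**  Δδ = |δ~free~ − δ~complex~| per matched proton
label, rounded half-up to two decimals for table comparison with the exact
value retained.  Unmatched labels are reported missing — never zero — and
ranged rows carry interval differences flagged non-scalar.  Ranking is by
descending Δδ with lexicographic tie-break.

## Titration analysis

The 1:1 isotherm under the excess-host approximation ([CD]~free~ ≈ [CD]₀,
valid for a 25 μM guest titrated with 0.1–4.0 mM host) linearizes to the
Benesi–Hildebrand double-reciprocal form, and K~C~ = intercept/slope of
the unweighted regression of 1/ΔF on 1/[CD]₀, with the zero-concentration
point defining F₀ and excluded from the reciprocal fit.  The standard
error of K~C~ comes from first-order propagation of the coefficient
covariance.

The reciprocal transform has a well-known pathology: it inflates the
weight of the smallest enhancements, so under realistic intensity noise
the unweighted estimator is poor (its median error at 1% noise is an
order of magnitude worse than the alternatives — demonstrated, not just
asserted, in the test suite).  Two remedies ship alongside: a
ΔF⁴-weighted reciprocal regression, which undoes the transform's variance
distortion, and `fit_isotherm_nonlinear()`, a direct NLS fit of the
untransformed isotherm that agrees with the reciprocal estimate exactly
on noise-free data and beats it under heteroscedastic noise.  The
nonlinear fitter can optionally solve the exact 1:1 mass balance instead
of the excess-host approximation for validation.

`stoichiometry_check()` reports the r² of the double-reciprocal line and a
verdict with a configurable threshold (default 0.99).  A straight line is
*consistent with* 1:1 binding, never proof; data generated from a
sequential 1:2 model with well-separated constants bend the plot visibly
below the threshold.

## The synthetic-data module

Generators draw i.i.d. samples from the exact laws the estimators assume
— no dynamics are simulated — with one explicit seed per call and no
global RNG state leakage.  Defaults encode the stated experimental world:
forward/reverse works are Gaussians with means ±ΔG + βσ²/2 and common
variance σ², which satisfies the Crooks relation exactly in distribution;
titrations use the 14-point 0–4.0 mM concentration design at 25 μM guest;
inversion recovery uses a 10-delay list straddling the null point;
gradient decays use 32 gradient strengths from 0 to 60 G/cm; restraint
traces sample each degree of freedom from its harmonic Boltzmann law.
The free parameters the study does not print — δ and Δ for the diffusion
pulse sequence, the intensity scale ΔF~C~ = 40 of titrations, work σ~w~ =
1 kcal/mol (a typical per-transition spread for a small host–guest
system) — are chosen once, documented here, and not revisited.

What a green test establishes is therefore estimator correctness on
model-faithful input: i.i.d. Gaussian work (real work distributions can
be skewed and correlated across snapshots), noise-free or homoscedastic
Gaussian intensity noise, mono-exponential recovery, rigid conformers
with isotropic jitter.  It does not establish anything about sampling
quality of real simulations — the study's own coupling-leg distributions
overlap poorly, and no synthetic test can repair that — nor about
spectral processing upstream of the tabulated peak values.

## Known limitations

* The MD/DFT-dependent published numbers (MM/GBSA totals, quantum-chemical
  energies, hydrogen-bond geometries, and the absolute ΔG values as
  outputs of real simulation engines) are not desk-reproducible and are
  covered by property-based recovery on synthetic inputs instead.
* The Bhattacharyya overlap depends on binning; values are comparable
  within one binning choice only.
* The gromos tie-break (lowest frame index) is a documented convention,
  not a reproduction of the reference tool's unspecified behavior.
* Anchor-atom selection for restraints ("most stable heavy atoms", 8 Å
  candidate cutoff) is implemented as ranking by positional fluctuation
  with configurable parameters; real selections depend on trajectory
  detail the package does not consume.
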