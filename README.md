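# cdbind

Desk-scale estimators for host–guest binding of a small molecule (the
flavonoid quercetin, QUE) to β-cyclodextrin derivatives — the
hydroxypropylated 2HP-β-CD and the methylated 2,6Me-β-CD.  Binding studies
of this kind combine several independent lines of evidence, and `cdbind`
implements the analysis side of each one:

* **Non-equilibrium alchemical free energies.**  The maximum-likelihood
  (Bennett acceptance ratio) estimator under the Crooks fluctuation theorem
  `P_F(W)/P_R(−W) = exp(β(W − ΔG))` solves

  `Σ_i [1 + (n_F/n_R) e^{β(W_i^F − ΔG)}]⁻¹ = Σ_j [1 + (n_R/n_F) e^{β(ΔG + W_j^R)}]⁻¹`

  for ΔG from bidirectional work samples, with bootstrap uncertainties and a
  Bhattacharyya overlap diagnostic (`cft_ml_estimate`, `bootstrap_uncertainty`,
  `work_overlap`).
* **Boresch restraints and the double-decoupling cycle.**  The analytical
  standard-state term
  `kT ln[ 8π² V° √(k_r k_θA k_θB k_φA k_φB k_φC) / (r₀² sinθ_A0 sinθ_B0 (2πkT)³) ]`,
  restraint selection from coordinate traces (lowest summed dispersion,
  mean-nearest reference frame), equipartition inversion of traces into
  force constants, cycle assembly
  `ΔG_bind = ΔG_solv^{elec+vdw} + ΔG_solv^{restr} − ΔG_prot^{elec+vdw} − ΔG_prot^{restr}`,
  and replica aggregation (mean value, root-sum-square error).
* **Conformational clustering and MM/GBSA bookkeeping.**  Pairwise
  superposition RMSD (Kabsch), greedy neighbor-count (gromos/Daura)
  clustering under an RMSD cutoff, representative selection, and the
  per-structure decomposition `ΔG_bind = G_complex − G_CD − G_QUE` into vdW,
  Coulomb, SolvGB, Lipo, Hbond and Covalent components.
* **NMR estimators.**  Inversion-recovery T1 (`B + F·exp(−x·G)`, T1 = 1/G),
  Stejskal–Tanner DOSY diffusion
  (`I = I₀·exp(−D γ² g² δ² (Δ − δ/3))`), the percentage-change metric of
  the published T1 tables, and chemical-shift-perturbation (Δδ) tabulation
  and ranking.
* **Fluorescence titration.**  Benesi–Hildebrand double-reciprocal fit
  `1/ΔF = 1/ΔF_C + 1/(K_C ΔF_C) · 1/[CD]₀`, a nonlinear 1:1 isotherm
  cross-check, and a linearity-based stoichiometry check.
* **Synthetic data.**  Every input above can be generated with known ground
  truth (`gen_crooks_work`, `gen_titration`, `gen_inversion_recovery`,
  `gen_gradient_decay`, `gen_toy_ensemble`, `gen_restraint_timeseries`), so
  the whole chain is testable without a simulation engine or spectrometer.

## Worked example

```r
library(cdbind)

# 1. Alchemical leg: Crooks-consistent work samples with known dG
ws <- gen_crooks_work(dg_true = -5.09, sigma_w = 1.0,
                      n_fwd = 2000, n_rev = 2000, seed = 11)
estimate_work_set(ws, n_boot = 200, seed = 1)
#> dG = -5.0994 +/- 0.0164 kcal/mol  [cft_ml]  overlap=0.678

# 2. Replica aggregation of four independent cycle estimates
tab <- ref_replica_table()
me <- tab[tab$system == "2-6Me-b-CD", ]
aggregate_replicas(replica_set(me$dg_kcal_mol, me$uncertainty_kcal_mol))
#> dG = -5.0875 +/- 0.7549 kcal/mol  [replica_mean]

# 3. Fluorescence titration at the standard design (guest 25 uM)
ts <- gen_titration(kc_true = 520, dF_c = 40, conc_list = titration_design_M())
fit_benesi_hildebrand(ts)
#> Kc = 520 +/- 1.85e-12 1/M  (dF_c = 40, r^2 = 1.00000, benesi_hildebrand)

# 4. DOSY diffusion of the bound complex
fit_diffusion(gen_gradient_decay(1.9e-10))$D
#> [1] 1.9e-10

# 5. T1 relaxation before/after complexation, table convention
t1_percentage_change(1.36, 1.12)$percent
#> [1] 24
```

The aggregated −5.09 ± 0.75 kcal/mol is the reported binding free energy of
QUE in 2,6Me-β-CD (the 2HP-β-CD rows give −1.40 ± 0.76); K_C = 520 M⁻¹ and
771 M⁻¹ are the fluorescence association constants of the two systems;
1.9 × 10⁻¹⁰ m² s⁻¹ is the shared apparent diffusion coefficient that
evidences complexation; 24% is the H2 percentage change of the methylated
host's T1 table.

## Command line

```sh
Rscript inst/cli/cdbind.R simulate  --kind work --seed 3 --out work.tsv
Rscript inst/cli/cdbind.R estimate  --work-file work.tsv --n-boot 500 --seed 1
Rscript inst/cli/cdbind.R titration --in titration.csv --fit both
Rscript inst/cli/cdbind.R nmr       --mode dosy --in decay.csv
```

See `vignettes/cdbind-methods.Rmd` for the model assumptions, parameter
choices and limitations.
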