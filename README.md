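# chitinsmfs

Single-molecule elasticity and conformation analysis of chitin across pH.

Chitin — the β-(1,4)-linked N-acetylglucosamine polysaccharide of fungal
cell walls and arthropod cuticle — changes its hydration, chain conformation
and mechanics dramatically between acidic, neutral and alkaline water. In
single-molecule force spectroscopy (SMFS) a single chain is stretched
between an AFM tip and a substrate while force is recorded against
extension; the shape of the force–extension (F–E) curve below ~1500 pN
reports the strength of the water bridges that hydrate the chain, while
above ~1500 pN the elasticity is backbone-dominated and environment
independent. This package implements the complete analysis pipeline for
such experiments, plus the conformational metrics used to interpret them
with molecular-dynamics-style frames, all validated against a synthetic
data generator with known ground truth.

## The model

The entropic backbone follows the freely jointed chain (FJC), with
fractional extension given by the Langevin function of the force:

$$z_{\mathrm{FJC}}(F) = \frac{L(F)}{L_0}\left[\coth\!\frac{F l_k}{k_B T} - \frac{k_B T}{F l_k}\right]$$

with Kuhn length $l_k = 0.514$ nm for chitin and $L(F) = L_0$ for the
default inextensible backbone. On top of this, each saccharide unit
occupies one of two states: a short, water-bridged state of length
$l_u = 0.45$ nm or a long, stretched state of length $l_f = 0.54$ nm,
separated by a free energy $\Delta G$ per unit and tilted by force through
$\Delta L = l_f - l_u = 0.09$ nm. The force-dependent effective unit
length is the two-state Boltzmann average

$$l_{\mathrm{eff}}(F) = \frac{l_u}{1 + e^{(F\Delta L - \Delta G)/k_B T}} + \frac{l_f}{1 + e^{(\Delta G - F\Delta L)/k_B T}}$$

and the two-state FJC (TSQM-FJC) extension is
$z_{\mathrm{TS}}(F) = [l_{\mathrm{eff}}(F)/l_u]\, z_{\mathrm{FJC}}(F)$.
$\Delta G$ is the hydration-strength readout: fitting it per environment
quantifies how strongly water (or hydronium) bridges adjacent saccharide
units. The state populations cross at the transition force
$F^* = \Delta G\, k_B T / \Delta L$, which is where the shoulder-like
plateau appears in the F–E curve.

Conformation metrics over molecular frames: the mass-weighted radius of
gyration $R_g = (\sum_i m_i |r_i - r_{\mathrm{com}}|^2 / \sum_i m_i)^{1/2}$,
the end-to-end distance, the characteristic viscosity convention
$\eta = (10\pi N_A/3)\, R_g^3\, \rho / M$ (only ratios between conditions
are interpreted), and geometric hydrogen-bond counting (donor–acceptor
distance ≤ 3.5 Å, D–H–A angle ≥ 130°) classified as intramolecular
(solute–solute) versus intermolecular (solute–solvent/ion).

## Worked example

Simulate a pH 3-like ensemble (strong water bridging, $\Delta G = 5.53\,k_BT$),
normalize each curve at 1500 pN and refit the model:

```r
library(chitinsmfs)

spec <- synthetic_curve_spec(
  params = two_state_parameters(delta_g = 5.53),  # pH 3 conditions
  n_curves = 5, noise_sd = 10, environment = "pH3", seed = 42)
curves <- generate_fec(spec)
ncurves <- lapply(curves, normalize_curve)
fit <- fit_tsqm_fjc(ncurves, fit_configuration())
print(fit)
#> TSQM-FJC fit: delta_g = 5.534 k_BT/unit (13.83 kJ/(mol.unit)), l_f = 0.5401 nm
#>   residual RMS 0.00653 over 2083 points; converged
transition_force(fit$params)
#> 253 pN (approximately; the shoulder-plateau height)
compare_environments(list(pH5 = 8.53, pH3 = fit$delta_g_kjmol))
#>   env_a env_b delta_g_a delta_g_b ddg_kjmol ratio_percent
#> 1   pH5   pH3      8.53  13.83427  5.304274            62
```

The fitted $\Delta G$ of 13.83 kJ/(mol·unit) recovers the generating value
(5.53 k_BT × 2.5 kJ/mol per k_BT); its transition force of ~253 pN is the
plateau height expected for a strongly hydrated chain in acid; and the
pH 5 : pH 3 energy ratio of 62% expresses how far the mild-acid chain has
progressed toward its fully spread acidic state.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write tables under `results/`:

1. `01_simulate.R` — generate F–E ensembles (DI water, pH 5, pH 3) and
   frame series (spread acid chain, intermediate, collapsed alkaline).
2. `02_fit_elasticity.R` — normalize, fit per environment, compare.
3. `03_conformation_metrics.R` — R_g and end-to-end series, hydrogen-bond
   classification, normalized viscosities.
4. `04_report.R` — collate `results/summary.json`.

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_fit_elasticity.R \
  && Rscript analysis/03_conformation_metrics.R && Rscript analysis/04_report.R
```

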