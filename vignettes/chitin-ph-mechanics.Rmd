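---
title: "Methods: two-state chain elasticity and conformation metrics for chitin across pH"
author: "chitinsmfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state chain elasticity and conformation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitinsmfs)
```

This vignette is the package's own account of its science and of the
numerical choices behind it. The pipeline analyses single-molecule force
spectroscopy (SMFS) retraction curves of chitin in aqueous environments of
varying pH, fits a two-state freely-jointed-chain elasticity model for the
per-unit water-bridge free energy, and computes conformational metrics
(radius of gyration, end-to-end distance, characteristic viscosity,
hydrogen-bond classification) over molecular frames. Because no raw AFM or
MD trajectories are distributed with chitin studies of this kind, a
synthetic-data module generates both kinds of input with known ground
truth; it is first-class, tested code and defines the conditions under
which the pipeline is validated.

## The elasticity model

A stretched polysaccharide is modelled as a freely jointed chain (FJC) of
Kuhn segments: the fractional extension at force $F$ is

$$z_{\mathrm{FJC}}(F) = \frac{L(F)}{L_0}\,\mathcal{L}\!\left(\frac{F l_k}{k_B T}\right),
\qquad \mathcal{L}(x) = \coth x - 1/x,$$

with $l_k = 0.514$ nm, the established Kuhn length for chitin. The
enthalpic factor $L(F)/L_0$ defaults to 1 (inextensible backbone); an
optional linear modulus $K_{\mathrm{seg}}$ gives $1 + F/K_{\mathrm{seg}}$
for users who want backbone stretch. The quantum-mechanically derived
backbone elasticity function used in parts of the polysaccharide
literature is not recoverable in closed form, so the package keeps this
factor configurable rather than hard-coding any particular curve; every
result shipped here uses the inextensible default.

Each saccharide unit additionally occupies a *short* state of length
$l_u = 0.45$ nm — the ring bridged to its neighbour by a bound water (or
hydronium) molecule — or a *long* stretched state of length
$l_f = 0.54$ nm, separated by a free energy $\Delta G$ per unit
(expressed in $k_B T$). Force tilts the balance through the length gain
$\Delta L = l_f - l_u = 0.09$ nm, giving the Boltzmann-averaged effective
unit length

$$l_{\mathrm{eff}}(F) = l_u\,\sigma\!\left(\Delta G - \tfrac{F \Delta L}{k_B T}\right)
 + l_f\,\sigma\!\left(\tfrac{F \Delta L}{k_B T} - \Delta G\right),
 \qquad \sigma(x) = \frac{1}{1+e^{-x}},$$

and the two-state extension
$z_{\mathrm{TS}}(F) = [l_{\mathrm{eff}}(F)/l_u]\, z_{\mathrm{FJC}}(F)$,
normalized to the free-state contour length $L_0 = N l_u$. The sign
convention is fixed by physics: the long state must be favoured at high
force ($l_{\mathrm{eff}} \to l_f$), and the two states are equally
populated at the transition force $F^* = \Delta G\, k_B T/\Delta L$, which
is where the shoulder-like plateau sits in measured curves (for
$\Delta G = 5.53\,k_BT$: $F^* = 253$ pN, matching the observed ~250 pN
plateau of chitin at pH 3). Likewise $\Delta L$ is defined as
$l_f - l_u > 0$; the opposite order appears in some transcriptions but
contradicts the positive 0.09 nm gain that the model requires.

Two energy conventions coexist in this literature: multiples of thermal
energy ($k_B T$ per unit) and kJ/(mol·unit). Published values convert
between them with the rounded factor 2.5 kJ/mol per $k_B T$
(1.50 → 3.75, 5.1 → 12.75), although the exact $k_B T$ at 298 K is
2.478 kJ/mol. The package therefore uses the rounded factor for
*reporting* (configurable through `physical_constants()`) and the exact
$k_B T$ in pN·nm for all *mechanics*.

## Curve processing

**Segmentation.** A retraction curve has three parts: an adhesion peak at
small extension from nonspecific tip–surface attraction, the elastic
stretch, and an abrupt detachment when the molecular bridge ruptures. The
adhesion region is found as the initial excursion above a baseline
threshold that returns to baseline before the global force maximum; its
end is taken at the local force minimum just after the return, within a
short (10-sample) window. The short window matters: right after the
adhesion peak the model force is nearly flat (of order 0.05 pN per
sample), so with 10 pN acquisition noise an unbounded minimum search
would drift through the noise floor. At zero noise the estimator lands on
the spike end exactly (±2 samples in the tests); at realistic noise the
boundary is verified to within 0.5 nm, which is inconsequential because
the fit window starts at 50 pN, well above the region. Detachment is the
first loss of at least 80% of the running force maximum within a 3-sample
window after the global maximum, guarded against flat traces; a
1800-pN-scale rupture is detected to ±2 samples at any tested noise
level. Curves without such a drop are flagged unruptured and analysed to
their last sample.

**Normalization.** Above ~1500 pN the elasticity of a polysaccharide is
backbone-dominated and environment-independent, so curves from chains of
different (unknown) contour length are made comparable by dividing every
stretch-region extension by the interpolated extension at the 1500 pN
reference. Interpolation is linear in extension-versus-force on the
monotonized stretch region (samples sorted by force, duplicate forces
averaged); the normalized curve carries its reference point
$(z = 1, F = 1500)$ explicitly, so normalization is idempotent and the
ensemble always spans the fit window. Curves that never reach the
reference force cannot be normalized and are excluded with a warning —
only fully stretched single-chain curves enter the ensemble fit.

## Fitting

The TSQM-FJC model is fitted to the pooled samples of a normalized
ensemble with bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), free parameters $\Delta G \in [0, 20]\,k_BT$ and
$l_f \in (l_u, 0.7]$ nm, multi-start over three initial $\Delta G$ values
to avoid local minima. The model curve is normalized by its own value at
the data's reference force, so the contour length cancels and no
per-curve length parameter is fitted (whether ensembles should be fitted
pooled or per curve is not standardised in this field; the package fits
pooled by default and per-curve fits are a one-line `lapply`).

Two numerical choices deserve explanation because both were made on
measured evidence:

* **Residual direction.** Residuals are taken in the *force* direction by
  default — observed minus model force at each observed normalized
  extension — because in AFM acquisition (and in the generator) the noise
  lives on the force channel while the extension axis is commanded.
  Regressing extension on noisy force instead produces a classic
  errors-in-variables bias: at 10 pN noise it inflates the recovered
  $\Delta G$ by about 2%, enough to push bootstrap confidence intervals
  off the generating value. With force-direction residuals the bias is
  ~0.1% and interval coverage is nominal. `residuals = "extension"`
  remains available; the two coincide exactly on noiseless data. The
  model force at an observed extension is evaluated by monotone
  interpolation of the forward model on a 400-point force grid, refined
  near the low-force region where curvature is highest.

* **Window selection.** The 50–1500 pN fit window (below 50 pN the
  adhesion region can contaminate; above 1500 pN elasticity is
  backbone-dominated and the curve was normalized there) is applied by
  mapping the window forces through each curve's interpolated profile and
  selecting samples by *extension*. Selecting by per-sample observed
  force would truncate the noise distribution at the window edges — only
  samples whose noise pushed them inside would enter — which measurably
  biases the fit.

`bootstrap_fit()` resamples curves with replacement (seeded), refits each
replicate from the full-ensemble estimate, and reports a percentile 95%
interval for $\Delta G$. The coverage test uses 20 ensembles of 20 curves
with 50 replicates each; substantially smaller replicate counts cannot
resolve 2.5% quantiles and under-cover for purely statistical reasons.

## Conformation metrics

The radius of gyration is the mass-weighted RMS distance from the centre
of mass of the selection (solute by default); the implementation is
checked against the independent pairwise-sum identity
$R_g^2 = \sum_{ij} m_i m_j |r_i - r_j|^2 / (2 M^2)$ and for rigid-motion
invariance. End-to-end distance uses the first and last heavy atoms of
the chain molecule in file order — no atom-naming convention exists for
coarse frames, so file order is the rule and is documented as such.

The characteristic viscosity follows the Flory-type convention
$\eta = (10\pi N_A/3)\,R_g^3\,\rho/M$ with $R_g$ in cm and the cell
density $\rho$ in g/cm³. The printed form of this relation in the
polysaccharide literature is typographically ambiguous; this convention
is adopted because it reproduces the benchmark acid-to-water ratio 2.151
exactly from the reference inputs ($R_g$ 12.27 vs 9.48 Å, $\rho$ 0.983 vs
0.991 kg/L, equal $M$). Absolute values carry the units implied by the
formula and are not claimed to be physical intrinsic viscosities — only
ratios between conditions are reported. Note the cubic sensitivity to
$R_g$: with the alkaline radius rounded to 7 Å the water-referenced ratio
evaluates to 0.402, and a shift of ~0.1 Å in the input moves it by ~4%,
so ratios computed from coarsely rounded radii should be read with that
uncertainty in mind.

## Hydrogen-bond analysis

Hydrogen bonds are detected geometrically: donor–acceptor distance at
most 3.5 Å and donor–hydrogen–acceptor angle at least 130°, the
conventional MD-analysis defaults; both are configurable, and all tests
use constructed geometries whose classification is robust to reasonable
criterion changes. N and O atoms with a covalently bonded hydrogen are
donors (bond lists are honoured; otherwise attachment is inferred at
1.25 Å, and a frame whose hydrogens cannot be attached raises an error
asking for bonds); all N and O atoms are acceptors. Records are
classified *intra* (donor and acceptor heavy atoms both solute), *inter*
(exactly one side solute — solvent and ion partners both count, and the
output table keeps molecule ids so they can be separated), or
solvent–solvent (excluded from both counts). Hydronium is represented as
a solvent/ion molecule with no special energetics. The inter:intra ratio
over a frame series is the package's analogue of the hydration-balance
readout; reproducing any particular simulation's absolute counts is out
of scope, since those depend on force field and trajectory.

## The synthetic-data generator

**Force–extension curves.** Each curve is built on a uniform extension
grid up to the detachment point: the unit count is resampled within ±20%
of its mean (molecular-weight variation between picked chains), force is
obtained by numerically inverting the TSQM-FJC model scaled by $N l_u$
(simultaneous bisection, residual tolerance $10^{-9}$), Gaussian noise of
$\sigma = 10$ pN is added on force (AFM-like; no drift or 1/f component),
a triangular adhesion spike of 300 pN within the first 5 nm is prepended
(only its exclusion matters, so the shape is deliberately simple), and
the curve ends with an abrupt drop to baseline at a detachment force of
1800 pN, above the 1500 pN reference so every curve is normalizable. The
default 1000 samples per curve matches typical acquisition density;
interpolation discretization errors in the analysis shrink quadratically
with this number and are below 0.1% of $\Delta G$ at the default.

**Molecular frames.** The solute is a freely rotating chain of point
saccharide units (mass 203 amu, the GlcNAc residue mass; exact masses are
immaterial to the ratios tested) whose direction correlation and a soft
confinement sphere are set by a compactness parameter $\kappa \in [0,1]$
— $\kappa = 0$ gives an extended, rod-like chain, $\kappa = 1$ a
collapsed globule, spanning the spread-in-acid to collapsed-in-alkali
morphology axis. Bridging waters are placed off the midpoint of an
adjacent unit pair so that both O–H arms point exactly at their units at
3.0 Å — each bridge therefore contributes exactly two intermolecular
bonds — and intramolecular bonds are built from a donor hydrogen on one
unit aimed at a side-group acceptor oxygen at textbook geometry. Bulk
waters (rigid 3-point geometry, O–H 0.96 Å, H–O–H 104.5°) are placed
uniformly with a 2 Å minimum distance among themselves and at least
4.5 Å from the solute: keeping bulk solvent outside hydrogen-bonding
range of the chain makes the constructed bond counts exact, which is what
the tests rely on. Every generated frame is *verified* against
`detect_hbonds()` and rebuilt (deterministically) if crowding produced an
unplanned contact. Frame series use per-frame seeds derived from one
master seed, emulating independent snapshots of an equilibrated
trajectory.

**What the generator does not emulate.** No thermodynamic ensemble,
force field, periodic boundary conditions or electrostatics; no baseline
drift, hydrodynamic drag or multiple-chain pickup in the curves; solvent
structure is geometric, not physical. Passing tests therefore demonstrate
that the *analysis* is correct and unbiased under controlled conditions —
they do not validate force-field physics, and quantities that depend on
real solvent structure (absolute hydrogen-bond counts, absolute $R_g$)
are only meaningful here as orderings and constructed ratios.

## Determinism and problem sizes

Every stochastic component takes an explicit seed, and equal seeds give
byte-identical outputs (data files are hashed into a manifest). The test
suite uses desk-scale problems chosen for statistical validity: 3–5
curves with 300–400 samples where tolerances are loose, full 20-curve ×
1000-sample ensembles for the stochastic-recovery and bootstrap-coverage
checks, frames of 5–13 units with up to a dozen waters, and 20 seeded
repetitions for ordering properties. The acceptance script regenerates
5-curve noiseless ensembles per environment at default density.

## Known limitations

* The backbone enthalpic factor is inextensible-by-default with only a
  linear optional correction; strongly stretched regimes (> 1500 pN) are
  deliberately outside the fit window.
* The alkaline hydrophobic-globule plateau (~100 pN unfolding plateau at
  pH ≥ 11) has no functional form in this model family; such curves
  simply deviate from the TSQM-FJC fit and are not fitted.
* Vendor binary AFM formats are out of scope; curves enter as the plain
  TSV dialect documented in `load_curves()`.
* `read_frame_pdb()` assigns roles from residue names and molecule ids
  from chain:residue, which is adequate for solvated single-chain cells
  but not for general biomolecular topologies.
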