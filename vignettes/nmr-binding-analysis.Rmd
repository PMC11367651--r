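---
title: "Mapping binding interfaces by NMR and ITC: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping binding interfaces by NMR and ITC: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbind)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the conventions that had to be fixed where the
field leaves a choice open, and what the synthetic-data tests do and do
not demonstrate about real data.

## The experimental setting

The package targets studies of intrinsically disordered proteins (IDPs)
binding folded partners. Three observables carry most of the
information:

1. **Peak heights.** An IDP gives sharp amide peaks because its segments
   reorient fast. Residues incorporated into a large complex broaden,
   often beyond detection. The height ratio I/I₀ (complex over free) per
   residue is therefore a binding-site map.
2. **Chemical shifts.** Under fast exchange the observed shift is the
   population-weighted average of free and bound shifts, so titration
   shift changes trace the binding isotherm and yield K_D.
3. **Heats.** ITC measures the binding enthalpy directly and, when the
   isotherm has curvature, the affinity and stoichiometry.

When the complex structure is solved, residual dipolar couplings (RDCs)
and the geometry of the docked helices validate and characterise it.

## Peak broadening

`compute_broadening_profile()` matches peaks by chain and author residue
number and reports I/I₀. Two conventions matter:

- A peak present free but absent bound is treated as **complete
  broadening** (ratio 0): peak disappearance is the strongest evidence of
  incorporation into the complex, and treating it as missing data would
  delete exactly the most-affected residues from the map.
- A peak present only in the bound table is flagged and excluded — it
  cannot contribute a ratio.

`call_binding_regions()` calls maximal runs of residues with I/I₀ below a
threshold (default 0.5, the conventional "reduced below 50%" reading),
at least `min_run = 3` residues long. IDP profiles are punctuated by
prolines (no amide) and unassigned residues, so runs may bridge up to
`gap_tolerance = 1` consecutive *unmeasured* residues; a measured residue
at or above threshold always breaks a run. Overlapped peaks are the
user's responsibility: the package treats anything not in the table as
unmeasured and never interpolates.

## Combined chemical shift perturbation and K_D fitting

Shift changes of the correlated nuclei of one residue are combined into
a weighted root-mean-square,

$$\mathrm{CCSP}_{2d} = \sqrt{\tfrac{1}{2}\left[\Delta\delta_H^2 +
(\alpha_N \Delta\delta_N)^2\right]},\qquad
\mathrm{CCSP}_{3d} = \sqrt{\tfrac{1}{3}\left[\Delta\delta_H^2 +
(\alpha_N \Delta\delta_N)^2 + (\alpha_C \Delta\delta_C)^2\right]},$$

with the conventional scaling factors α_N = 0.16 and α_C = 0.045
compensating the larger ppm ranges of ¹⁵N and ¹³C′. Differences are
taken bound minus free (signs are irrelevant to the formula but the
signed trajectory feeds the linearity diagnostic below).

For a single two-state equilibrium at labeled-protein concentration *p*
and ligand concentration *c*, mass action gives the observed CCSP

$$y = \frac{a}{2p}\left[c + p + K_D - \sqrt{(c+p+K_D)^2 - 4cp}\right],$$

where *a* is the CCSP of the fully bound labeled protein.
`fit_kd_titration()` fits one shared K_D across the selected residues
with one amplitude *a_r* per residue. Because the model is **linear in
the amplitudes for fixed K_D**, they are profiled out analytically
(clamped at zero) and K_D is optimised in one dimension on a log scale —
a coarse grid over eight decades brackets the optimum and Brent's method
refines it to ~1e-12 relative. This is the same least-squares estimator
as a joint nonlinear fit, but it cannot diverge, has no starting-value
sensitivity, and is fast enough to bootstrap. On noiseless synthetic
titrations it returns the generating parameters to better than 1e-6
relative.

Uncertainties come from a nonparametric bootstrap over residue × point
cells (default 1000 resamples, seeded); a resample confined to a single
concentration cannot identify K_D and is redrawn. With only three
concentration points around K_D the percentile interval is honest about
how weakly K_D is determined — intervals spanning an order of magnitude
are the correct answer there, not a defect.

`saturation_ccsp()` inverts the binding curve to extrapolate an observed
CCSP to full saturation using one global K_D (the package does not refit
K_D per residue for the extrapolation; with per-residue K_D the
"shared-site" premise of the comparison would be abandoned).
`csp_trajectory_linearity()` is an advisory diagnostic: in two-state fast
exchange every titrated peak moves on a straight line in the
(Δδ_H, α_N Δδ_N) plane, so the leading-eigenvalue fraction of each
trajectory's positional covariance should be ≈ 1. `phospho_degree()` is
the volume fraction of the modified species from resolved peak pairs.

## RDC extraction and alignment tensors

IPAP spectra separate the two ¹⁵N doublet components; the coupling is

$$^1D_{NH} = (\delta_{IP,or} - \delta_{AP,or}) -
(\delta_{IP,iso} - \delta_{AP,iso}),$$

converted from ppm to Hz with the ¹⁵N Larmor frequency, which is a
**required argument** (`freq_n15_mhz`, e.g. ≈ 96.3 MHz on a 950 MHz
instrument): the formula is written in shifts and its scale is implicit
in the field. IPAP component ordering differs between processing
conventions, so a `flip_sign` switch exists; no global sign flip is
applied by default.

The alignment tensor is kept directly in Hz as a symmetric traceless
Saupe matrix S with D = vᵀS v for a unit bond vector v. Fitting is
linear least squares for the five independent elements via SVD;
the design condition number is reported and (near-)collinear vector sets
— e.g. the amides of a single ideal helix, which are almost parallel to
the axis — are rejected rather than silently producing a rank-deficient
tensor. From the eigen-decomposition (|S_zz| ≥ |S_yy| ≥ |S_xx|):
D_a = S_zz/2, R = (2/3)(S_xx − S_yy)/S_zz ∈ [0, 2/3]. Back-calculation
uses the Saupe contraction, which is algebraically identical to
D_a[(3cos²θ − 1) + (3/2)R sin²θ cos2φ]; the tests verify the two
formulations against each other.

`compare_ensemble()` fits **one tensor per model** (not a joint tensor):
each conformer of an NMR ensemble aligns slightly differently, and the
per-model fit is what per-model quality statistics refer to. The quality
factor is Cornilescu-style, Q = rms(D_obs − D_calc)/rms(D_obs); the
denominator convention is recorded in the output because Q values are
only comparable within one convention.

## Docking-complex geometry

**Helix axes.** The centerline is traced by weighted 4-residue Cα
windows. A plain 4-residue average (one helical turn) leaves a residual
spiral of amplitude |sin(2t)|/(4 sin(t/2)) ≈ 0.11 of the Cα radius
(t = 100° per residue), which biases the principal-component axis of an
8-residue helix by ≈ 0.6°. The window weights (1, w, w, 1) with
w = −cos(3t/2)/cos(t/2) ≈ 1.347 cancel the fundamental helical frequency
exactly, so axis recovery on generated helices of 8–30 residues is well
under 0.5°. The axis is oriented N → C.

**Oriented angles.** The unsigned angle between two axes does not
distinguish the two rotational senses of one helix about the
inter-helix connection. The package's sign is that of
(u_a × u_b)·w with w the unit vector from the midpoint of helix a to
the midpoint of helix b. This convention is order-invariant (swapping
the helices flips both the cross product and w), is recorded in the
output, and is realised exactly by the `make_two_helix_complex()`
generator, which places helix b's axis by rotating helix a's axis about
w. Published signed angles rarely state their convention, so
cross-study comparisons should use a generous tolerance.

**Ensemble RMSD.** Every model pair is superposed by Kabsch rotation
(SVD with reflection guard) on the selected atoms; the reported statistic
is the **mean pairwise RMSD**, with RMSD-to-the-mean also computed. For
docking ensembles the meaningful selection is the ordered parts —
backbone N/Cα/C′ of the folded core and the docked helix — and is fully
configurable; "ordered parts" selections are rarely printed exactly, so
reproduced values are selection-dependent.

**Contacts and restraints.** A residue pair is in contact in a model if
any heavy-atom pair is below the cutoff (default 5 Å, a common
NOE-consistent definition); occupancy over models separates contacts
present in all models from transient ones. CYANA `.upl` restraints use a
single continuous numbering, so a chain map (residue ranges per chain)
resolves molecule identity; classification bins same-chain restraints by
|i−j| (0 / 1 / 1<|i−j|<5 / ≥5) and counts cross-chain restraints as
intermolecular, sub-binned per chain pair.

## The one-set-of-sites ITC model

For n identical independent sites, the bound fraction Θ after injection
k solves a quadratic in the total concentrations M_t, X_t; the cell heat
content is Q_k = n Θ_k M_{t,k} ΔH V₀. Perfusion cells expel an equal
volume on each injection, so the totals carry the instrument-style
dilution factors M_t = M₀(1 − v/2V₀)/(1 + v/2V₀),
X_t = X₀(v/V₀)/(1 + v/2V₀), and the measured injection heat includes the
displacement correction ΔQ_k = Q_k − Q_{k−1} + (dV_k/V₀)(Q_k+Q_{k−1})/2.
To first order this correction returns the heat of complex expelled with
the overfill, so summed heats conserve n M₀ V₀ ΔH (verified to 1% in the
tight-binding limit). Heats of dilution are assumed pre-subtracted; the
simulator can add a constant offset for robustness tests.

`fit_itc()` runs Levenberg–Marquardt on (n, log K_D, ΔH) with
self-starting values: ΔH from the first-injection heat per mole
injected, n from the molar ratio at half total heat, K_D = M_t/100. Two
failure modes are handled explicitly rather than returned as plausible
numbers: an isotherm whose final heats are still ≥ 80% of the maximum
has no equivalence point inside the data and is rejected as
unidentifiable; and when the Wiseman parameter c = n·M_t/K_D exceeds
1000 the isotherm is a near-step, so the fit converges (exactly, on
noiseless data) but K_D is flagged low-precision — with c ≈ 2500 and
realistic noise the relative error on K_D is far larger than on n and
ΔH, which the fit covariance reports.

The stoichiometry convention is sites per cell macromolecule: a titrant
that binds as two monomer equivalents per macromolecule appears as
n = 2.

## Synthetic data: what it does and does not show

Every generator is seeded, restores the caller's RNG state, and is a
**fixed point** of its analysis at zero noise: the analysis applied to a
noiseless synthetic dataset returns the generating parameters to solver
tolerance. Noise models are the simplest consistent with the data type —
multiplicative log-normal for peak heights, additive Gaussian for CCSP,
RDC and heats.

Problem sizes used in the test-suite: 100–120 residue broadening
profiles; 3-concentration titrations with 1–3 residues (bootstrap
default 1000 resamples; the 200-seed coverage property uses 400, where
the percentile interval is already stable); 40–50 bond vectors for
tensor fits; 8–30 residue helices; 60–70 × 1 μl ITC schedules.

Passing these tests shows the estimators are correct implementations of
their models. It does **not** show the models fit real data: real
titrations have concentration errors correlated across residues, real
broadening profiles have exchange-regime structure and overlapped peaks,
real RDC sets have alignment inhomogeneity, and real ITC baselines
drift. The accession-backed geometry checks (deposited multi-model
ensembles and restraint lists) require the deposited files themselves,
which must be supplied locally; synthetic two-helix complexes stand in
for them in the automated suite.

## Known limitations

- Two-state binding only: no ternary complexes, no slow/intermediate
  exchange lineshape analysis, no competitive ITC models.
- RDC analysis assumes rigid bond vectors; no dynamic averaging
  amplitudes, no alignment prediction from molecular shape.
- NMR-STAR support is read-only and limited to assigned chemical shift
  loops; SPARKY/NMRPipe peak-list dialects are out of scope.
- Restraint classification reports what the file contains; discrepancies
  between deposited counts and publication text are surfaced, not
  resolved.
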