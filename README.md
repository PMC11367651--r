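# nmrbind

Mapping protein–protein binding interfaces of intrinsically disordered
proteins by solution NMR and calorimetry.

When a disordered protein binds a folded partner, the residues it donates
to the complex stop behaving like a disordered chain: their NMR peaks
broaden as they tumble with the large complex, their chemical shifts move,
and — once the complex structure is solved — their geometry can be
validated against orientational data. `nmrbind` implements the
quantitative pipeline around this kind of study for people analysing
titration and docking data:

- **Peak broadening (I/I₀).** Per-residue ratios of peak heights in the
  complex to the free protein, and calling of contiguous binding regions
  (ratio < 0.5 over ≥ 3 residues by default, bridging unassigned gaps).
- **Chemical shift perturbation.** Combined CSP for ¹H/¹⁵N
  (`CCSP = √[(Δδ_H² + (0.16 Δδ_N)²)/2]`) and ¹H/¹⁵N/¹³C′ spectra, the
  two-state fast-exchange binding curve
  `y = (a/2p)[c + p + K_D − √((c+p+K_D)² − 4cp)]`, a shared-K_D titration
  fitter with per-residue saturation amplitudes and bootstrap
  uncertainties, extrapolation of partial-saturation CCSP to the fully
  bound state, and modification degree from peak volumes.
- **Residual dipolar couplings.** ¹D_NH extraction from IPAP peak
  positions, `¹D_NH = (δ_IP,or − δ_AP,or) − (δ_IP,iso − δ_AP,iso)` (ppm →
  Hz via the ¹⁵N Larmor frequency), SVD fitting of the Saupe alignment
  tensor (D = vᵀS v), back-calculation, Cornilescu Q-factors and
  per-model comparison against multi-model structure ensembles.
- **Docking-complex geometry.** Helix-axis fitting, signed inter-helix
  angles under a stated convention, mean pairwise ensemble RMSD (Kabsch),
  intermolecular contact occupancies, identification of the "more
  ordered" protomer of a docked symmetric dimer, and classification of
  CYANA distance restraints by sequence separation
  (intraresidue / sequential / medium-range / long-range /
  intermolecular).
- **ITC.** Simulation and Levenberg–Marquardt fitting of the
  one-set-of-sites isotherm, `Q_k = n Θ_k M_t ΔH V₀` with the
  displacement (overfill) correction, including the steep-isotherm regime
  where the Wiseman parameter c = n·M_t/K_D is large and K_D is flagged
  low-precision.
- **Synthetic data.** Seeded generators for every input above (ideal and
  two-helix structures, broadening profiles, CCSP titrations, RDC sets,
  ITC isotherms), so the full pipeline runs and is testable with no
  external data.

Formats: tsv peak tables, NMR-STAR assigned-shift loops (read-only),
PDB/mmCIF ensembles (via bio3d), CYANA `.upl` restraints, csv ITC data.

## Worked example

Simulate a titration in which residues 60–70 broaden out, a CSP titration
with K_D = 147 μM, and a steep ITC isotherm, then analyse each:

```r
library(nmrbind)

# binding-region call from peak broadening
sb   <- synth_broadening(120, region = c(60, 70), depth = 0.3,
                         noise_sd = 0.02, seed = 1)
prof <- compute_broadening_profile(sb$free, sb$bound)
call_binding_regions(prof, threshold = 0.5, min_run = 3)
#>   chain first last n_below
#> 1     .    60   70      11

# shared-KD titration fit (80 uM labeled protein, 3 ligand points)
ts  <- synth_titration(p = 80e-6, concentrations = c(40e-6, 80e-6, 160e-6),
                       a = c("93" = 0.2, "94" = 0.15, "95" = 0.1),
                       KD = 147e-6, noise_sd = 0.005, seed = 1)
fit_kd_titration(ts, n_boot = 1000, seed = 1)
#> Two-state titration fit (shared KD, per-residue amplitude)
#>   KD = 179 uM +- 4.9e+05 (bootstrap 95% CI 48.37-1.599e+06)
#>   residues: 93, 94, 95
#>   a (ppm): 93=0.2317, 94=0.1743, 95=0.1092

# one-set-of-sites ITC on a steep isotherm (c = n*Mt/KD >> 1000)
sched <- itc_schedule(cell_conc = 25e-6, syringe_conc = 600e-6)
fit_itc(simulate_itc(sched, n = 2, KD = 9e-9, dH = -35.6e3,
                     noise_sd = 1e-7, seed = 1))
#> One-set-of-sites ITC fit
#>   n  = 2.001 sites per macromolecule (se 0.00052)
#>   KD = 9.08 nM (se 0.3 nM)  [low precision: c = n*Mt/KD = 5509 > 1000]
#>   dH = -35.57 kJ/mol (se 0.029)
```

The broadening call recovers the 60–70 region exactly. The titration fit
returns the point estimate with a deliberately wide bootstrap interval —
three concentrations around K_D identify K_D only weakly, which is
exactly what the interval reports. The ITC fit pins the stoichiometry
(n = 2) and enthalpy tightly while flagging that at c ≈ 5500 the
dissociation constant is at the edge of what the isotherm shape can
determine.

A `bindmap` command-line interface over the same functions (subcommands
`broaden`, `ccsp`, `fitkd`, `saturate`, `rdc-extract`, `rdc-compare`,
`helix-angle`, `rmsd`, `contacts`, `restraints`, `itc-sim`, `itc-fit`,
`synth`) is installed at
`system.file("cli", "bindmap.R", package = "nmrbind")`.

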