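# holokin

Geometric ensemble analysis of CaMKII holoenzyme particles.

## What this is for

CaMKII holoenzymes — the α and β isoforms of the calcium/calmodulin-
dependent kinase central to synaptic plasticity — are rings of 12–16
subunits: a central hub of association domains with kinase domains
tethered to it by disordered linkers. In negative-stain EM projections
the kinase domains form a conformational continuum, so the informative
analysis is not class averaging but per-particle geometry: the radial
extension of each kinase domain, nearest-neighbor kinase separations,
hub symmetry, and inter-holoenzyme clustering. `holokin` provides:

* a **synthetic holoenzyme generator** (`simulate_ensemble()`,
  `simulate_field()`, `simulate_dose_response()`) with ground-truth
  labels for every subunit state (extended / dimerized / compact), hub
  stoichiometry (12/14/16-mer), clustering, and pixel-scale noise;
* the **measurement conventions** (`kinase_radius()` with the appended
  2.25 nm domain radius, `linker_extension()` via the
  subtract-(2.25 + 5.5 + 2.25) nm rule, `neighbor_separation()` to the
  nearest clockwise neighbor);
* **state classifiers**: compact (< 10 nm radius), dimer (4.5/5/6 nm
  separation cutoffs), an angular-Fourier hub symmetry census
  (`classify_stoichiometry()`), and 1.5×-diameter cluster detection;
* **ensemble statistics**: Gaussian summaries with one-sided 95%
  envelopes (mean + 1.96 SD), F-then-Welch two-sample comparison, and a
  Monte-Carlo test for excess short separations against the dimer-free
  null;
* a **Gaussian-chain polymer null** for linker extensions
  (RMS end-to-end = b·√N);
* **cooperative-activation analysis**: variable-slope Hill fits
  `v = Vmax·c^h/(EC50^h + c^h)`, extra-sum-of-squares F comparison
  between isoforms, Michaelis–Menten fractional velocities
  `S/(Km + S)`, and stochastic trans-autophosphorylation on the ring.

## Worked example

Simulate a β-isoform-like ensemble, run every measurement stage, and
fit an activation curve:

```r
library(holokin)
rep <- run_pipeline(beta_config(), n_particles = 1000, seed = 1,
                    dose_response = list(vmax = 1, ec50 = 14.6e-9,
                                         hill_h = 1.64))
print(rep)
#> <pipeline_report> 1000 particles (seed 1)
#>   kinase radius: 16.8 +/- 3.3 nm (SEM 0.03), 95% envelope 23 nm
#>   linker extension: 6.8 nm (chain b = 0.711 nm over 92 residues)
#>   neighbor separation: 8.8 +/- 5.8 nm
#>   compact: 1.8%; dimers: cutoff_4.5_nm 24.8%, cutoff_5.0_nm 29.3%, cutoff_6.0_nm 38.1%
#>   local concentration (12-mer): 1.00 mM
#>   census: called_6 92.70%, called_7 4.20%, called_8 0.30%, called_ambiguous 2.80%
```

Reading the numbers: the recovered kinase radius distribution
(16.8 ± 3.3 nm) implies kinase domains range out to a 95% envelope of
~23 nm; subtracting the hub radius and two kinase radii leaves a mean
linker extension of 6.8 nm, equivalent to an effective chain step of
0.71 nm over the 92-residue linker. Twelve kinase domains inside the
swept sphere give a ~1.0 mM local concentration (the α-like 12.6 nm
radius gives ~2.4 mM); at a substrate Km of 10 μM both sit at
saturation (99.01% vs 99.50% of Vmax):

```r
local_concentration(12, 16.8)                 # 1.00 mM
local_concentration(12, 12.6)                 # 2.38 mM
100 * mm_fractional_velocity(2e-3, 10e-6)     # 99.50
100 * mm_fractional_velocity(1e-3, 10e-6)     # 99.01
```

The hub census calls 92.7% sixfold (12-mer), with the rare eightfold
(16-mer) class and an ambiguous rejection bin. See the vignette
(`vignettes/holoenzyme-geometry.Rmd`) for the models, thresholds and
known limitations, including which features of real micrograph data the
generator deliberately does not emulate.

A thin command-line wrapper over the same pipeline lives at
`inst/scripts/run_pipeline.R`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the Hill slope recovered from synthetic α-isoform activation
data, the EC50 (nM) recovered from synthetic β-isoform data, and the
percentage of hubs called eightfold by the symmetry census on a
17,000-particle β-like ensemble, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
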