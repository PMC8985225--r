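---
title: "Geometric ensemble analysis of CaMKII holoenzymes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric ensemble analysis of CaMKII holoenzymes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holokin)
```

## The measurement problem

CaMKII holoenzymes are rings of 12–16 subunits: a central hub of
association domains (a 6-, 7- or 8-fold ring of vertical dimers, ~11 nm
outer diameter) with kinase domains (~4.5 nm diameter) tethered to it by
intrinsically disordered linkers. Because the linkers are flexible, the
kinase domains form a conformational continuum rather than a small set
of discrete classes, so averaging-based image analysis fails and the
informative statistics are *per-particle geometric measurements* taken
on single negative-stain EM projections: the radial extension of each
kinase domain, the distance to its nearest clockwise neighbor, and
whether hubs of neighboring holoenzymes sit within interaction range.

`holokin` implements that measurement calculus together with a
synthetic-particle generator that emulates the statistical structure of
such measurements with ground-truth labels, so every classification
stage can be benchmarked by parameter recovery.

## Measurement conventions

All coordinates are 2D (the projection plane), in nanometres, with the
image-frame convention *x right, y down, angles clockwise-positive*,
stated here once and honored by the "nearest clockwise neighbor"
definition. The conventions are:

* **Kinase radius** — distance from the hub center to a kinase-domain
  center, plus an appended 2.25 nm kinase-domain radius
  (`kinase_radius()`).
* **Linker extension** — kinase radius minus the hub ring radius
  (5.5 nm) minus twice the kinase-domain radius:
  `extension = r − 2.25 − 5.5 − 2.25` (`linker_extension()`). Negative
  values are reported as-is. Note that a kinase radius of exactly 10 nm
  corresponds to zero linker extension, which is why 10 nm is also the
  compact-state cutoff.
* **Neighbor separation** — Euclidean distance from each kinase center
  to the angularly next center in clockwise order about the hub
  (`neighbor_separation()`). Every subunit contributes exactly one
  distance, so the statistic is direction-invariant as a multiset;
  angular ties are broken by radius, then index.
* **Compact state** — kinase radius below 10 nm (steric contact range
  between kinase and hub; `classify_compact()`).
* **Kinase-domain dimers** — neighbor separations below center-to-center
  cutoffs of 4.5 nm (the crystal-dimer distance), 5 nm, and 6 nm (the
  maximal interaction distance); fractions are nested by construction
  (`classify_dimers()`).
* **Clustering** — a holoenzyme is clustered when another hub center
  lies within 1.5 × the particle diameter; clusters are connected
  components of this proximity graph (`detect_clusters()`). The
  particle diameter defaults to 2 × the ensemble mean kinase radius,
  a choice this package makes explicit because "diameter" is otherwise
  underdefined for a fuzzy-halo particle.

Distances are carried at full precision internally and reported at
0.1 nm; fractions at 0.1%.

## The synthetic generator as a stated world

`simulation_config()` fixes the generator's world; the defaults *are*
the measured ensemble statistics of the two isoforms
(`alpha_config()`: radius 12.6 ± 1.6 nm, 31-residue linker, hub census
88/5.2%; `beta_config()`: 16.8 ± 3.3 nm, 92 residues, 92.7/5.5/0.4%).
Per particle:

1. The symmetry order is drawn from the stoichiometry mixture. The
   mixture may sum to less than 1; the remainder becomes an
   **ambiguous** class whose hub vertices receive 3× positional jitter,
   giving the census stage a rejection class (the empirical census
   percentages do not sum to 100% either).
2. Hub vertices are placed at exact equal angles on a 5.5 nm circle
   with a uniform random phase.
3. Subunit states: adjacent index pairs become **dimers** with the
   configured pair probability; remaining subunits become **compact**
   at the conditional rate that preserves the marginal compact
   fraction; the rest are **extended**.
4. Extended subunits: the measured radius is drawn from
   `Normal(radius_mean, radius_sd)` truncated below at
   `hub_radius + kinase_radius` = 7.75 nm (a kinase center cannot sit
   inside the hub), and the azimuth is uniform — the
   `gaussian_radius` model, the default because the measured radius
   distributions are apparently Gaussian. The alternative `chain`
   model instead displaces each subunit from its anchor vertex by a
   projected 3D Gaussian-chain vector (below). No generative model is
   observable in projection data, so both are explicit constructions.
5. Dimer pairs sit at a midpoint drawn from the extended radial model,
   with the two centers straddling it at `dimer_separation`
   (default 4.5 nm) along a uniformly oriented axis. Compact subunits
   get a measured radius Uniform(7.75, 10) nm.
6. Isotropic Gaussian noise (`noise_sd`, default 0.437 nm = one pixel
   at the 4.37 Å calibration) is added to every coordinate, last.
   Ground-truth labels are recorded before noise.

Determinism: one integer seed per run, one sequential RNG stream;
identical `(config, seed)` give bit-identical output.

What the generator does **not** emulate: kinase–kinase excluded volume,
anchoring correlation between a subunit's azimuth and its hub vertex
(in the default model), stain texture or the contrast transfer function
(rendered micrographs are idealized Gaussian blobs), 3D→2D
foreshortening of dimer separations, and subunit exchange. A green
recovery test therefore establishes that the *measurement and
classification stages* are faithful, not that the generator is a
complete physical model of the specimen.

## The polymer null

The linker null model is a freely jointed Gaussian chain: RMS
end-to-end distance `b·√N` for `N` residues of effective step `b`
(`expected_end_to_end()`), with `b` calibrated from a measured mean
extension as `b = extension/√N` (`calibrate_step()`). Calibrating both
isoforms independently gives b ≈ 0.71 nm (6.8 nm over 92 residues)
versus b ≈ 0.49 nm (2.7 nm over 31) — a ~1.5× disagreement that the
package reports rather than hides: a single-`b` random walk cannot fit
both linkers at once, so chain-model consistency is assessed as
ratio/order-of-magnitude agreement, never as a fit. `chain`-model
sampling draws per-axis `Normal(0, b·√(N/3))` displacements; projection
to the image plane drops one axis, giving in-plane RMS `b·√(2N/3)`.

## Ensemble statistics

`gaussian_summary()` reports moments (SD with the n−1 denominator,
SEM = SD/√n) and a least-squares Gaussian fit to the 0.5-nm-bin
histogram, mirroring the fitted curves drawn on measurement histograms;
the *moments* are authoritative downstream, the histogram fit is
cosmetic. The 95% positional envelope is one-sided,
`mean + 1.96·SD` — the radius "up to" which kinase positioning is
expected — because that is the reading that reproduces both isoform
envelopes (16 and 23 nm) from their printed moments; envelopes round to
integer nm, SD/SEM to one decimal.

Two-sample comparisons use a two-sided variance-ratio F test followed
by the unequal-variance (Welch) t test, the standard two-stage recipe
for these measurement distributions; both delegate to base R and no
multiple-testing correction is applied (none is applied in the
workflows this package emulates).

`null_deviation_test()` asks whether separations are skewed toward
short distances relative to the dimer-free generator: the statistic is
the fraction of separations below 5 nm (the upper edge of the most
populated short-distance bin) and the p-value is Monte-Carlo,
`(1 + #{null ≥ observed})/(1 + n_sims)` — the add-one convention keeps
p in (0, 1] and uniform on its attainable grid under the null, at the
cost of a minimum attainable p of `1/(n_sims+1)`.

**Power in this stated world.** With 15% of subunits in planted 4.5 nm
dimers, the expected excess below the 5 nm cutoff is only about two
percentage points over a ~29% null background, against a null spread of
~1.4 points at 900 subunits: the test is correctly calibrated but has
only ~17% power there, and needs on the order of 10⁴ subunits to detect
reliably. Two stated-world features cause this: the uniform-azimuth
geometry produces many short separations by crowding alone (no excluded
volume), and an angular interloper between the members of a tight pair
masks it from the nearest-clockwise statistic roughly 40% of the time.

## Stoichiometry census

`classify_stoichiometry()` replaces mask-focused 2D classification with
an angular Fourier power reading: for vertex azimuths θⱼ,
`P(k) = |Σⱼ exp(i·k·θⱼ)|²/m` at k = 6, 7, 8. A call requires the best
order to beat the runner-up by a factor of 2 **and** to reach an
absolute coherence floor of m/2 (half the vertices in phase). The floor
matters: with only three candidate orders, pure angular noise clears a
ratio-2 spike often enough to contaminate a rare class such as the
0.4% eightfold population, whereas coherent rings at pixel-scale noise
sit far above half power; heavily jittered hubs are thus rejected as
"ambiguous" as intended. Both thresholds are this package's choices
(the workflow being emulated used visual inspection of class averages)
and are exposed as arguments.

## Cooperative activation

`fit_hill()` fits the variable-slope Hill equation
`v = Vmax·c^h/(EC50^h + c^h)` by bounded least squares on log₁₀
concentration (parameterizing log₁₀ EC50; EC50 constrained to the data
range ×[10⁻², 10²]; starts: Vmax = max(v), EC50 at the half-max
crossing, h = 1). The baseline is fixed at zero because activities are
normalized to Vmax; a free-baseline variant sits behind
`fix_baseline = FALSE`. All replicate points are fit (no averaging
before fitting). The default concentration grid spans 0.6 nM–6 μM:
with EC50s in the 15–30 nM range, sub-EC50 points are required for the
fit to be constrained at all, which is why the generator defaults to
the wider of the two plausible assay ranges.

`compare_fits_ess_f()` is the extra-sum-of-squares F comparison:
separate three-parameter fits per dataset versus a joint fit with the
chosen parameter(s) tied,
`F = ((RSS_shared − RSS_sep)/Δdf)/(RSS_sep/df_sep)`. Sharing EC50
between curves generated at 14.6 vs 30.1 nM is rejected at p < 0.001;
sharing the slope between curves at h = 1.65 vs 1.64 is not — the
qualitative pattern the acceptance suite checks across seeds.

`mm_fractional_velocity()` is the closed form `S/(Km+S)`: at
Km = 10 μM, local kinase-domain concentrations of ~2 mM versus ~1 mM
(from `local_concentration()`, `c = n/(N_A·(4/3)πr³)` over the sphere
swept by the tethered domains) give 99.50% versus 99.01% of Vmax —
the quantitative argument for why a two-fold difference in local
concentration cannot show up in autophosphorylation kinetics.
`simulate_trans_autophosphorylation()` pushes past that closed form
with a Gillespie simulation on the ring in which unphosphorylated
subunits are substrates of their two active neighbors; with substrate
depletion the local substrate concentration falls with each event
(the regime where the Michaelis–Menten picture breaks down), and
without it the mean trajectory reduces to `1 − exp(−2·k_pair·t)`,
which the tests verify against the closed form.

## Numerical and degenerate-input choices

* Truncated-normal radius draws use rejection sampling (the truncation
  point is ≥ 2.9 SD below the mean for both presets, so rejection is
  rare).
* `gaussian_summary()` flags zero-variance input as degenerate instead
  of fitting; histogram fits that fail to converge are reported as
  such with moments still valid.
* Coincident kinase and hub centers are legal (radius = 2.25 nm);
  all-coincident hub vertices are a hard error for the symmetry call.
* Field packing uses bounded rejection sampling (2000 tries per
  holoenzyme) and raises a packing diagnostic rather than looping
  forever; clustered holoenzymes are laid down in pairs (one triple for
  an odd count) between a hard-core distance (default half a diameter:
  kinase halos interpenetrate in a contacting pair, hubs do not) and
  0.95 × the clustering distance.
* Monte-Carlo p-values use the add-one convention (above); fit SEs for
  EC50 come from the delta method on log₁₀ EC50.

## Known limitations

* At the alpha ensemble moments (12.6 ± 1.6 nm) the Gaussian radial
  model itself places ~5% of extended subunits below the 10 nm compact
  cutoff, so a small planted compact fraction is not identifiable
  there by the radius threshold alone — the recovery benchmark uses a
  radial model that stays clear of the cutoff. Any Gaussian fit with
  these moments has this property; the empirical sub-10 nm tail is
  lighter than Gaussian.
* Dimer and separation *fractions* are background-dominated in a
  uniform-azimuth world (see the power discussion); dimer benchmarks
  are therefore label-recovery (sensitivity) checks, not
  fraction-equality checks.
* The mean neighbor separation of the beta-like default world lands
  near, but not exactly at, the measured 9.4 nm — azimuthal placement
  is the least constrained part of the model and agreement there is
  assessed loosely.
* The chain model treats one residue as one step with an effective
  step length; no worm-like-chain or excluded-volume physics.
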