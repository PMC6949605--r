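---
title: "Photon budgets and chip-scan analysis for fixed-target SFX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon budgets and chip-scan analysis for fixed-target SFX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfxchip)
```

## The problem

Fixed-target serial femtosecond crystallography (SFX) rasters a
pore-patterned silicon chip through an XFEL focus at the pulse repetition
rate, collecting one diffraction snapshot per pore. For weakly diffracting
samples the experiment is won or lost on background: every layer between
vacuum and crystal — graphene sealing films, polymer support films, the
enclosed buffer, the gas atmosphere — scatters photons onto the detector.
This package provides the quantitative toolbox around that experiment:

1. a **scattered-photon budget** for layered enclosures,
2. **Poisson crystal-loading statistics** connecting slurry concentration,
   pore count and hit rates,
3. a **synthetic chip-scan generator** with the statistical structure the
   analysis assumes, and
4. the **per-shot analysis pipeline**: single-photon gain calibration,
   radial profiles, median-intensity population classification, hit
   finding, chip maps, and unit-cell statistics from CrystFEL-style
   streams.

## The photon-budget model

For one enclosure layer the expected number of elastically scattered
photons per pulse is

$$N_\mathrm{scat} = \frac{N}{A_b}\, M\, \sigma_R
  = N \cdot n_A \cdot \sigma_R,$$

where $N$ is the number of incident photons in the pulse, $A_b$ the beam
footprint, $M$ the number of scattering units (molecules, monomers or
atoms) in the beam, $n_A = M/A_b$ their areal number density, and
$\sigma_R$ the Rayleigh scattering cross-section per unit. The beam area
cancels exactly; `n_scat()` is therefore independent of `beam_area_cm2`,
and linear in both thickness and pulse energy. Areal densities come from
$\rho N_A t / M_\mathrm{mol}$ for condensed slabs, a per-layer area
density for 2-D sheets (graphene: 2 C atoms per hexagonal cell of
$a = 2.46$ Å, i.e. $3.82\times10^{15}\,\mathrm{cm^{-2}}$ per monolayer),
and $P t / k_B T$ for ideal-gas columns. Water vapor pressure uses the
Antoine equation (A = 8.07131, B = 1730.63, C = 233.426; mmHg/°C),
times a relative-humidity fraction.

Cross-sections are computed in-package by numerical integration of the
Thomson differential cross-section weighted by squared atomic form factors
in the standard International Tables 4-Gaussian (Cromer–Mann)
parametrisation,

$$\sigma_R(Z, E) = 2\pi r_e^2 \int_0^\pi \frac{1+\cos^2\theta}{2}
  \, f_Z^2\!\big(\sin(\theta/2)/\lambda\big)\, \sin\theta \, d\theta,$$

with CODATA constants throughout, so all outputs are bit-reproducible.
Three conventions are exposed:

* `atomic_additive` (default) — the independent-atom sum
  $\sum_i n_i \sigma_R(Z_i, E)$, the convention used by standard
  compilations for compounds;
* `atomic_plus_incoherent` — adds a Compton term (Klein–Nishina with a
  Waller–Hartree closure approximation for the incoherent scattering
  function, $S = Z(1-(f/Z)^2)$; adequate for the few-percent role Compton
  plays below 12 keV, not a precision Compton model);
* `molecular` — the point-molecule coherent limit
  $|\sum_i n_i f_i|^2$, an upper bound bracketing intramolecular
  interference from above.

`calibrate_cross_section_mode()` evaluates all three against a built-in
reference set of published per-mJ totals for the standard enclosure
layers and selects the convention with the smallest median deviation;
`atomic_additive` wins and is the default.

### What the calibration shows — and a caveat

Under `atomic_additive` the carbon-film reference rows (8 graphene
monolayers, 80 nm PMMA, 5 µm Mylar at 7.5 keV) are reproduced to within
10–15%, i.e. at their printed two significant figures. The liquid-water
rows and the helium row of the same reference set are **not** reproducible
under any of the three conventions: the water entries back-solve to an
effective ~2.8 barn per molecule where every additive Rayleigh convention
gives 9–10 barn (a pattern consistent with a per-*atom* compound
cross-section having been combined with a per-*molecule* column density —
water has three atoms per molecule), and the helium entry is an order of
magnitude below the atomic value. The water-vapor entry is likewise about
two orders of magnitude above any saturated-vapor column density at 20 °C.
The package computes all of these faithfully from the stated model and
reports its own numbers; `calibrate_cross_section_mode()` exposes the
per-row ratios so the disagreement is visible rather than hidden.

```{r budget}
stack <- list(material_library("graphene", n_layers = 8),
              material_library("pmma"),                      # 80 nm
              material_library("water", thickness_cm = 20e-4))
background_budget(stack, beam_spec(7.5, pulse_energy_mj = 1))
```

The enclosed water dominates the enclosure background by more than two
orders of magnitude, which is why the analysis pipeline below is organised
around mapping the water background across the chip.

## Poisson crystal loading

Crystals settle into pores independently, so pore occupancy is Poisson
with mean $\lambda$: the total hit rate is $1-e^{-\lambda}$, the
single-crystal hit rate $\lambda e^{-\lambda}$ peaks at $\lambda = 1$
with value $1/e \approx 37\%$ (where the total hit rate is
$1 - 1/e \approx 63\%$), and $P(k\ge 2)$ is exposed as
`multi_hit_rate()`. `lambda_from_hit_rate()` inverts an observed hit rate
($0.38 \rightarrow \lambda = 0.478$; $0.08 \rightarrow 0.083$), and
`lambda_from_loading()` predicts $\lambda$ from slurry concentration,
deposited volume and pore count (e.g.
$2.2\times10^6\,\mathrm{ml^{-1}} \times 20\,\mu l / 10^5$ pores
$= 0.44$, a predicted total hit rate of 36%).

## The synthetic chip scan

`make_chip_layout()` builds the pore lattice: the stock `cxi` design is an
18 × 5 grid of 1.5 × 1.5 mm windows separated by 100 µm struts, patterned
with 15 µm pores on a 50 µm hexagonal lattice (94 500 pores); `mfx` uses a
6 × 2 grid with 100 µm spacing. The window size of the `mfx` design is not
fully specified by its source description; 1.0 × 1.5 mm is used.

`simulate_scan()` visits pores in row-major order at 120 Hz and renders
per-shot frames: an isotropic expected-photon field (Gaussian water ring
at $q = 2.0$ Å⁻¹, width 0.5 Å⁻¹ — the broad liquid-water peak — plus a
flat enclosure term), Poisson pore occupancy, Bragg spots for occupied
pores (Poisson-many disk peaks of radius 1–2 px with log-normal peak
intensities, median 150 photons; countable peaks, not a reciprocal-lattice
model), integer Poisson photon statistics, ADU gain with Gaussian read
noise, and 5% pulse-energy jitter. Defaults — gain 30 ADU/photon, read
noise 3 ADU — keep the single-photon peak resolvable, which the gain
calibration requires. The three background populations seen on enclosed
chips are emulated by `three_region_scene_map()`: a frame band along the
chip edge (median 50 photons/px, the polyimide support frame), wet pockets
of enclosed buffer (median 20), and dry background (median 2), with pore
occupancy 0.28 in wet/frame regions versus 0.05 elsewhere so hits
colocalise with high water background at a rate ratio of about five.

Everything the generator knows is carried as truth columns
(`true_n_crystals`, `true_region`, `true_median_pp`), so every downstream
estimator can be scored without re-simulation. All randomness flows
through one seed; identical seed and configuration give bit-identical
scans.

What the generator does **not** emulate: crystallographically correct
Bragg geometry, detector panel gaps and per-ASIC gain variation,
common-mode noise, beam-position drift, and non-isotropic background.
Passing tests therefore demonstrate the statistical correctness of the
pipeline, not its robustness to every real-detector artefact.

## The analysis pipeline

`analyze_scan()` applies, per frame:

* **Gain calibration** (`estimate_gain()`): pools pixel values (from the
  lowest-median quarter of frames in auto mode), histograms them finely
  (the top 0.1% tail is excluded so Bragg spots cannot dominate the
  binning), finds the photon-peak spacing from the autocorrelation of the
  baseline-subtracted histogram, anchors the zero peak at the *leftmost*
  prominent mode (at occupancies near one photon/pixel the global mode is
  the one-photon peak), and refines with a shared-spacing three-Gaussian
  fit. Calibration refuses to return a number when the mode half-width is
  large against the peak spacing (merged peaks) or when there is no
  peak-to-valley contrast. Recovery is within 2% for gains 10–100
  ADU/photon at 3 ADU read noise.
* **ADU→photon conversion** with a configurable clipping floor, and
  saturation masking above a configurable ceiling.
* **Radial averaging** in equal-width $q$ bins about the beam centre,
  optionally divided by pulse energy.
* **Median intensity** per shot — the median over valid pixels, robust to
  the ≤1% pixel fraction Bragg reflections occupy — in photons px⁻¹ mJ⁻¹
  by default (a raw mode is available). The median is taken over frame
  pixels, not radial-profile bins: both were defensible; pixels are the
  more robust estimator.
* **Population classification** at the fixed thresholds: `low` < 5,
  `moderate` ∈ [10, 35], `high` > 40 photons/pixel, the gaps reported as
  `unclassified`.
* **Hit finding** with the standard serial-crystallography parameters
  (200 intensity units, SNR 6, ≥2 px/peak, ≥10 peaks/hit). The intensity
  threshold is applied to *background-subtracted* values — annulus medians
  when a geometry is supplied (the estimator that follows the steep water
  ring), tile medians otherwise — because an absolute 200 ADU threshold is
  meaningless on frames whose smooth water background alone exceeds
  1500 ADU. The SNR denominator is the local MAD-based robust sigma.

`map_shots()` arranges per-shot statistics on the pore lattice (unvisited
pores stay missing, never zero), `hit_rate_field()` smooths hit indicators
over a disk — radius 250 µm by default; the source descriptions disagree
between a 250 µm radius and a 250 µm diameter, the radius reading is used
and the parameter is fully configurable — and `colocalization_report()`
quantifies the hit/background coupling as the hit-rate ratio above versus
below a median-intensity threshold. All recorded shots enter the field,
including blanks outside the loaded area. Smoothing is an unweighted
top-hat by default with a Gaussian option.

`parse_stream()` reads the minimal CrystFEL-stream dialect (chunk
delimiters, `Cell parameters … nm, … deg` with nm→Å conversion, per-chunk
resolution limits), skipping unindexed chunks and warning on malformed
ones (strict mode errors). `cell_summary()` bins cell parameters over
chunk order and fits a linear volume/resolution trend — the dehydration
diagnostic: a shrinking unit cell over the scan indicates water loss.

## Numerical choices and problem sizes

Integration tolerances: `stats::integrate` at `rel.tol = 1e-10` for
cross-sections. The default detector is a single square 512² panel with
110 µm pixels at 27 mm — a single panel suffices because only the
radius→q mapping matters for azimuthal analysis, and the distance is
chosen so the water ring at 2 Å⁻¹ falls at ~60% of the panel half-width.
Test geometries scale the pixel pitch with the panel size to keep the
same q coverage at smaller sizes. The test and acceptance suites run
scans of a few hundred 64²–128² frames and occupancy-only scans of 10⁴
shots; these sizes give the quoted tolerances (2% gain recovery, 3
binomial SE on hit rates, ≥95% classification) with comfortable margins
and run on a laptop in well under a minute per suite.

## Known limitations

* Rayleigh cross-sections use non-relativistic Cromer–Mann form factors
  for Z ≤ 20 and omit anomalous-dispersion corrections; both effects are
  at the few-percent level below 12 keV and far below the 2-significant-
  figure use of the budget.
* The incoherent closure approximation overestimates Compton scattering
  for multi-electron atoms; the default convention does not use it.
* Liquid structure is ignored: independent-atom cross-sections
  overestimate the *coherent* scattering of liquid water at low q because
  the structure factor suppresses it. A liquid-water S(q) correction
  would need tabulated structure-factor data and is out of scope.
* The hit finder is a threshold/SNR peak counter, not an indexer; it
  cannot distinguish single- from multi-crystal hits.
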