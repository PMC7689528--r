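---
title: "Methods: spectral SAXS estimation of amyloid burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral SAXS estimation of amyloid burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssaxs)
```

## The measurement model

Spectral SAXS records elastically scattered photons simultaneously in
angle- and energy-dispersive modes: a collimated polychromatic beam (50-kVp
tungsten spectrum, dual pinholes of 2.5 and 1.0 mm separated by 160 mm)
passes through the sample, and an 80 × 80 photon-counting detector with
250-µm pixels at SDD 214 mm bins each photon into 1-keV energy bins between
6 and 50 keV. A pixel at radial distance $r$ from the beam centre observes
scattering angle $2\theta = \arctan(r/\mathrm{SDD})$ (evaluated exactly —
at these angles the small-angle approximation would be harmless, but the
exact form is just as cheap and unambiguous) and therefore momentum
transfer

$$q = \frac{4\pi E \sin\theta}{hc}, \qquad hc = 1.24\ \mathrm{keV\,nm}.$$

For a homogeneous sample of thickness $T$ along the beam, the scattered
counts factorize as
$N_s(i,j,E) = N_t(E)\, S(q_{ij,E})\, T$, where $N_t(E)$ is the transmitted
primary-beam spectrum. Scattering is treated as elastic throughout: $S$
depends on $q$ only, and inelastic (Compton) contributions are absorbed
into each phantom's smooth background component rather than modelled
separately.

## Reduction pipeline

1. **Transmission correction.** Counts are divided by $N_t(E)$, measured
   with the sample in place (beamstop removed, reduced tube current), which
   cancels the source spectrum, detector response and Beer–Lambert
   attenuation in a single step, and additionally by $T$, so that samples
   differing only in thickness reduce to identical profiles (verified to
   relative error $<10^{-6}$ in the noiseless limit). $N_t$ is a
   per-energy scalar broadcast over pixels: the transmission scan measures
   the primary-beam spot, and per-pixel flat fielding is out of scope.
   Counting uncertainty propagates as $\sqrt{N_s}/(N_t T)$. Analysis-band
   energy bins with non-positive $N_t$ are flagged `NA` with a warning and
   skipped downstream — they signal insufficient transmission statistics,
   and silently zero-filling them would bias the area statistic.
2. **q binning.** Per energy bin, unmasked pixels are assigned to
   $\Delta q = 1.2\ \mathrm{nm^{-1}}$ bins (half-open intervals
   $[q_k, q_{k+1})$, pixel-centre q values, bin centres at midpoints) and
   **averaged**, not summed. Averaging removes the annular
   pixel-multiplicity imprint of the flat detector, making profiles
   geometry-independent; because ΔAUP is a ratio, the choice does not
   affect the burden statistic, only the interpretability of intermediate
   profiles. Cells with no contributing pixel are missing (`NA`), never
   zero.
3. **Energy summation.** S(q) is summed cell-wise over the 30–45 keV band,
   skipping missing cells, with uncertainties combined in quadrature.

### Geometry defaults

Two geometric quantities are not fixed by the instrument description and
were set once, as package defaults, from the analyzable q range
(1.3–28 nm⁻¹ at 30–45 keV):

* **Beam centre at a detector corner** (0, 0 mm; configurable). A centred
  beam reaches only $r \le 14.1$ mm, i.e. $q \approx 15\ \mathrm{nm^{-1}}$
  at 45 keV; the corner placement extends the diagonal reach to ~28 mm,
  covering the full range.
* **Beamstop radius 1.83 mm** (configurable), back-solved so that the
  30-keV momentum transfer at the beamstop edge equals the 1.3 nm⁻¹ floor.

Pixel coordinates are pixel centres at $(i + 0.5) \times$ pitch for
0-based $i$; the geometry is echoed into every output file.

## Burden statistics

**AUP** is the trapezoidal integral of the energy-summed profile over
3.6–8.4 nm⁻¹, the window dominated by the 6.04 nm⁻¹ inter-sheet cross-β
reflection; window endpoints between bin centres are included by linear
interpolation. **No baseline is subtracted** — this is the
fidelity-critical choice: the additive tissue background is common to
diseased and control animals and largely cancels in

$$\Delta \mathrm{AUP} = \frac{\mathrm{AUP}_i -
\overline{\mathrm{AUP}}_{WT}}{\overline{\mathrm{AUP}}_{WT}},$$

which is exactly 0 at the wild-type level, can be negative (no amyloid
signal), and is invariant to any global rescaling of all profiles. The
broad 13.24 nm⁻¹ reflection is excluded from the burden window because it
overlaps the lipid scattering of brain tissue.

The **wild-type reference** is ambiguous between two readings — a pooled
mean over all wild-type ROIs, or a per-ROI mean over location-matched
wild-type measurements. Both are implemented; the default is `per_roi`,
which respects location matching and removes any ROI-specific anatomy from
the contrast, with `pooled` available as a config switch.

Repeat summaries use the arithmetic mean and the $n-1$ sample standard
deviation (sd 0 with a logged note for a single repeat). Peak detection
(local maxima above a prominence floor, centroid refined by a three-point
parabolic fit through the maximum bin) is a validation aid — the burden
window itself is fixed. The default prominence floor is 3× a robust noise
scale, $\mathrm{sd}(\Delta s)/\sqrt{2}$ from successive differences.
Correlation against histology is the sample Pearson coefficient with a
two-sided p-value from the t transform on $n-2$ degrees of freedom; zero
variance in either variable yields an undefined correlation, reported as
`NA` rather than a number.

## What the forward simulator emulates

* **Phantoms.** Scattering models are sums of Gaussian Bragg components
  and power-law backgrounds (`amp * (q + 0.5)^-slope`; the soft 0.5 nm⁻¹
  offset keeps the model finite at $q = 0$). Peak shapes are nowhere
  parameterized by the bench literature, so Gaussians with σ = 1 nm⁻¹
  (6.04 peak) and σ = 3 nm⁻¹ (broad 13.24 peak) are the defaults. The BSA
  surrogate carries both cross-β peaks; brain phantoms carry tissue
  background plus a broad lipid maximum near 13.2 nm⁻¹ and a 6.04 nm⁻¹
  component linear in `plaque_density`, with the coupling fixed in closed
  form so density 1 produces exactly 15% excess AUP over the plaque-free
  background — anchoring the simulator to the top of the observed burden
  scale.
* **Source and attenuation.** Kramers bremsstrahlung shape
  $\propto (\mathrm{kVp}-E)/E$, zero above 50 keV; amplitude calibrated
  once so a 10-mm tissue phantom at 600 mAs yields tens of counts per
  pixel per bin (a few 10⁶ analyzed counts per stack). Attenuation is a
  single effective $\mu(E) = \mu_{30}(E/30)^{-1}$ per phantom
  (µ₃₀ = 0.037 mm⁻¹ for tissue, water-like); the skull is folded into µ
  rather than modelled separately.
* **Counting statistics.** Per-pixel means are scaled by the plain
  solid-angle factor $(\mathrm{pitch}^2/\mathrm{SDD}^2)\cos^3 2\theta$ (no
  polarization or oblique-incidence corrections) and drawn Poisson, seeded.
  `noiseless` mode returns the exact real-valued means — it is the oracle
  for round-trip tests, where integer rounding would contaminate
  machine-precision comparisons.
* **Study structure.** The default design is 2 AD + 2 WT animals × 3 ROIs
  (H1S2, H1S3, H3S4) × 3 repeats = 36 measurements. Head repositioning
  between repeats dominates the real variability (instrument-only
  variability is below 10%), and is modelled as a multiplicative Gaussian
  factor on the effective burden, sd 0.15, truncated at 0. Latent burdens
  default to values anchored to the published burden scale: strong
  hippocampal/cortical deposition in AD (0.55–1.0), weak midbrain signal
  (0.18–0.34), zero in wild type.
* **Histology.** Sections are Boolean-disk fields: Poisson-count plaques
  with lognormal radii (median 15 µm, σ_log 0.3) on a noisy background,
  with germ intensity $\lambda = -\ln(1-f)/E[\text{disk area}]$ so the
  expected covered fraction equals the target $f$ exactly, overlap
  included. The load scale couples to the burden scale as
  load(%) = 8 × latent burden, so sSAXS and histology measure one latent
  variable — making the end-to-end correlation a parameter-recovery test.
  Amyloid load is the percent of thresholded pixels in a 1-mm circular ROI
  (pixel-centre inclusion), averaged over four slices. The positivity
  threshold is the plaque-free mean + 3 sd after background subtraction
  (the original thresholding routine is unspecified; this is the package's
  own documented default, with a fixed-value override, and load values do
  depend on it — e.g. Gaussian background tails alone produce ~0.14%
  "load" in plaque-free sections).

What the generator does **not** emulate: detector charge sharing,
fluorescence escape and pile-up (the beamstop is respected by masking, not
modelled); Compton scattering as a distinct channel; anatomical structure
within the beam (one scalar burden per location); slice-to-atlas
registration; real source filtration and detector-efficiency curves.
Passing tests therefore demonstrate the correctness and statistical
behaviour of the *pipeline*, not detector physics fidelity.

## Numerical choices and degenerate inputs

* q assignment by half-open bins; pixels outside the grid are dropped;
  energy-bin q maps are evaluated at bin-centre energies.
* AUP requires the window inside the q grid and rejects inverted windows;
  all-`NA` q bins propagate as missing.
* `delta_aup` rejects non-positive references (a corrupt wild-type set);
  `correlate_burden` requires ≥ 3 pairs.
* Parabolic centroid refinement falls back to the bin centre when the
  three-point curvature is non-negative (flat top).
* Full-run determinism: every stochastic operation takes a seed; study
  generation derives per-stack seeds from the master seed, and rerunning
  any subcommand with the same config and seed reproduces tables byte for
  byte (config MD5 hash and seeds are stamped into all outputs).

## Problem sizes used in validation

The test-suite and acceptance runs use the full 80 × 80 × 44-bin stacks at
the default 600-mAs exposure; the end-to-end parameter-recovery check runs
20 replicate 36-measurement studies (Pearson r between ΔAUP and synthetic
load ≥ 0.9 in every replicate, typically ≈ 0.99), and the histology
bookkeeping check averages 100 seeded sections. These sizes were chosen to
exercise the study design at its native scale while keeping a full
validation run in the minutes range on one core.

## Known limitations

* Profiles are in relative units; absolute-intensity calibration is out of
  scope, and all burden statistics are relative to wild type.
* The synthetic correlation (r ≈ 0.99) is tighter than what mixed
  biological variability produces in real cohorts; it validates recovery,
  not expected field performance.
* Burden-scale anchors (15% excess AUP, 8% load per unit density) are
  calibrated to the published study conditions, not to first-principles
  cross sections.
* Stacks are serialized as self-describing plain text, which is
  transparent and diff-able but bulkier than binary containers; the format
  is versioned via the package version stamped in each header.
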