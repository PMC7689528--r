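# ssaxs

Label-free estimation of brain amyloid burden with spectral small-angle
X-ray scattering (sSAXS).

Amyloid plaques — the β-sheet-rich deposits of Alzheimer's and related
diseases — diffract X-rays at characteristic momentum transfers set by
their cross-β architecture (an inter-sheet reflection near 6 nm⁻¹ and a
broad inter-strand reflection near 13 nm⁻¹). An sSAXS bench pairs a
polychromatic tube with an energy-resolving 2D photon-counting detector,
so each 300-s acquisition of a mouse head yields a 3D count stack
(80 × 80 pixels × 1-keV energy bins). This package is the complete
analysis chain for such data, aimed at preclinical small-animal studies,
plus a forward simulator of the instrument and a synthetic
Thioflavin-S histology generator so the whole pipeline can be exercised and
validated without detector hardware.

## Method

Each pixel `(i, j)` at energy `E` observes momentum transfer

```
q = 4π E sin θ / hc,          hc = 1.24 keV·nm,   2θ = arctan(r / SDD)
```

with `r` the pixel's radial distance from the beam centre and SDD = 214 mm.
The reduction implements, per measurement:

1. **Transmission correction** — scattered counts `Ns(i,j,E)` are divided
   by the transmitted primary counts `Nt(E)` (measured with and without the
   sample, no beamstop) and by the sample thickness `T`, following
   `Ns = Nt ∫₀ᵀ S(x, θᵢⱼ, E) dx`;
2. **q binning** — corrected pixels are averaged into Δq = 1.2 nm⁻¹ bins
   over 1.3–28 nm⁻¹, per 1-keV energy bin;
3. **Energy summation** — S(q) is summed over the 30–45 keV band.

Amyloid burden is quantified as the area under the energy-summed profile
over the amyloid-sensitive window (**AUP**, 3.6–8.4 nm⁻¹, trapezoidal, no
baseline subtraction) and reported as the fractional excess over the
wild-type reference mean:

```
ΔAUP = (AUPᵢ − mean(AUP_WT)) / mean(AUP_WT)
```

with mean ± sd over three repositioned repeats per location, and a Pearson
correlation against histology-derived percent-area amyloid load
(Thioflavin-S positive pixels in a 1-mm circular ROI, four slices per
location).

## Worked example

Reduce a simulated measurement of the BSA amyloid surrogate (packed bovine
serum albumin, a standard cross-β phantom) and locate its reflections:

```r
library(ssaxs)
geom    <- instrument_geometry()            # 80x80 px, SDD 214 mm, corner beam
spec    <- kramers_spectrum()               # 50-kVp bremsstrahlung source
bsa     <- make_bsa_phantom()
stack   <- simulate_stack(bsa, geom, spec, exposure = 600,
                          mode = "poisson", seed = 42)
scan    <- simulate_transmission(bsa, spec)
profile <- reduce_stack(stack, scan, geometry = geom, grid = q_grid())
find_peaks(profile)
#>          q       height   prominence
#> 1  6.02174 1.899216e-05 1.605401e-05
#> 2 13.15446 1.633856e-05 1.340040e-05
```

The two centroids fall within half a q bin of the cross-β reference
positions (6.04 and 13.24 nm⁻¹); heights are in relative cross-section
units per nm⁻¹ (the scale cancels in ΔAUP).

A full synthetic study — 2 amyloid-bearing (AD) + 2 wild-type animals,
3 brain locations, 3 repeats with repositioning jitter, matched synthetic
histology:

```r
res <- run_study(seed = 7)
subset(res$paired, animal %in% c("AD1", "WT1"),
       c(animal, roi, delta_aup_mean, delta_aup_sd, load_mean))
#>   animal  roi delta_aup_mean delta_aup_sd load_mean
#> 1    AD1 H1S2   7.529422e-02  0.020050382 4.4254279
#> 2    AD1 H1S3   1.552864e-01  0.026124049 8.5228199
#> 3    AD1 H3S4   2.274427e-02  0.004072233 1.2876936
#> 7    WT1 H1S2   4.177795e-04  0.004053545 0.1461899
#> 8    WT1 H1S3  -4.690923e-05  0.002364415 0.1482274
#> 9    WT1 H3S4   2.911575e-04  0.004410234 0.1416055
res$correlation
#> $r [1] 0.9936402   $p [1] 8.107053e-11   $n [1] 12
```

The hippocampal location of the first AD animal shows the maximum burden,
ΔAUP = 0.155 ± 0.026 at an 8.5% histological load; wild-type locations sit
at ΔAUP ≈ 0, and ΔAUP tracks the amyloid load across all 12
location-matched records (Pearson r = 0.99).

## Command line

A thin CLI wraps the same functions
(`simulate | reduce | burden | histo | correlate | study`), driven by a
single YAML run config whose hash and seeds are stamped into every output:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ssaxs.R",package="ssaxs"))')" \
    study --seed 3 --out run1
```

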