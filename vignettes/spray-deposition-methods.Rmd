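---
title: "Quantifying spray deposition for AFM: models, statistics and design choices"
author: "spraydep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spray deposition for AFM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spraydep)
```

## The problem

Atomic force microscopy of biomolecules in air requires drying a solution
onto an atomically flat substrate. During the seconds-to-minutes of manual
deposition, proteins diffuse on the liquid--solid interface and can align
along the crystallographic directions of mica or HOPG, or self-assemble
into structures that never existed in solution; rinsing and drying also
remove weakly bound species, biasing heterogeneous samples. Microfluidic
spray deposition sidesteps both artifacts by delivering the sample as
femtolitre droplets that dry in milliseconds -- faster than a protein can
take a meaningful diffusion step.

`spraydep` implements the quantitative analysis around that idea in three
parts: (i) an ordering statistic that *detects* surface self-organisation
in AFM height maps, with a calibrated random-placement null; (ii) the
droplet physics that *predicts* drying times, and hence the diffusion
bound; and (iii) surface-occupancy statistics connecting the sprayed
concentration to what is seen on the surface. A synthetic AFM generator
with exact ground truth exercises the full chain.

## The ordering parameter

Particles are local height maxima. For each detected maximum the nearest
neighbour is found, each unordered pair is counted once, and a pair is
discarded when its length exceeds the distance from its centre point to
the nearest image border (otherwise the true nearest neighbour could lie
outside the image, biasing orientations near edges). Pair orientations
$\theta_i = \arctan(p_{i,y}/p_{i,x}) \in [-\pi/2, \pi/2]$ are binned into
$N_\mathrm{bin} = 8$ bins centred on multiples of $\pi/8$; the two
half-width end bins at $\pm\pi/2$ are one bin, since only orientation
matters. Aligning bins with the pixel grid axes minimises discretisation
artifacts.

With $N$ retained pairs and $p = 1/8$, random placement makes each bin
binomial: $\mu_\mathrm{bin} = Np$,
$\sigma^2_\mathrm{bin} = Np(1-p)$. Ordering shows up as excess variance of
the observed counts $C_i$:

$$O = \frac{\sigma^2_\mathrm{Sample} - \sigma^2_\mathrm{bin}}
           {\mu_\mathrm{bin}^2},
  \qquad
  \sigma^2_\mathrm{Sample} = \frac{1}{N_\mathrm{bin}}
    \sum_i (C_i - \mu_\mathrm{bin})^2,$$

normalised by $\mu_\mathrm{bin}^2$ because an ordering *signal* scales
with the counts themselves. $O$ ranges from
$-(N_\mathrm{bin}-1)/N$ (perfectly flat histogram) to
$(N_\mathrm{bin}-1)(1 - 1/N)$ (all pairs in one bin); small negative
values are expected noise, not a pathology. The central-limit estimate of
the spread is

$$\sigma_O = \frac{\sigma^2_\mathrm{bin}}{\mu_\mathrm{bin}^2}
             \sqrt{\frac{2}{N_\mathrm{bin}}},$$

and images are combined by fixed-effect inverse-variance weighting
(`combine_order`). A confidence measure against the random null uses the
standardised counts $X_i = (C_i - \mu_\mathrm{bin})/\sigma_\mathrm{bin}$,
$\sigma_x^2 = \frac{1}{N_\mathrm{bin}}\sum X_i^2$, and
$p = 1 - \Phi(\sigma_x)$. Two caveats are implemented as documented
behaviour rather than silently "fixed": under the null
$\sigma_x \approx 1$, so this p-value is about 0.16 for perfectly random
data and 0.5 only for an exactly flat histogram -- it is a confidence
measure, not a uniformly distributed test statistic; and the bin-count
convention takes $N$ = retained pairs (so $\sum C_i = N$), which keeps
the binomial null self-consistent.

### What the null calibration shows

Across hundreds of simulated random fields the combined $\hat O$ is
statistically consistent with 0 and the empirical spread of $O$ matches
the $\sigma_O$ formula to within a few percent (see
`analysis/02_ordering_analysis.R` and the acceptance suite; 200 fields of
about 450 points / 300 retained pairs on 3 x 3 um). Nearest-neighbour
pairs are not perfectly independent draws -- pairs sharing a point have
weakly dependent orientations -- which shows up as a very small negative
bias of $O$ (well under $\sigma_O$ per image). The tests bound it at the
3-sigma level of the combined estimate; users combining thousands of
images should expect the null to sit a hair below zero.

## The synthetic generator

`generate_random_field` draws a homogeneous Poisson field (count
$\sim$ Poisson(density x area), positions uniform). `generate_ordered_field`
emulates lattice-guided self-organisation: a fraction $s$ of particles is
laid down in chains whose bond angles come from the lattice orientation
set (default $\{0^\circ, 60^\circ, 120^\circ\}$, the three-fold substrate
symmetry) plus Gaussian jitter of s.d. $10^\circ (1 - s)$. The single
knob $s$ therefore moves the field continuously from the random null
($s = 0$, exactly the random generator, same RNG stream) to perfect
alignment ($s = 1$, zero jitter). The mapping from $s$ to the $O$ values
of real manually deposited samples is deliberately uncalibrated: the
published ordering values exist only as plotted points, so the generator
is a *power* instrument (is $O$ monotone in the true ordering?), not a
reproduction of any specific image.

Positions are continuous nanometre coordinates; rasterisation happens
only in `render_height_map` (Gaussian bumps at pixel centres, additive
i.i.d. Gaussian pixel noise), so ground truth is exact. Defaults --
height 0.4 nm (lognormal, sdlog 0.25), footprint sigma 5 nm -- match
monomeric protein dimensions (cross-sectional heights about 0.2-0.6 nm).
Chain spacing defaults to 20 nm: with 5 nm-sigma bumps (FWHM about 12 nm)
chain members remain resolvable as individual maxima, while staying well
below the random nearest-neighbour distance at the densities used, so
chains read as aligned bead strings the way surface-organised monomers
do. What the generator does *not* emulate: tip convolution, scan-line
artifacts, drift, or aggregation kinetics. Passing tests therefore
validate the statistics and detection chain, not instrument-specific
distortions.

## Particle detection

The map is median-filtered (3 x 3 default), then local maxima are kept if
(filtered) height exceeds a threshold and topographic prominence -- the
drop required before any connected path reaches a higher pixel -- exceeds
a noise tolerance. Prominence is computed exactly by a persistence
union-find over pixels in decreasing height order; plateaus merge into a
single peak. Both knobs default to 3x the map's robust noise (MAD),
estimated on the *raw* map -- the median filter roughly halves apparent
noise, and thresholds derived from the filtered map let smoothed noise
peaks through (we measured about half of all detections being false
positives on sparse synthetic maps with filtered-map thresholds; with
raw-map thresholds the count matches ground truth to a few percent).
The threshold additionally sits on top of the median background level.
Detection positions are pixel-precise; no sub-pixel refinement is
attempted because the pairing statistics operate at tens of nanometres.

## Droplet physics

All internal physics is SI; interfaces use fL, um, ms, cm. Liquid
defaults are water at 25 C (rho = 997 kg/m^3, gamma = 0.072 N/m); vapour
diffusivity 2.5e-5 m^2/s; saturation vapour concentration from the Magnus
relation via the ideal gas law (23 g/m^3 at 25 C).

* **Spherical caps.** Bond number $\rho g L^2/\gamma \approx 10^{-5}$ at
  the largest observed imprints, so landed droplets are spherical caps.
  `cap_volume`/`imprint_area` convert between imprint area and volume at
  the equilibrium contact angle (default 15.3 degrees, measured for the
  fluorescein model solution on glass); they are exact inverses, which is
  how landing conserves volume in the pipeline.
* **In flight.** Maxwell diffusion-limited evaporation,
  $dV/dt = 4\pi R D_v \Delta c/\rho$ (about 10 fL/ms for a 100 fL
  droplet at lab air), integrates to the $R^2$ law. Constant velocity
  over the flight (default 20 m/s, measured range 10-30); drag and
  evaporative cooling neglected -- order-of-magnitude treatment, like the
  original estimates.
* **On the surface.** Contact lines pin for contact angles below 90
  degrees, so the base radius stays fixed and the diffusion-limited rate
  $dV/dt = -(\pi a D_v \Delta c/\rho)(0.27\theta^2 + 1.30)$ is constant:
  drying time $= V/|dV/dt|$. This is the standard pinned-line
  small-angle model from the sessile-droplet literature and is
  deliberately isolated in `sessile_drying_time` so it can be swapped.
* **Air state.** The deposition happens under the spray's pressurised
  dry-N2 jet, so the drying analyses use $\Delta c = c_\mathrm{sat}$
  (RH 0 at 25 C). This choice is anchored by the measured drying of the
  reference droplet: 100 fL / about 200 um^2 dries in about 5 ms, and the
  pinned-line model gives 5.4 ms in dry air (within 10%), versus about
  2x longer at RH 0.5. The generic `air_state()` default remains
  25 C / RH 0.5 for equilibrated lab air; sensitivity to +/-2 C and
  +/-10% RH is a first-class output (`drying_time_sensitivity`).
* **Ensembles.** Initial volumes are lognormal, parameterised by the
  measured median (100 fL) and IQR (40-210 fL) of fluorescein imprints:
  meanlog = log(median), sdlog = log(q3/q1)/(2 z_{0.75}). The printed
  median and quartiles are slightly inconsistent with a single lognormal
  (geometric mean of the quartiles is 91.7 fL); we honour the median
  exactly and let the quartile ratio set the width. Droplets that dry out
  mid-flight are counted and excluded from landed summaries. The
  pipeline's median drying time comes out in the low milliseconds
  (about 4 ms at the default 4 cm / 20 m/s), consistent with the
  published 0.7-4.3 ms interquartile scale; the exact published
  distribution depends on supplementary modelling details that are not
  available, so the package reports its own distribution and does not
  arbitrate (the published main text and methods themselves quote 4.3
  and 4.6 ms for the upper quartile).
* **Coalescence.** A droplet landing on a still-wet predecessor
  coalesces. Expected wet coverage = arrival rate x drying time x mean
  imprint / footprint, with footprint $\pi(d\tan(9^\circ))^2$ (18-degree
  full cone). Regime I (resolved droplets) below 5% wet coverage by
  default; coalescence probability from a Boolean overlap model,
  $1 - e^{-4\,\mathrm{coverage}}$. At 300 ul/h, 250 fL droplets and a
  15 ms window this gives 5000 droplets per window covering under 1% of
  the footprint at 4 cm -- no coalescence, consistent with observation.

The headline consequence: drying times of a few ms and interfacial
diffusion constants of 0.1-0.3 um^2/s bound surface displacement by
$\sqrt{4Dt}$, i.e. about 40 nm (24-59 nm across the drying-time IQR) --
smaller than typical inter-particle distances, hence no time to
self-organise.

## Surface occupancy

For a Poisson surface of intensity $\lambda$ the mean nearest-neighbour
distance is $1/(2\sqrt\lambda)$. The deposition model is linear:
$\lambda = C N_A V_\mathrm{sprayed}\,\epsilon / A_\mathrm{footprint}$,
with a single free sticking efficiency $\epsilon$ (default 1) standing in
for everything the minimal model ignores (partial transfer, overspray);
`fit_deposition_efficiency` recovers it from measured distances by least
squares. Cross-sectional particle heights are peak value minus the median
of a local background annulus (default inner radius about 3 particle
sigmas, 4 px wide; median for robustness to neighbours in the annulus),
which makes them invariant to map offset and slow tilt. The height
distribution must be independent of deposition density -- the signature
that deposition does not alter assembly state -- and is tested as such.

## Numerical and interface choices

* Angles: $p_x = 0$ maps to $+\pi/2$ (merged end bin); a value exactly on
  a bin edge goes to the higher bin.
* Nearest-neighbour ties break to the lowest index; coincident maxima are
  excluded and counted. NN queries use an exact grid-bucket search
  (ring-bounded); an all-pairs brute force serves as the test oracle.
* Distances are computed in nm (`position x pixel_size`, pixel-centre
  convention); border distance is to the nearest map edge in nm.
* Degenerate inputs fail loudly: empty histograms, zero footprints,
  sub-window maps, ragged ASCII rasters. Fewer than 2 maxima yields an
  empty pair set with a warning (an image with one molecule is data, not
  an error). Saturated air returns an infinite drying time rather than
  NaN.
* TIFF output is single-strip 32-bit float (the reading side uses the
  `tiff` package; heights round-trip exactly at single precision); the
  ASCII format round-trips doubles bitwise. Pixel sizes are never read
  from TIFF metadata -- instrument tags are unreliable -- and must be
  supplied.
* Reproducibility: every stochastic entry point takes a seed; multi-part
  analyses derive child seeds from one master via `split_seed`, and
  `run_pipeline` writes the resolved configuration, seed and
  discarded-pair counts next to its outputs. Reruns are byte-identical.

## Problem sizes

The shipped analyses and tests use 2-3 um synthetic fields at 50-120
particles/um^2 (a few hundred maxima per map, matching the statistics of
single AFM frames), 200-field null calibrations, 10 seeds per ordering
strength, 20 fields of 10^4 points for the point-process checks, and
4000-droplet ensembles. These sizes give sub-percent Monte Carlo error on
every reported mean while keeping a full run in well under a minute.

## Known limitations

* The sessile model is the pinned-line, diffusion-limited small-angle
  approximation; evaporative cooling, Marangoni flow and solute effects
  are out of scope.
* The p-value is the published expression, reported as defined; its null
  distribution is not uniform (see above).
* The deposition model is the minimal linear reading; the efficiency
  parameter absorbs all unmodelled loss and is only identifiable with
  multi-concentration data.
* No fibril tracing, periodicity, or 2D-Fourier ordering metrics; no
  vendor AFM file formats; no tip-shape deconvolution.
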