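---
title: "Monte Carlo dosimetry of an Ir-192 HDR source in heterogeneous phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dosimetry of an Ir-192 HDR source in heterogeneous phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-dose-rate (HDR) brachytherapy delivers dose from a miniature Ir-192
source placed in or near the tumour.  Clinical dose calculation follows the
TG-43 formalism, whose parameters are defined in water; real anatomy
contains lung (density far below water) and cortical bone (far above), and
the question this package addresses is how much the dose distribution in
those media, and across planar interfaces between them, departs from the
water-based picture.  The package re-implements the whole simulation study
as tested code: a photon-transport Monte Carlo engine, TG-43 parameter
extraction, interface dose comparisons with isodose contours, and a
synthetic point-dosimeter stage standing in for physical film and glass
dosimeter measurements.

## Source model

The source is the active core of a microSelectron-type Ir-192 HDR source: a
0.6 mm diameter by 3.5 mm long iridium cylinder.  Emissions are sampled
uniformly over the active volume and isotropically in angle, from a
five-line spectrum (290, 308, 317, 468, 608 keV with intensities 14.34,
14.69, 40.96, 23.46, 6.55 per cent; mean 366.29 keV).  Three deliberate
modelling choices:

* **No encapsulation or cable.**  Only the bare active pellet is modelled;
  capsule attenuation and the cable shadow are out of scope.
* **Primary self-absorption in the pellet, on by default.**  The line
  intensities are renormalised decay intensities, so attenuation inside
  the iridium metal is not yet accounted for.  Each primary is attenuated
  over its chord from the emission point to the pellet surface by
  rejection sampling (absorbed photons deposit inside the source).  This
  is what gives the anisotropy function its near-axis structure: photons
  leaving along the long axis traverse up to ~1.75 mm of iridium
  (attenuation factor of several), transverse photons a fraction of the
  0.3 mm radius.  With `self_absorption = FALSE` the package recovers a
  bare effective-source model whose geometry-corrected angular profile is
  flat — useful for isolating medium effects, but unable to reproduce any
  anisotropy observation.  Scattered photons re-entering the sub-millimetre
  pellet are neglected either way, and the iridium attenuation values
  (packaged over 100-800 keV) are approximate, interpolated in atomic
  number from neighbouring high-Z elements; only the primary rejection
  step uses them.  Normalised transverse-axis quantities — g(r), dose
  ratios, interface profiles — are insensitive to the whole mechanism,
  because the pellet factor toward the transverse axis is independent of
  radius and cancels in every ratio.
* **Five lines, not the full ~110-line spectrum.**  The reduced spectrum is
  the stated simulation input; its 366.29 keV mean sits within 1 per cent
  of the ~370 keV average usually quoted for the full spectrum, so
  energy-averaged quantities are essentially unchanged.

```{r}
library(irbrachy)
src <- source_spec()
src$spectrum
```

## Materials

Three ICRU-44-style media are packaged: liquid water (1.00 g/cm3), cortical
bone (1.92 g/cm3) and inflated lung (0.26 g/cm3).  Each CSV table under
`inst/extdata/` holds, on a 31-node log grid spanning 10-800 keV, the total
mass attenuation coefficient, a photoelectric/incoherent/coherent channel
decomposition, and the mass energy-absorption coefficient.  Lookups use
log-log interpolation, the standard treatment for photon cross sections
(sub-percent accurate on a grid this dense).

Provenance, stated plainly: the water and cortical-bone totals and
energy-absorption values are transcribed from the standard NIST compound
tables; the inflated-lung table is constructed from the water table by
electron-density scaling of the Compton channel and effective-atomic-number
scaling of the photoelectric and coherent channels (ICRU-44 lung
composition); and the per-channel split is a physically parameterised model
(Klein-Nishina times electrons-per-gram with a low-energy binding
suppression factor; the remainder partitioned between photoelectric and
coherent by a two-term power-law fit), constrained so the three channels
sum to the transcribed total at every node.  Dose observables depend on the
total attenuation and energy-absorption columns; the channel split only
steers the relative frequency of interaction types.  Tests assert the
structural invariants: channels sum to the total within 1 per cent,
energy absorption never exceeds total attenuation, water attenuation
decreases monotonically over 100-700 keV, and interpolation reproduces
nodes exactly.

## Phantoms

All phantoms are 25 x 25 x 25 cm3 cubes centred on the source.  Interface
presets (`water_lung`, `bone_lung`) add one planar interface perpendicular
to the transverse measurement axis (+x), parallel to the source long axis,
with the denser medium on the source side and inflated lung beyond.  The
published experiment prints no slab dimensions, so the source-to-interface
distance is an explicit parameter with default 1 cm.  Tie-breaks are
arbitrary but fixed: a point exactly on the interface belongs to the lung
side, a point exactly on the cube face is inside.

## Transport and scoring

Photons are tracked by delta (Woodcock) tracking against the per-energy
majorant attenuation coefficient — exact in heterogeneous geometry with no
boundary ray tracing.  At a real collision the channel is chosen in
proportion to the partial coefficients:

* **Photoelectric**: full local energy deposit, history ends.
* **Incoherent**: scattered energy and angle from the free-electron
  Klein-Nishina distribution via Kahn's rejection method; the energy
  difference is deposited locally.  Neglecting the incoherent scattering
  function biases nothing appreciably above ~50 keV, well below this
  source's lines.
* **Coherent** (optional, on by default): direction change with no energy
  loss, angle from the Thomson distribution weighted by a screened
  hydrogen-like form factor with characteristic momentum transfer
  0.47 Zeff^(1/3) inverse Angstrom.  Coherent events are ~1 per cent of
  interactions at these energies, so this simple angular model suffices.

Secondary electrons are not transported: their CSDA range at <= 885 keV is
sub-millimetre, below every bin size, so energy transferred to electrons is
deposited at the interaction point (collision-kerma approximation).
Photons below the 10 keV transport cutoff deposit their remainder locally.
No variance reduction beyond the estimator below is used.

Two estimators are provided.  The **analog** estimator deposits energy
actually transferred at real collisions and satisfies emitted = deposited +
escaped to double precision, which the tests assert on every run.  The
default **track-length** estimator scores expected collision kerma
(E times mu_en/rho times rho per unit track length) along every flight
segment by adaptive sub-stepping, with step length 5 per cent of the local
radius (floor 0.02 cm) to match the log-spaced radial grid.  Each sub-step
is scored at a uniformly random point within it: a deterministic evaluation
point would alias against the geometric bin structure, because every
primary flight starts at the source and would lay down the same comb of
scoring radii.  With the random evaluation point the line-integral estimate
is unbiased for any partition, which the interaction-free inverse-square
test verifies directly.

Uncertainties come from 20 independent history batches per run; the
variance of the batch means is the variance of the reported dose.  An
across-seed calibration check (independent runs versus the reported
standard error) is part of the test suite's design history; the mirror
symmetry and estimator cross-check tests would catch a mis-scaled variance
immediately.

## Scoring grids

Four grids are filled in one pass:

* **Cylindrical (r, theta)**: radial edges log-spaced at 8 bins per factor
  of two from ~0.09 to 12.5 cm, so the geometric bin centers fall exactly
  on 0.5, 1, 2, 4, 8 cm — the classic checkpoint radii are bin centers,
  not bin edges, and the bin-averaging factor cancels in every ratio of
  equal-log-width bins.  Polar bins are 2 degrees wide, arranged so 90
  degrees is a bin center (the TG-43 normalisation angle).
* **Transverse profile**: a 0.3 cm radius cylinder along the signed
  transverse axis, 0.5 cm bins centred on half-integer positions.
* **Plane**: 0.1 cm pixels on the plane containing the source transverse
  axis (a 0.5 cm slab), for isodose contours.
* **Film**: annular rings on a thin slab just upstream of the default
  interface position, emulating a film sandwiched at the slab boundary.

Bin masses integrate the local density over the bin, including the
azimuthal-fraction integral for cylindrical bins straddling the interface
plane.  Dose is energy per unit mass per emitted photon; all TG-43
quantities are ratios, so absolute units never enter.

## TG-43 extraction

The line-source geometry factor is the closed form
G(r, theta) = beta / (L r sin theta), with the on-axis limit
1/(r^2 - L^2/4) and the point-source limit 1/r^2; tests pin it to a
numerical line-integration oracle at 1e-6 relative accuracy.  g(r) and
F(r, theta) are read from the cylindrical tally with no smoothing (the bin
containing the requested point), normalised at r0 = 1 cm and theta0 = 90
degrees, which the grid design makes exact bin centers.  Media are
normalised in their own medium, since the study compares shapes across
media.

The packaged `g_reference_synthetic.csv` deserves an honest note: the
published benchmark g(r) table could not be redistributed here, so the
packaged reference was generated by this package's own engine at 2e7
histories.  The default `compare_radial_to_reference()` comparison is
therefore an internal consistency and regression check at the study's
stated 1.7 per cent level — it demonstrates estimator stability across
history counts, not independent validation.  Supplying an external
reference table through the `reference` argument turns it into the real
comparison.

## Interface analysis: two different questions

Two comparison geometries are provided because they answer different
questions and behave differently:

* **On the film plane** (`interface_film_profile()`): points on the
  interface plane see the same primary fluence in both phantoms — the ray
  from the source never crosses the interface — so the difference isolates
  the scatter that the lung half fails to return.  The deficit is fractions
  of a per cent at 1 cm and grows steadily with distance as the scatter
  fraction grows.  This matches how a film sandwiched at the slab boundary
  measures, and it is the comparison whose printed ranges the study
  reports.
* **Along the transverse axis into the lung** (`compare_profiles()`): two
  effects compete.  Just beyond the interface the missing backscatter
  dominates and the interface-phantom dose is a few per cent lower; deeper
  into the lung the reduced attenuation (mu proportional to density 0.26)
  wins and the interface-phantom dose rises above the homogeneous one.
  The crossover sits a few centimetres past the interface under the
  default geometry.  Both normalisation modes are provided
  (per-point relative, and normalised to the homogeneous dose at 1 cm)
  because published statements are ambiguous between them.

The profile bin that straddles the interface itself is reported but should
be interpreted with care: its dose is a mass-weighted average lopsided
toward the denser half, a discretisation artifact of any binned tally with
an internal density jump.  Isodose contours come from marching squares
(`grDevices::contourLines`) on the plane grid, with optional one-pass 3x3
box smoothing (off by default).

## Synthetic measurements

The measurement stage replaces the physical dosimetry: point readings at a
dual-radius, multi-angle layout are the simulated doses perturbed by
mean-one multiplicative log-normal noise (default CV 3 per cent, the scale
of both the simulation's statistical error target and typical
re-readable-dosimeter reproducibility), averaged over three repeats as the
physical protocol averaged three readings.  Multiplicative, positive noise
is the natural model for luminescent dosimetry.  The generator is exactly
unbiased (the log-normal is mean-corrected), reproducible bit-for-bit
under a fixed seed, and its stated CV is what the agreement report's
coverage is calibrated against.  What it does **not** emulate, by design:
detector energy dependence (severe for high-effective-Z glass at tens of
keV), angular dependence, volume averaging over the ~1 mm readout volume,
or film scanner response.  Passing tests therefore validate the
simulation-to-measurement comparison machinery, not detector physics.

## Numerical choices and problem sizes

* Transport cutoff 10 keV (both the stated threshold and the coefficient
  tables' lower edge); photons below it deposit locally.
* Delta-tracking majorant is the maximum material coefficient at the
  current energy, recomputed after every energy change.
* Sub-step length 0.05 r with a 0.02 cm floor; evaluation point uniform in
  the sub-step.
* 20 uncertainty batches (40 for the packaged reference run).
* Default runs in the analysis scripts and acceptance use 1e6 histories —
  enough to put the transverse-axis bins at a fraction of a per cent and
  the 12 cm bin under one per cent relative error, with single runs in
  tens of seconds; the packaged reference uses 2e7.  The study's stated
  1e8-history error target is checked by the standard sqrt(N)
  extrapolation from 1e6.
* Seeds: one integer master seed per run feeds a counter-seeded
  xoshiro256++ generator, so tallies are bit-identical for a fixed seed
  and independent of R's RNG state; R-level samplers scope their seed and
  restore the caller's RNG.

## Known limitations

* Collision kerma, not absorbed dose: no electron transport, so doses
  within ~1 mm of the source and of interfaces are approximate exactly
  where charged-particle equilibrium fails.
* Free-electron Compton and a screened-form-factor coherent model: small
  low-energy biases, irrelevant above ~50 keV.
* No absolute dose-rate constant: that requires an air-kerma strength
  calibration, a physical measurement out of scope.
* The interface study's printed ranges depend on unprinted slab dimensions;
  the package fixes a documented default geometry and reports full
  profiles, checking order-of-magnitude consistency rather than exact
  endpoint reproduction.
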