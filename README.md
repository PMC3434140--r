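# irbrachy

Monte Carlo photon-transport dosimetry for a high-dose-rate (HDR) Ir-192
brachytherapy line source in water, cortical-bone and inflated-lung
phantoms and their planar interfaces.

## The problem

HDR brachytherapy treatment planning computes dose with the TG-43
formalism, whose parameters are defined in water.  Real anatomy is not
water: inflated lung (0.26 g/cm3) attenuates and scatters far less,
cortical bone (1.92 g/cm3) far more, and planar interfaces between such
media distort the dose on both sides.  This package is for medical
physicists who want a small, fully tested simulation pipeline that
quantifies those effects: it models the source, transports photons through
homogeneous and two-region cubic phantoms, extracts TG-43 dose parameters,
compares interface against homogeneous dose distributions, and generates
synthetic point-dosimeter readings standing in for film / glass-dosimeter
validation data.

## The model in brief

The source is the 0.6 mm x 3.5 mm active iridium cylinder of a
microSelectron-type Ir-192 source, emitting uniformly over its volume and
isotropically in angle from the five principal lines (290, 308, 317, 468,
608 keV at 14.34 / 14.69 / 40.96 / 23.46 / 6.55 per cent; mean 366.29 keV).
Primary photons are attenuated over their chord through the pellet
(rejection sampling); the encapsulation is not modelled.  Transport uses
delta (Woodcock) tracking with photoelectric absorption, free-electron
Klein-Nishina Compton scattering (Kahn's method) and screened-form-factor
coherent scattering, down to a 10 keV cutoff.  Dose is collision kerma:
secondary electrons deposit locally (their range is sub-millimetre at
these energies).  The default estimator scores expected kerma along every
track segment; an analog estimator with exact energy conservation
(emitted = deposited + escaped) is kept as a cross-check.

TG-43 quantities follow the standard decomposition around a line source of
active length L:

    D(r, theta)  ~  G(r, theta) * g(r) * F(r, theta)

with geometry factor `G(r, theta) = beta / (L r sin theta)` (beta the angle
subtended by the active length), radial dose function g(r) normalised to
g(1 cm) = 1 on the transverse axis, and anisotropy function F(r, theta)
normalised to F(r, 90 deg) = 1.

## Worked example

```r
library(irbrachy)

src   <- source_spec()                     # Ir-192 HDR defaults
water <- phantom_preset("water")           # 25 cm cube, homogeneous
tally <- run_simulation(src, water, n_histories = 1e6, seed = 1)

dose_at(tally, r = c(0.5, 1, 2))           # transverse-axis dose
#>   r_cm theta_deg   dose       se
#> 1  0.5        90 3.1841 0.023437
#> 2  1.0        90 0.8060 0.006109
#> 3  2.0        90 0.2049 0.001656
```

Dose is in keV per gram per emitted photon; only ratios matter for TG-43
quantities.  The ratios D(0.5)/D(1) = 3.95 and D(2)/D(1) = 0.254 are the
line-source versions of the inverse-square factors 4 and 1/4 — the small
departures are exactly the geometry factor's finite active length.  The
relative standard error of the 12 cm transverse bin at 1e6 histories,
extrapolated by sqrt(N) to 1e8 histories, is below 0.1 per cent — far
inside the 3 per cent target usually quoted for such simulations.

```r
g <- radial_dose_function(tally)           # g(r), g(1) == 1 exactly
f <- anisotropy_function(tally, r_list = c(1, 3, 5, 10))

lung  <- run_simulation(src, phantom_preset("water_lung"), 1e6, seed = 2)
fp    <- interface_film_profile(tally, lung)   # film-plane dose deficit
```

Across media the radial dose function separates cleanly by 10 cm
(g_bone 0.71 < g_water 0.87 < g_lung 0.97 at the bin nearest 10 cm, from
`analysis/02_homogeneous_dose.R`), and on the interface plane the
water-lung phantom reads a dose deficit that grows from about 1 per cent
near the source to roughly 17 per cent at 10 cm (3 to ~28 per cent for
bone-lung): the lung half returns almost no scatter.

The `analysis/` directory holds the numbered study drivers
(`01_source_spectrum.R` ... `05_synthetic_measurements.R`); each is a thin
narrative script over the package functions that writes its tables under
`results/`.

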