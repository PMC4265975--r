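---
title: "Models and methods behind sonasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sonasim re-creates, entirely in software, the control environment of a
clinical MR-HIFU platform: a 256-element focused-ultrasound array driven
by time-indexed treatment protocols under MR-thermometry guidance. This
vignette documents the models, the defaults and why they were chosen, the
numerical choices, and what the simulation does and does not claim about
real hardware.

## Protocol and engine semantics

A treatment protocol is an ordered list of commands, each with an order
index (0-based, `0..n-1`) and a time index in seconds. These are distinct:
the order index determines execution sequence, the time index the earliest
start time. Command `i` starts at `max(end of command i-1, time_index +
offset)`, where the offset rebases protocol time to the engine clock. A
modification with a `goto` position resets that offset so the target
command starts "now" — this is what makes "restart the protocol" loops
(element scans, per-segment pattern switching) work. Pseudo-code "step 1"
and "step 3" of the reproduced experiments correspond to positions 0
and 2.

Commands with an unspecified end ("remain inactive") are pauses of
infinite duration; they end only through a goto modification. Exposure
turn-off steps are represented by finite exposure durations plus an
explicit wait-for-previous pause at the turn-off position, preserving the
five-step shape of the source protocols.

The engine's primary time base is a simulated clock (`advance_clock()`),
which makes every run bit-reproducible: identical protocols, modification
schedules and clock steps give identical event logs (this is asserted as
a property test). A wall-clock driver would simply call `advance_clock()`
with elapsed real time. Status queries are pure reads of the engine state
and are additionally logged (`status_query` events) so that
synchronization behaviour — "wait until the exposure is over by polling
status" — is auditable in the log.

Two modelling constants have no published value and are configurable
engine parameters: mechanical transducer speed (default 5 mm/s
translation, 10 deg/s rotation) so the moving/idle indicator is
meaningful, and reflected acoustic power as a fixed fraction of forward
power (default 2%), since only the existence of the indicator is
documented. Mechanical travel limits default to ±100 mm per axis and ±30°
per rotation angle. Pulsed exposures report duty-cycle-averaged forward
power.

## Acoustic model

Elements are circular discs on a spherical shell of 120-mm radius of
curvature and 130-mm aperture, packed deterministically along an
equal-area sunflower spiral (the clinical layout is proprietary; the
layout here is pluggable and seeded). Discrete circular elements cannot
tile a cap, and clinical randomized arrays are sparse; the default fill
factor is 55% of the shell area, giving 3.1-mm element radii. This
matters: with full tiling (4.2-mm radii) the element directivity would be
so narrow that ±10-mm electronic steering — which the reproduced
experiments perform routinely — would lose most of its focal intensity.

Element fields are Rayleigh–Sommerfeld integrals over the discretized
element surface,

  p(r) = (i rho c k u0 / 2pi) * sum_patches exp(-(alpha f + i k) d) / d dS,

with patches of at most lambda/8 at 1.5 MHz (0.125 mm). lambda/8 rather
than lambda/4 keeps the on-axis near field within 1% of the closed-form
baffled-piston solution, which is the accuracy bound the test suite
enforces over z in [a, 4F]. A field point closer to a patch than the
patch's own equivalent radius uses that radius as a regularized distance
instead of diverging. Steering phases are
`phi_n = k (|r_n - r_f| - F)`, wrapped to (-pi, pi]; they vanish
identically at the natural focus.

For volumetric heat-deposition maps the per-patch integral is replaced by
a far-field disc model: one source per element with the baffled-disc
directivity `2 J1(k a sin theta)/(k a sin theta)`. The elements sit ~15
Rayleigh distances (`a^2/lambda` ≈ 8 mm) from the focus, where this model
is exact up to a common Fresnel phase; focal magnitudes agree with the
patch integral to 0.2%. The acceptance-grade accuracy tests always use
the patch integral.

`acoustic_power` in a command is realized by scaling the drive so the
plane-wave intensity integrated over the element surfaces — equivalently,
over a plane just past the aperture — equals the commanded power:
`u0 = sqrt(2 P / (rho c sum_n amp_n^2 A_n))`. Heat deposition is
`Q = alpha_abs f |p|^2 / (rho c)` with attenuation in Np/m/MHz and an
absorption fraction (default 1).

The propagation medium is single and homogeneous per run (degassed water:
no attenuation; tissue-mimicking phantom: 0.5 dB/cm/MHz, a standard
phantom value). This is the model's largest deliberate simplification for
the heating-pattern experiment, where the physical beam crosses mostly
low-loss water before entering the phantom slab: whole-path phantom
attenuation under-drives the focus by roughly 3x in intensity. Because
the bioheat model is linear in Q, all *relative* statements (segment
uniformity, background fractions, power monotonicity) are unaffected; the
absolute ~10 °C phantom peak of the hardware experiment is therefore
matched qualitatively, not numerically (the simulated default-run peak is
~4.6 °C).

## Bioheat model

The Pennes equation is integrated with an explicit FTCS scheme:

  T' = T + dt/(rho c) [ k lap(T) - w_b c_b (T - T_a) + Q ],

with Dirichlet (fixed at baseline) boundaries by default and insulated
(Neumann) boundaries available for conservation checks. The scheme
refuses time steps above the stability bound `dx^2 rho c / (6 k)` and
sub-steps automatically. It is verified against three independent
oracles: the 3-D Gaussian Green's function of a point impulse (RMSE ≤ 2%
of peak once the diffusion width reaches 3 voxels), the exponential
perfusion-only relaxation (≤ 0.5%), and closed-box energy conservation
(≤ 1%).

Default phantom thermal properties are k = 0.5 W/m/K, rho c = 3.6e6
J/m^3/K, zero perfusion — generic soft-tissue/phantom values, configurable
per run.

During a steered exposure the focal point cycles through the trajectory
(an 8-s exposure over a 10-point, 25-ms trajectory makes 32 full passes);
on solver steps longer than the dwell interval, Q is time-averaged
uniformly over the trajectory points. The averaging error is largest for
partial passes and is negligible at the default step (≈ 0.15 s vs a
0.25-s pass). Heat deposition is evaluated only within a configurable
support radius of the focal targets (12 mm in the pattern app); the
pre-focal cone deposit outside that region is neglected.

## MR signal model and the virtual scanner

Frames are synthesized pixel-wise on the reconstructed grid (FOV /
reconstruction matrix; LR increases with +x), sampling the phantom maps
by trilinear interpolation at pixel centers:

* magnitude per echo: `S_e = PD exp(-TE_e / T2(T))` with
  `T2(T) = T2_baseline + slope * dT` (the fat T2 slope is what makes
  marrow thermometry possible);
* phase: `wrap(2 pi gamma B0 alpha_PRFS TE1 dT * water_fraction + drift)`
  with gamma = 42.576 MHz/T and alpha_PRFS = -0.01 ppm/°C. Fat
  (water fraction ≈ 0) contributes no PRFS phase;
* complex Gaussian noise added before magnitude/phase extraction;
* B0 drift injected as a spatially uniform phase, linear in the dynamic
  number (default 0.02 rad/dynamic, configurable).

There is no k-space simulation: echo train length, flip angle and NEX are
carried as metadata only, slices are sampled at their center plane
(thickness is metadata), and no partial-volume, chemical-shift or motion
effects exist. Consequently, passing round-trip tests demonstrates the
correctness of the encode/decode chain and the stream semantics — not
robustness to artefacts of real acquisitions.

The scanner exposes the real-time contract: multiple subscribers each
receive every frame in a private FIFO; a continuously querying consumer
keeps its queue at depth ≤ 1; pause stops production and resume continues
the dynamic numbering without gaps; stack position/orientation are
redefinable between frames; volumetric acquisition orders frames by
(type, stack, slice).

## Thermometry

PRFS maps are `dT = wrap(phi - phi_ref) / (2 pi gamma B0 alpha TE)`;
pixels below 5% of the per-frame maximum magnitude (in either frame) are
flagged invalid rather than zeroed. Phase differences are wrapped to
(-pi, pi] before scaling; excursions beyond one wrap alias, and temporal
unwrapping is out of scope. At 3 T and TE = 20 ms one wrap corresponds to
±19.6 °C; the small-animal demo intentionally reaches ablative
temperatures and therefore reports both the simulated (ground-truth) peak
and the wrap-limited map peak.

Drift correction is zeroth-order by default: subtract the mean map value
over a non-heated ROI (corrected ROI mean is exactly zero; the operation
is idempotent). A first-order planar fit is available behind a flag. When
the reference frame is many dynamics old — per-letter references in the
pattern application live for ~100 s — the accumulated drift itself exceeds
±pi and a *map-domain* correction would alias; for that case
`prfs_delta_t()` accepts a drift ROI and removes the circular mean of the
phase difference before wrapping. Both routes are tested; the map-domain
operation remains the canonical small-drift correction.

Two-echo T2 maps are `T2 = (TE2 - TE1)/ln(S1/S2)` with pixels masked
invalid where `S1 <= S2` (degeneracy is handled by masking, never an
error), and temperature change in fat is `dT = (T2 - T2_ref)/slope` with
a 20 ms/°C default slope, the calibration value reported for bone marrow.
The suite verifies noiseless T2 recovery within 1% and recovery of an
injected 20 ms/°C slope within 5% at SNR 50.

## The applications and their fixtures

*Element scan.* Five commands per channel (all off; element n on; pulsed
exposure 40 cycles @ 1.2 MHz, 40 Hz, 1.8 s; turn-off marker; remain
inactive), then a modification switching the element and restarting at
step 0. The app polls engine status to detect the exposure end and then
advances a 0.5-s transfer/modification overhead, so each channel costs
exactly 2.3 s of simulated time and the 256-element scan totals 588.8 s
(~589 s). The 0.5-s overhead is a configuration default chosen to
reproduce the published per-channel time.

*Heating pattern.* Ten 18-mm segments form the letters H (3), I (1),
F (3), U (3), drawn in 20 x 18-mm boxes at a 25-mm letter pitch (the
published figure shows the layout but no coordinates; these constants are
ours). Segments are steered in 2-mm steps (10 points, endpoints
inclusive) at a 25-ms dwell; per segment: move to the letter center (new
letters only), 2-s reference pause, 8-s 80-W exposure, 60-s cooling, then
a modification (goto 0 for a new letter, goto 2 otherwise). Imaging runs
concurrently at 0.59-s dynamics (FOV 200 mm, reconstruction matrix 224,
TE/TR 20/30 ms); every frame becomes a drift-corrected temperature map
folded into a running maximum projection. Default problem sizes: a 131 x
43 x 21 voxel 1-mm slab (the 0.5-mm grid changes the reported peak by
~5%), ~712 s of simulated time, ~1200 frames; the run takes about a
minute of wall time. The engine's five-step protocol, the modification
sequence and the four per-letter references are asserted against the
event log.

A note on the background criterion: the per-pixel maximum over ~1200
noisy maps rides on the extreme value of the per-map noise (≈ 3.7 sigma,
about 0.6 °C at the default image noise of 0.02). The geometric
legibility checks are therefore evaluated on the noiseless movie, where
the far-field background is ~13% of the global peak; with default noise
the same statistic includes that noise ceiling.

*Small-animal demo.* A 64-element bowl (F = 50 mm, D = 32 mm) at 3 MHz —
deliberately outside the clinical array's 1.0–1.5 MHz band — heats a
small tissue phantom for 9 s at 25 or 35 W while a single coronal slice
is imaged at 0.35-s dynamics (TE/TR 16/23 ms, FOV 80 mm) through the
subscribe/query/compute loop. With ≥ 25 heated dynamics per run, a 0-W
null run whose readings stay within 3x the ROI noise floor, and
monotonicity of the ground-truth peak in power, the demo exercises the
full streaming pipeline end to end. Quantitative map statistics are
restricted to pixels with at least 20% of the maximum reference
magnitude; rim pixels just above the 5% validity threshold carry
near-uniform phase noise.

## Known limitations

* Linear acoustics only: no nonlinearity, cavitation, refraction,
  aberration or element cross-talk; single homogeneous medium per run.
* No thermal dose (CEM43), temperature-dependent properties, or damage
  model.
* No k-space/artefact simulation; no multi-echo (> 2) T2 fitting, Dixon
  separation, or referenceless thermometry.
* The TCP server multiplexes sessions by polling in one process — fair
  and non-blocking across sessions, but not hard real time, and without
  authentication.
* Absolute temperatures in the heating applications are scale-accurate
  only up to the homogeneous-medium attenuation simplification discussed
  above.
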