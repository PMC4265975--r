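# sonasim

A hardware-free control stack for MR-guided high-intensity focused
ultrasound (MR-HIFU) research. Treatment protocols for a 256-element
phased-array therapy device are built as data, executed by a deterministic
engine on a simulated clock, modified in real time, and monitored through
status queries — while a physics backend (phased-array acoustics plus
Pennes bioheat) and a virtual MR scanner stand in for the scanner and
therapy hardware, so complete MR-thermometry-guided experiments run on a
desk.

## Who this is for

Groups prototyping MR-HIFU applications — sonication scheduling, electronic
beam steering, real-time protocol modification, PRFS and T2 thermometry
pipelines — who want to develop and regression-test control and analysis
code without scanner time.

## What is inside

* **Protocol model** — immutable commands (continuous/pulsed exposure,
  transducer move, pause, element-level R&D), assembled into identified
  protocols; modifications target commands by position and may restart
  execution (`goto`). JSON (de)serialization with a frozen schema
  (`sonasim-protocol/1`).
* **Execution engine** (`HifuEngine`) — one protocol at a time, simulated
  clock, event log, atomic live modifications, status snapshots (position,
  forward/reflected power, ultrasound on/off, moving/idle, time index).
  Also served over TCP as newline-delimited JSON sessions
  (`hifu_serve()` / `hifu_connect()`).
* **Acoustic simulator** — spherical-shell array layout (256 elements,
  F = 120 mm, D = 130 mm, 1.0–1.5 MHz), Rayleigh–Sommerfeld element
  fields, electronic steering phases
  `phi_n = k (|r_n - r_f| - F)`, superposition, heat deposition
  `Q = alpha f |p|^2 / (rho c)`, and a virtual hydrophone with tone-burst
  averaging.
* **Bioheat solver** — explicit Pennes finite differences
  `rho c dT/dt = k lap(T) - w_b c_b (T - T_a) + Q`
  with stability checking, verified against the Gaussian Green's function,
  a perfusion-only closed form, and energy conservation.
* **Virtual MR scanner** (`VirtualScanner`) — dynamic magnitude/phase and
  two-echo frames from digital phantoms, with the real-time stream
  contract: subscribe/query/unsubscribe, pause/resume, stack
  repositioning, and volumetric ordering by (type, stack, slice).
* **Thermometry** — PRFS maps
  `dT = wrap(phi - phi_ref) / (2 pi gamma B0 alpha TE)` with drift
  correction against a non-heated ROI; two-echo T2 maps
  `T2 = (TE2 - TE1)/ln(S1/S2)` with a fat calibration slope (20 ms/°C)
  for marrow thermometry; maximum-temperature projections.
* **Applications** — end-to-end runs: an automated per-element transducer
  scan, a ten-segment steered heating pattern spelling "HIFU" imaged with
  live PRFS thermometry, and a small-animal single-slice thermometry loop.

## Worked example

Automated per-element characterization of the array: each element is
driven alone with a pulsed exposure (40 cycles at 1.2 MHz, 40-Hz
repetition) for 1.8 s, a virtual hydrophone capture is averaged 64 times,
and a protocol modification switches to the next element and restarts the
protocol — the waiting is driven by engine status queries, not by
sleeping.

```r
library(sonasim)
geometry <- make_array_geometry()        # 256 elements, F 120 mm, D 130 mm
scan <- run_element_scan(geometry)
nrow(scan$records)
#> [1] 256
head(scan$records, 2)
#>   element_id summary_amplitude_pa channel_time_s completed_at_s
#> 1          1             15380.86            2.3            2.3
#> 2          2             15380.86            2.3            4.6
scan$total_time_s
#> [1] 588.8
```

Each channel takes 2.3 s of simulated time (1.8-s exposure + 0.5-s
transfer/modification overhead), so the full array completes in 588.8 s —
just under ten minutes, matching the published timing of the hardware
experiment this reproduces. The summary amplitude is the half
peak-to-peak focal pressure of the averaged burst; all elements read the
same value here because every element of an ideal shell is equidistant
from the focus.

The heating-pattern application combines the engine, the bioheat solver
and the virtual scanner:

```r
res <- run_hifu_pattern(seed = 1, noise_sd = 0)
res$report$n_segments          # 10 steered 18-mm line exposures
res$report$n_reference         # 4 reference frames, one per letter
round(res$report$peak_delta_t_c, 1)
#> [1] 4.6                      # peak temperature change, deg C
round(res$report$background_max_c / res$report$peak_delta_t_c, 2)
#> [1] 0.13                     # far-field background fraction
```

`res$max_projection` holds the per-pixel maximum temperature change over
all ~1200 dynamics — the word "HIFU" written in heat. Export it with
`write_temperature_nifti()`.

A thin CLI wraps the same functions:

```sh
inst/cli/sonasim run element-scan --out out/
inst/cli/sonasim serve --port 7777
inst/cli/sonasim status --port 7777
```

## Layout

```
R/            protocol model, engine, server, acoustics, bioheat,
              virtual scanner, thermometry, applications
src/          Rcpp kernels (Rayleigh summation, Laplacian, trilinear)
tests/        testthat suite, including end-to-end acceptance checks
vignettes/    methods vignette (model, defaults, numerical choices)
scripts/      acceptance script
inst/cli/     command-line front end
```
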