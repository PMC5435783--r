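# umiflow

Relating a 2D unsteady blood-flow field to forward and backward pressure
waves in a carotid-like artery, from simultaneous — and exactly
synchronized — pressure measurement and flow-field analysis.

The package is aimed at computational-hemodynamics and cardiovascular
biomechanics researchers who want to study wall shear stress (WSS) and wave
propagation together. It implements:

- a **2D ultrasonic-measurement-integrated (UMI) simulation**: an
  incompressible Navier–Stokes finite-volume solver on a staggered grid
  (QUICK convection, second-order implicit time stepping, SIMPLER-style
  pressure–velocity coupling) with a color-Doppler feedback body force

  **f** = −K\*ᵥ (ρU/L) (V_c − V_m) **ê**,

  which drives the computed beam-projected velocity V_c toward the measured
  Doppler velocity V_m inside a feedback domain. Setting the gain
  K\*ᵥ = 0 gives the ordinary (2D-O) control simulation. The mean inlet
  velocity of every frame is estimated by golden-section search on the
  Doppler error norm e(t) = (1/N_e) Σ|V_c − V_m|/V_type.
- the **pressure-measurement signal chain**: ECG filtering (50 Hz notch,
  FIR high/low-pass, exact group-delay compensation) and R-peak detection;
  PPG normalisation and cuff calibration to P₀(t) in mmHg; watershed
  extraction of the vessel-area "image pulse" from B-mode-like stacks;
   1-ms peak-time clock alignment between the PPG and ultrasound clocks.
- **wave-intensity and PU-loop analysis**: WI = dP/dt·dU/dt with
  forward/backward/absorption labelling, systolic PU-loop linearity (R²)
  and curvature classification (straight = synchronized, concave = delayed
  pressure, convex = advanced pressure), and 5-ms PU-loop-based
  synchronization refinement.
- a **synthetic twin-experiment generator** (ground-truth pulsatile flow,
  Doppler frames with noise, speckled B-mode stacks, Beer–Lambert PPG,
  synthetic ECG, controlled clock offsets) so the entire pipeline is
  testable without clinical data.

## Worked example

A twin experiment: a known "truth" flow with a skewed inlet profile
generates noiseless Doppler frames; a UMI run (K\*ᵥ = 500) and an ordinary
run (K\*ᵥ = 0) assimilate them.

```r
library(umiflow)

sc     <- twin_scenario(inlet_shape = "skewed", n_frames = 8, noise_sd = 0)
truth  <- generate_truth(sc)
frames <- sample_doppler(truth)

umi <- run_simulation(frames, truth$grid, mode = "umi")
ord <- run_simulation(frames, truth$grid, mode = "ordinary")

glance(umi)
#> # A tibble: 1 × 6
#>   mode  K_v_star n_frames e_mean e_final u_inlet_mean
#>   <chr>    <dbl>    <int>  <dbl>   <dbl>        <dbl>
#> 1 umi        500        8 0.0150  0.0183        0.367

glance(ord)$e_mean
#> [1] 0.08338612

mean(umi$results$e) / mean(ord$results$e)
#> [1] 0.1799637
```

The error norm e(t) is non-dimensional (normalised by the typical carotid
velocity 0.39 m/s): the feedback reduces the Doppler mismatch to ~19% of
the ordinary simulation's — the interior velocity field follows the
measurements even though the imposed parabolic inlet shape is wrong for
this truth. `tidy(umi)` returns the per-frame table (t, e, inlet velocity,
space-averaged lower-wall WSS), and `autoplot(umi)` plots the three series.

Wave analysis on a synthetic water-hammer beat (P = a + b·U exactly):

```r
fs <- 200; tb <- seq(0, 0.9, by = 1/fs)
u  <- 0.1 + 0.35 * exp(-((tb - 0.3)/0.1)^2)
P  <- bio_signal(80 + 100*(u - 0.1), fs, kind = "pressure")
U  <- bio_signal(u, fs, kind = "velocity")

glance(build_pu_loop(P, U))
#> # A tibble: 1 × 5
#>   r_squared quad_coef classification t_foot t_peak
#>       <dbl>     <dbl> <chr>           <dbl>  <dbl>
#> 1         1  8.13e-16 straight        0.159    0.3
```

A full run — twin generation, clock sync, UMI assimilation, WI/PU
analysis, CSV/JSON report and the seven-panel aligned figure — is one call:

```r
r <- run_pipeline(list(scenario = list(n_frames = 10, clock_offset = 0.029),
                       out_dir = "out"))
r$summary$coarse_shift_ms   # 27  (vs 29 ms injected)
r$summary$pu_r_squared      # 0.9996
```

A thin command-line wrapper with subcommands `twin-gen`, `sync`, `run`,
`wi`, `puloop`, `report` is installed at `inst/cli/umiflow.R`.

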