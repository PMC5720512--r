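# pennemg

Forward simulation of differential-electrode surface EMG (sEMG) for
pennate skeletal muscle, parameterised for the human Tibialis Anterior
(TA).

Surface EMG is the skin-recorded superposition of motor-unit action
potentials. Most forward models assume fibres parallel to the skin; TA is
pennate — its fibres run at an angle θ to the line of traction — so both
the volume-conductor geometry and the interpretation of recorded features
change. pennemg builds the signal from first principles and provides the
feature and statistics layers used to validate such models against
recordings. It is written for researchers in neuromuscular
electrophysiology who want a transparent, scriptable simulator: every
stage is an exported, tibble-returning function.

**The model, stage by stage.**

* Membrane source: the Rosenfalck intracellular action potential
  `Vm(z) = A (λz)³ e^(−λz) − B` and its transmembrane current
  `Im(t) = C A λ² (λvt)(6 − 6λvt + (λvt)²) e^(−λvt)`,
  `C = d²σᵢπ/(4v²)` — a charge-balanced tri-phasic pulse travelling at
  the fibre's conduction velocity.
* Volume conductor: anisotropic point-source weighting
  `1/(4πσₑ √((z−z′)² + σ[(x−x′)² + (y−y′)²]))` applied in the
  fibre-local frame, so pennation is a rigid rotation of the fibre path;
  differential single-fibre action potentials (SFAPs) are synthesised by
  summing delayed, weighted sources along the discretised fibre. The
  default source formulation is charge-conserving through wave generation
  and extinction (`source_model = "progressive"`); the literal truncated
  per-point form is available too.
* Motor-unit pool: size-principle recruitment with the exponential
  threshold ladder `RTᵢ = exp((ln RR / T_Mu) i)`, linear rate coding from
  the minimum firing rate at threshold to the peak rate at 100 %MVC, and
  renewal spike trains with inter-spike-interval jitter.
* Composite sEMG: per-unit MUAP templates superposed at the firing times,
  with batch runs that redraw the physiological parameters (motor-unit
  count 125–652, muscle radius 20 ± 2 mm, conduction velocities
  3.9/4.9 ± 0.3 m/s, half fibre length 45 ± 0.4 mm, firing-rate bounds
  7–23 / 14–50 Hz, pennation 20 ± 2°) on every repetition.
* Features: windowed RMS (2500 ms windows), median frequency (MDF), and
  Higuchi fractal dimension (FD, k = 6).
* Equivalence statistics: two-sample t-test, Bland–Altman limits of
  agreement as margins, and the two one-sided tests procedure (TOST) with
  broom-style `tidy()`/`glance()` methods.

Amplitudes are in "Rosenfalck units": no gain chain is modelled, so only
relative amplitude comparisons are meaningful; MDF and FD are
amplitude-invariant.

## A worked example

```r
library(pennemg)

cfg <- simulation_config(pool_params(n_units = 150), duration_ms = 5000)
sig <- simulate_semg(cfg, mvc = 25, seed = 3)
semg_features(sig, fs = 1000)
#> # A tibble: 1 × 5
#>     rms   mdf    fd window_ms k_max
#>   <dbl> <dbl> <dbl>     <dbl> <dbl>
#> 1  160.  91.6  1.52      2500     6
```

One 5-second contraction at 25 %MVC: RMS 160 (arbitrary units), median
frequency 91.6 Hz and fractal dimension 1.52 — spectral and fractal values
in the physiological range for TA at low force.

```r
sweep <- pennation_sweep(cfg, angles = c(0, 5, 10, 20), mvc = 50, seed = 11)
tibble::as_tibble(sweep)[c("angle", "correlation", "rms", "mdf", "fd")]
#> # A tibble: 4 × 5
#>   angle correlation   rms   mdf    fd
#>   <dbl>       <dbl> <dbl> <dbl> <dbl>
#> 1     0       1      443.  96.2  1.47
#> 2     5       0.991  361.  95.6  1.48
#> 3    10       0.973  319.  96.3  1.50
#> 4    20       0.936  301.  96.4  1.52
```

The `correlation` column is the Pearson correlation between the
amplitude-normalised reference-fibre SFAP at each angle and the parallel
(0°) fibre: the shape stays highly similar (r > 0.9) up to 20° of
pennation even as composite-signal features shift — the model's headline
behaviour. `autoplot(sweep)` draws the panels.

```r
set.seed(1)
a <- rnorm(20, 1.50, 0.05)   # e.g. FD from a simulated batch
b <- rnorm(20, 1.49, 0.06)   # e.g. FD from a second batch
glance(equivalence_test(a, b, feature_name = "fd", mvc_level = 25))
#> # A tibble: 1 × 11
#>   feature   mvc mean_difference lower_bound upper_bound tost_p   t_p alpha …
#> 1 fd         25          0.0199    -0.00849      0.0483 0.0376 0.207   0.1
```

The Bland–Altman ±2 SD limits become the TOST margins; `tost_p < alpha`
declares the two feature batches statistically equivalent (here p = 0.038
at α = 0.10), while the ordinary t-test (p = 0.21) merely fails to find a
difference.

A thin command-line wrapper covers the same pipeline:
`inst/scripts/pennemg simulate|batch|sweep-pennation|features|equivalence|config`.

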