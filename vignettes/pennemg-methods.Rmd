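---
title: "Forward modelling of pennate-muscle surface EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modelling of pennate-muscle surface EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pennemg)
```

pennemg simulates the differential-electrode surface electromyogram (sEMG)
of a pennate skeletal muscle from first principles — single-fibre membrane
currents, volume conduction through anisotropic tissue, motor-unit
recruitment and rate coding — with the human Tibialis Anterior (TA) as the
default parameterisation. This vignette is the package's own account of the
model: the equations, the coordinate and orientation conventions, the
numerical choices, which parameters matter and why their defaults are what
they are, and what the simulations can and cannot say about real
recordings.

## The membrane source

The intracellular action potential follows the classical Rosenfalck
closed form,

$$V_m(z) = A\,(\lambda z)^3 e^{-\lambda z} - B,$$

with $z$ the distance travelled behind the excitation front (mm), $A$ an
amplitude scale, $B$ the resting potential magnitude, and $\lambda$ a
spatial scaling factor. The transmembrane current density of a wave
travelling at conduction velocity $v$ is its second spatial derivative
scaled by the line-source constant $C = d^2 \sigma_i \pi / (4 v^2)$
($d$ fibre diameter, $\sigma_i$ intracellular conductivity):

$$I_m(t) = C A \lambda^2\, (\lambda v t)\,
  \bigl(6 - 6 \lambda v t + \lambda^2 (v t)^2\bigr)\, e^{-\lambda v t},$$

a tri-phasic (+, −, +) pulse whose time integral vanishes — every unit of
outward current returns. The numeric values $A = 96$ mV, $B = 90$ mV,
$\lambda = 1$ mm$^{-1}$ are the classical Rosenfalck fit; because no
measured gain chain is modelled, all simulated voltages are in these
"Rosenfalck units" and **only relative amplitude comparisons are
meaningful**. Simulated absolute RMS is therefore never compared with
recorded microvolts.

Two typed parameter sets ship with the package: slow fibres
(`membrane_params_slow()`, $d = 35.46\ \mu$m, $v = 3.9$ m/s) and fast
fibres (`membrane_params_fast()`, $d = 50.68\ \mu$m, $v = 4.9$ m/s),
the TA literature values. The formula for $C$ is exposed as
`source_constant()` so the scaling convention can be replaced wholesale;
the printed form of its denominator is typographically ambiguous between
$4v^2$ and $4\pi v^2$, a choice that only rescales every waveform by a
constant and is therefore immaterial under the relative-amplitude regime.

## Volume conduction and geometry

Coordinates: the innervation zone of the reference fibre is the origin,
$z$ runs along the muscle's line of traction, $y$ toward the skin, $x$
transverse. The muscle is a cylinder of radius 20 mm about the $z$ axis;
the skin surface lies one cutaneous layer (3 mm) above it, and the
electrode contacts sit on the skin.

A point source is weighted at the electrode by the anisotropic unbounded
medium kernel

$$f = \frac{1}{4\pi\sigma_e \sqrt{(z - z')^2 +
  \sigma\,[(x - x')^2 + (y - y')^2]}},$$

with $\sigma_e$ the extracellular conductivity and $\sigma$ the
longitudinal/transverse anisotropy ratio, applied in the *fibre-local*
frame: for a fibre pennated by $\theta$ the electrode position is rotated
about the $x$ axis into the frame in which the fibre is the $z$ axis
(`weight_pennate()`), which reduces exactly to the parallel kernel at
$\theta = 0$. Defaults $\sigma_i = 1.01$ S/m, $\sigma_e = 0.2$ S/m give
$\sigma \approx 5$, the standard skeletal-muscle anisotropy. The
medium is a homogeneous half-space surrogate: no layered skin/fat
conductor, no finite-element mesh (documented limitation).

**Orientation convention.** A rigid rotation about a fibre's own
neuromuscular junction necessarily raises one fibre half toward the skin
and lowers the other. The printed pennate kernel is mirror-ambiguous in
the sign of this tilt. pennemg defines positive pennation as tilting the
fibre half on the electrode side *away* from the skin — the descending
course of a TA fascicle from the superficial toward the deep aponeurosis,
with the montage placed distally. Under the opposite orientation the
rising fibre end sweeps into the electrode's near field and the
single-fibre action potential (SFAP) shape decorrelates almost completely
by 20°, which contradicts the shape stability this model family is known
for; under the chosen convention the shape correlations fall gently
(about 0.99 / 0.96 / 0.93 at 5° / 10° / 20° for the default mid-depth
reference fibre). Fibre segments whose global position leaves the muscle
cylinder are clipped: anatomically the fibre ends at the fascia.

**Differential montage.** Two point contacts 10 mm apart along $z$
(the standard bipolar inter-electrode distance). A pair centred exactly
over the innervation zone sees mirror-image potentials at its two
contacts — the differential signal cancels identically — so the default
pair is centred 10 mm toward the tendon, the conventional placement
between innervation zone and tendon. Both contact positions are fully
configurable, and `muap()` can optionally average each contact over a
transverse bar (`contact_halfbar_mm`), though at the default geometry
this changes composite features by well under 1%.

**Reference fibre for shape studies.** The single-fibre sweep
(`pennation_sweep()`, and acceptance targets) uses one fibre whose
innervation point lies 13 mm below the contacts: 10 mm of muscle (a
mid-depth fibre of the 20 mm radius TA) plus the 3 mm cutaneous layer.
The source papers in this family do not state the depth they used; the
mid-depth choice is anatomically neutral and reproduces the published
correlation pattern. SFAPs for shape analysis are sampled at 10 kHz so
that correlations compare waveform shape rather than sampling artefacts.

## SFAP synthesis and the two source formulations

The fibre is discretised into axial steps of $\Delta z = 0.5$ mm
(midpoint rule); two excitation waves leave the innervation zone toward
the two ends at velocity $v$; each source point contributes its time
course delayed by $|u|/v$ and weighted by the kernel; the differential
SFAP is $\phi_0(t) - \phi_1(t)$. The step is deliberately decoupled from
the sampling rate — time courses are evaluated analytically at exact
delays — and halving it changes the waveform by well under 0.5% in L2
norm (grid-refinement test in the suite).

Two source formulations are implemented:

* `source_model = "truncated"`: each point's transmembrane current
  $I_m(t - |u|/v)$ switches on abruptly and the sum is cut at the fibre
  ends. This is the literal per-point reading of the current source.
* `source_model = "progressive"` (default): the identical physics written
  as the distributional second axial derivative of the intracellular
  profile, evaluated by moving both derivatives onto the kernel
  (integration by parts): the pulse $C A (\lambda v \tau)^3
  e^{-\lambda v \tau}$ weighted by the kernel's second axial derivative.
  For an infinite fibre the two coincide; on a finite fibre the
  progressive form is charge-conserving through wave *generation* at the
  end plate and *extinction* at the fibre ends, the construction used by
  the standard line-source simulators in this field.

The difference matters. The truncated form radiates uncompensated birth
and end transients whose broadband energy dominates the composite
spectrum (median frequency near 190 Hz and Higuchi dimension near 1.9 at
25% MVC); the progressive form puts the composite near the values this
model family reports for TA (median frequency 100–110 Hz, fractal
dimension about 1.55). Numerically the truncated integrand is
charge-balanced and nearly cancels in the far field, so its midpoint sum
also converges an order of magnitude more slowly there (the suite checks
its $O(\Delta z^2)$ convergence toward the progressive waveform in the
fibre interior). Both remain available because the truncated variant is
the construction many published models actually used, and its boundary
transients — not any shape change of the travelling wave — are what
produce the frequently reported *increase* of amplitude, frequency and
fractal dimension with pennation angle. Under the charge-conserving
default, amplitude instead *decreases* with angle at a distal montage
(every fibre segment recedes from the contacts) while the fractal
dimension still rises; the package reports this honestly rather than
reproducing a transient-driven trend.

## Motor-unit pool

Recruitment follows the size principle with the exponential threshold
ladder

$$RT_i = \exp\!\bigl(\tfrac{\ln RR}{T_{Mu}}\, i\bigr), \qquad
  i = 1, \dots, T_{Mu},$$

so thresholds are geometric in size rank and the last unit is recruited
exactly at the recruitment range $RR$ (default 30 %MVC, the standard
value in this model family). An active unit fires at

$$FR_i = MFR + (drive - RT_i)\,\alpha_i, \qquad
  \alpha_i = \frac{PFR - MFR}{100 - RT_i},$$

rising linearly from the minimum firing rate at its own threshold to the
peak firing rate at exactly 100 %MVC, clamped at $PFR$; a unit with
threshold 100 fires only at full drive. Spike trains are renewal
processes with Gaussian inter-spike-interval jitter of coefficient of
variation 0.2 (the customary value; 0 gives strictly periodic trains for
deterministic tests), first spikes desynchronised uniformly over one mean
interval.

Pool geometry: `build_pool()` assigns each unit a fibre count
proportional to its threshold (large-threshold units are large),
normalised so the muscle holds `fiber_density` (20 /mm²) times its
cross-sectional area in fibres; territory radii follow from holding that
density inside each territory; territory centres are uniform over the
muscle disc, shrunk so territories stay inside it; fibres are uniform
within territories. Fibre types are assigned to whole units, 70% slow by
default (TA is slow-dominant; the proportion is configurable). Each
fibre's neuromuscular junction sits at its own mid-length, but the
junctions scatter uniformly over ±10 mm along the muscle axis
(`iz_spread_mm`): TA end-plate bands are of that order, and with zero
scatter every unit would lie entirely on one side of the bipolar montage,
a degenerate geometry. Minimum and peak firing rates are drawn once per
simulation from the literature ranges (7–23 Hz, 14–50 Hz) and shared by
all units; a per-unit assignment is a documented alternative reading, but
the repeated-simulation study reads most naturally as one draw per run.

## Composite signal and the repeated-simulation batch

`simulate_semg()` computes one motor-unit action potential (MUAP)
template per unit — the exact sample-wise sum of its fibres' SFAPs,
collapsed to one time kernel because a unit's fibres share type, length
and angle — and superposes templates at the spike times, placed at the
nearest sample of the 1 kHz grid (≤ 0.5 ms jitter; sub-sample placement
is a possible extension, not the default, to keep the superposition
oracle exact). Signals default to 15 s, the isometric-trial duration of
the validation protocol; the test-suite and acceptance runs use 3–5 s to
keep runtimes modest, a problem-size reduction only. No measurement
noise is added by default (none is part of the model); the experimental
2–450 Hz analogue chain is not emulated.

`semg_batch()` repeats the simulation `n_repeats = 20` times, each time
redrawing the physiological parameters: motor-unit count uniform over
125–652 (the acceptance runs restrict to 125–250), muscle radius
20 ± 2 mm, slow/fast conduction velocities 3.9/4.9 ± 0.3 m/s, half fibre
length 45 ± 0.4 mm, firing-rate bounds from their ranges (redrawn until
$MFR < PFR$, since the printed ranges overlap), and pennation 20 ± 2°
(redrawn by default; pin it with `redraw_pennation = FALSE`). Gaussian
draws are clamped at ±4 SD. Per-repeat seeds derive from the master seed
and are recorded in the output table.

## Signal features

* `semg_rms()` — $\sqrt{\sum x_i^2 / N}$ over non-overlapping 2500 ms
  windows, mean across complete windows.
* `median_frequency()` — the frequency splitting the rectangular-window
  periodogram's power into halves. The two-sided defining condition is
  applied symmetrically (cumulative crossings interpolated from below
  and from above, averaged), so two equal-power tones yield their
  midpoint and a pure tone its own frequency.
* `higuchi_fd()` — Higuchi's fractal dimension with $k_{max} = 6$, the
  tuning reported for sEMG: decimated sub-series at offsets
  $m = 1..k$ (the standard convention; a printed $m = 0..k$ variant is a
  known typographic inconsistency in the source literature), normalised
  curve lengths with the $(N-1)/(\lfloor (N-m)/k \rfloor k^2)$ factor,
  and the least-squares slope of $\ln L(k)$ on $\ln(1/k)$. Calibration:
  ≈ 1 on a straight line, ≈ 2 on white noise, ≈ 1.5 on Brownian motion
  ($2 - H$), all asserted in the suite.
* `semg_features()` — all three at once; the fractal dimension is the
  mean over 2500 ms windows, matching the windowed reading of the
  feature table it emulates.

RMS scales linearly with the signal; MDF and FD are amplitude-invariant —
the reason FD is attractive for validating a simulator whose absolute
gain is arbitrary.

## Equivalence testing

Model validation in this setting asks not "are simulated and recorded
features significantly different?" but "are they demonstrably
*equivalent* within margins?". The layer provides:

* `two_sample_t()` — Welch by default (the variance structures of
  simulated and recorded batches differ); pooled and paired variants
  behind flags, since the source literature is inconsistent about which
  it used.
* `bland_altman_bounds()` — mean difference ± 2 SD of paired differences,
  the limits-of-agreement used as TOST margins. Simulated and recorded
  batches are not naturally paired; `equivalence_test()` pairs by sorted
  magnitude first, a documented and replaceable rule.
* `tost()` — two one-sided Welch tests against the margins;
  `tost_p` is the larger p-value, equivalence declared at
  $\alpha = 0.10$, matching the 90% confidence criterion: equivalence
  holds exactly when the $(1 - 2\alpha)$ CI of the difference lies inside
  the margins (asserted against the CI oracle in the suite). Results are
  broom-friendly (`tidy()`, `glance()`) and plot with
  `plot_bland_altman()`.

The human recordings behind the published comparison are not available,
so the pipeline is validated on synthetic calibrations: type-I error of
the t-test, boundary behaviour of TOST (p ≈ 0.5 when the true difference
sits on a margin), TOST–CI duality, and simulated-vs-simulated feature
batches from disjoint seeds, which must test equivalent.

## What the synthetic studies do and do not show

The generator reproduces the *structure* of the target experiment —
recruitment and rate-coding statistics, fibre geometry, tissue
anisotropy, the montage — under idealisations: homogeneous tissue, point
contacts, no motor-unit synchronisation, no force/twitch model, no
measurement noise, a 2D-style circular cross-section, and an amplitude
scale fixed only up to the Rosenfalck constants. Passing the suite
therefore shows the implementation realises this model faithfully and
that its spectral and fractal summaries sit in the physiological range;
it does not show that any one real recording will match, and absolute
RMS in particular is not comparable to recorded volts. Known honest
discrepancies at the frozen defaults: the batch-mean Higuchi dimension
runs ≈ 0.03–0.08 above the 1.50–1.51 this model family reports (a few
percent), and composite amplitude falls, rather than rises, with
pennation at a distal montage under the charge-conserving source — see
the source-formulation section for why the transient-driven alternative
was not adopted as the default.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(pool_params(n_units = 150), duration_ms = 5000)
sig <- simulate_semg(cfg, mvc = 25, seed = 3)
semg_features(sig, fs = 1000)
sweep <- pennation_sweep(cfg, angles = c(0, 5, 10, 20), mvc = 50, seed = 11)
autoplot(sweep)
```
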