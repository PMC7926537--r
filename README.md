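# manucount

Calibration-free counting of hand movements from a wrist-worn
magnetometer array sensing a finger-worn magnet ring — plus everything
needed to exercise the pipeline without hardware.

People recovering from a stroke are often advised to "use the hand more",
but real-world hand use is hard to measure: wrist accelerometry counts
arm swings, not hand movements. The device this package models pairs a
watch-like band holding **four 3-axis magnetometers** (16-bit, ±4 gauss,
52.6 Hz) with a silicone ring carrying a small neodymium disk magnet on
the index finger. Wrist or finger motion moves the magnet relative to the
array; arm motion does not.

The package implements, in R:

* **Differential reading** (`compute_differential`): the average of the
  near-minus-far magnetometer differences on each side of the board,
  `d = ((m1−m2)+(m3−m4))/2`. A spatially uniform field — the Earth's —
  cancels exactly; only the ring's inverse-cube gradient survives.
  Averaging both sides makes the reading hand-agnostic.
* **HAND counting** (`hand_count`, `calibrate`): a second-order
  Butterworth low-pass (8 Hz), a per-sample change threshold (8 LSB ≈
  0.98 mG), and per-axis *same-direction run* tracking. A movement is
  counted when two axes simultaneously hold runs of `round(5σ)` samples,
  or one axis holds `round(5σ)+2`, where σ is the standard deviation of
  the noise run-length distribution measured once per device on
  movement-free data (`calibrate`). After a count, detection re-arms on a
  direction reversal or after 2 s.
* **UE activity counts** (`activity_count`): the conventional wrist
  accelerometry comparator — windowed sum (0.25 s ≈ 13 samples) of
  absolute acceleration changes, peaks above 0.33 g, at most 4 per second.
* **A physics-based testbed simulator** (`simulate_protocol`,
  `testbed_protocol`, `lab_protocols`): exact point-dipole field of the
  ring magnet (m = BrV/μ0 ≈ 0.465 A·m²), minimum-jerk strokes of the
  wrist or MCP joint across three anthropometric hand sizes, sensor noise
  and 16-bit quantization, with ground-truth labels; amplitude sweep
  5–90°, peak speeds 20–600 °/s under a servo acceleration cap, and the
  in-lab 50-prompt hand / 200-movement arm exercise protocols.
* **Evaluation** (`counting_probability`, `overall_accuracy`,
  `parameter_sweep`, `intensity`): event-to-movement matching, counting
  probability by amplitude/speed-class/hand-size, the filter/threshold
  exploration harness, and counts-per-hour intensity.

## Worked example

Calibrate on simulated movement-free data, then count a simulated 50-prompt
hand-exercise session:

```r
library(manucount)

params <- hand_count_params()        # 8 Hz, 8 LSB, SDs(2 axes)=5, +2
rest   <- simulate_rest(120, noise = noise_model(seed = 1))
cal    <- calibrate(compute_differential(rest), params)
cal
#> HAND run-length calibration
#>   sigma      : 1.1472 samples (from 706 runs)
#>   n_two_axes : 6 samples
#>   n_one_axis : 8 samples

lab <- lab_protocols()
sim <- simulate_protocol(lab$hand_only, noise = noise_model(seed = 2),
                         spacing_s = attr(lab$hand_only, "spacing_s"))
res <- hand_count(compute_differential(sim$frames), params, cal)
res$count
#> [1] 55
head(res$events, 3)
#>          t  trigger axes run_x run_y run_z
#> 1 1.197719 one_axis    x     8     1     5
#> 2 3.155894 two_axes  x|z     6     3     6
#> 3 5.133080 one_axis    z     4     1     8
overall_accuracy(res$events, sim$truth)
#> [1] 98
```

55 counts for 50 prompted movements: every prompt was detected (98 % of
movements matched at least one event) with a 10 % overcount, comparable
to the modest lab overcounting the physical device shows. The arm-only
protocol (hand splinted, 200 arm movements) yields 4 spurious hand counts
(2 % crosstalk) while the accelerometry comparator racks up 677 activity
counts — the difference between sensing the hand and sensing the arm:

```r
arm <- simulate_protocol(lab$arm_only, noise = noise_model(seed = 3),
                         spacing_s = 1)
hand_count(compute_differential(arm$frames), params, cal)$count
#> [1] 4
activity_count(arm$frames)$count
#> [1] 677
```

A command-line front end wrapping these functions (subcommands
`calibrate`, `count`, `activity`, `simulate`, `evaluate`, `sweep`; CSV/JSON
in and out) is installed at `system.file("cli/manucount.R", package =
"manucount")`.

The sensor-log dialect is a plain CSV with header
`t,m1x,m1y,m1z,...,m4z,ax,ay,az,gx,gy,gz` — time in seconds,
magnetometers in signed integer LSB, accelerometer in g, gyroscope in °/s.

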