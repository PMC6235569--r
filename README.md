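# epiosc

Analysis of how an epithelial monolayer responds to localized in-plane
shear. When the midline of an MDCK monolayer grown across two device
planks is sheared by 100 um, two things happen: cells within < 50 um of
the shear plane deform and recoil opposite the shear within hours, and the
whole sheet mounts a collective, damped oscillation in the direction
perpendicular to the shear — an inward wave that starts at the shear plane,
propagates an order of magnitude faster than cells migrate, and reverses
direction every few hours with decaying magnitude. A spring-mounted
sensing plank (k_s = 0.93 N/m) simultaneously records the force across the
monolayer, which peaks at shear and relaxes exponentially.

`epiosc` provides the full analysis chain for such experiments, exercised
end-to-end on seeded synthetic data so that no imaging is required:

* **Kymographs** — horizontal averaging of PIV velocity fields, folding of
  the two planks over the shear plane, temporal binning (3 x 5 min),
  trapezoidal integration to displacement traces, and wave-front
  propagation speed estimation from onset times.
* **Force sensing** — spring-constant conversion of plank deflection and a
  three-parameter exponential relaxation fit; tau is the 63.2% decay time
  of the decaying span.
* **Oscillation fitting** — nonlinear fit of
  `v(t) = v0 + A exp(-t/(2D)) sin(2pi(t - t0)/P)` to the mean collective
  velocity, reversal (zero-crossing) detection, and Kruskal–Wallis-gated
  pairwise Mann–Whitney comparison of fitted parameters across conditions.
* **Mechanical model** — a Maxwell branch (spring k, damper c in series)
  in parallel with an inerter b, driven by a step of inward force:
  `b dv/dt = F - F_m`, `dF_m/dt = k v - (k/c) F_m`, with natural period
  `P = 2 pi sqrt(b/k)`, damping ratio `zeta = sqrt(k b)/(2c)`, and the
  condition maps `c = k D`, `b = k P^2/(4 pi^2)` (inerter effectively
  infinite where no signal propagates). Fixed-step RK4 simulation plus an
  exact closed-form oracle.
* **Synthetic data** — condition presets (`+Shear`, `-Shear`, `+Blebb`,
  `+Jasp`, `T151`) parameterized by the measured speeds, periods and
  relaxation constants, generating bit-reproducible velocity-field series
  and sensing traces.

## Worked example

```r
library(epiosc)

preset <- make_condition_preset("+Shear")
series <- generate_velocity_series(preset, grid_spec(), seed = 1)
kymo   <- fold_kymograph(build_kymograph(series, "y", plank = "top"),
                         build_kymograph(series, "y", plank = "bottom"))

front <- estimate_propagation_speed(kymo)
fit   <- fit_damped_sinusoid(mean_velocity_series(kymo))
trace <- generate_sensing_trace(preset, f_max = 1, seed = 1)
efit  <- fit_exponential_decay(displacement_to_force(trace))
model <- params_from_fit(k = 1, fit, propagation = front$speed)
sim   <- normalize_response(simulate_step_response(model, t_end = 24))
```

which prints:

```
front speed: 288.9 um/h (R2 = 0.990)
Damped-sinusoid fit: A = 13.77 um/h, P = 7.648 h, D = 4.6 h, t0 = 3.241 h, v0 = 0.2265 (rss 343)
Force relaxation fit: F_MAX = 1.022 uN, F_inf = 0.2097 uN, tau = 3.524 min (rss 0.0848)
Mechanical model: k = 1, c = 4.60034, b = 1.48173
  omega0 = 0.8215 /h, zeta = 0.1323, natural period = 7.648 h
simulated reversal times (h): 0.33 4.18 8.04 11.9 15.76 19.62 23.47
```

The inward wave front crosses the plank at ~289 um/h (ten times the
~30 um/h cell speed); the collective velocity oscillates with a ~7.6 h
period and ~4.6 h damping time, reversing roughly every 4 h; the sensed
force relaxes with tau ~3.5 min at this noise draw (3.7 min noiselessly);
and the simulated circuit built from those fits reverses every half damped
period, mirroring the measured kymograph. `run_pipeline()` chains all of
this (3 replicates per condition, JSON report, CSV stage outputs), and
`inst/cli/epiosc.R` exposes `generate | kymo | force | fit | simulate |
run` subcommands for shell use.

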