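# predalign

Training initially **chaotic recurrent neural networks** to generate
target dynamics with a local, online plasticity rule — *predictive
alignment* — plus the full supporting cast: a FORCE/recursive-least-
squares baseline, leaky integrate-and-fire variants (single- and
two-population), generators for a battery of benchmark tasks, and
dynamical diagnostics.  Intended for computational-neuroscience work on
chaos suppression, reservoir computing and biologically plausible
learning rules.

## The model

A rate network with two recurrent weight structures,

```
tau dx/dt = -x + (G + M) r + W_in I + sigma xi ,   r = tanh(x),  z = W r
```

* `G`: sparse, strong, **fixed** — Gaussian entries with sd
  `g/sqrt(pN)`, `(p, g) = (0.1, 1.2)`; gain above 1 makes the untrained
  network chaotic.
* `M`: dense, weak, **plastic** — trained not to reduce output error but
  to minimize

```
L_rec = 1/(2T) ∫ ||Q z − M r||²  −  alpha/T ⟨G r, M r⟩
```

i.e. the recurrent prediction `M r` learns to match the random output
feedback `Q z` while *aligning* with the chaotic drive `G r`
(`alpha = 1`).  The resulting local online update is
`ΔM = eta_M [Q z − (M − alpha G) r] rᵀ`; the readout is plain LMS,
`ΔW = eta_W (f − z) rᵀ`.  Feedback `Q` never enters the dynamics — chaos
is suppressed by the alignment, not by clamping the output.

## Worked example

```r
library(predalign)

conn <- init_connectivity(connectivity_spec(N = 300, seed = 11))
task <- make_periodic("sine", period = 60, amplitude = 1.5)
fit  <- train(conn, task, train_config(T_train = 90000, seed = 12))
fit
#> pa_training: task=sine_T60 rule=pa T=90000 ms
#>   readout RMS error: first segment 0.1877 -> last segment 0.002818

te <- test_autonomous(fit, task, duration = 300)   # plasticity off
round(te$rms, 4)
#> [1] 0.0066

lyapunov_exponent(conn, seed = 14)        # untrained: chaotic
#> [1] 0.001001703
lyapunov_exponent(fit$conn, seed = 14)    # trained: chaos suppressed
#> [1] 0.0001008731
```

The training log shows the readout RMS error falling from 0.19 to
0.003 across the ten logged segments; with plasticity off the network
autonomously replays the 60 ms sine to within RMS 0.007 of the target
(amplitude 1.5).  The leading Lyapunov exponent of the very same
connectivity drops by an order of magnitude toward zero after learning —
the rule tames the chaos rather than fighting it with fast output
clamping (the paired `alpha = 0` control in the acceptance suite shows
the alignment term is what does the suppressing).

Other tasks ship as one-liners: `make_lorenz()`, `make_rsg()`,
`make_memory_bits()`, `make_multi_targets()`, `make_control_switch()`,
`make_synthetic_movie()`; spiking networks via `spike_config()` /
`init_spike_connectivity()` / `train_spike()`; diagnostics via
`lyapunov_exponent()`, `efficiency_index()`, `eigenspectrum()`,
`tent_map()`, `fixed_point_probe()`, `pca_project()`.

Configured end-to-end runs:

```r
run_experiment(presets()$fig2a_sine, "runs/sine")   # or the CLI:
```

```sh
inst/exec/predalign preset-list
inst/exec/predalign train --preset fig2a_sine --out runs/sine
```

Every preset has a desk-scale default; `presets(paper_scale = TRUE)`
restores publication sizes.

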