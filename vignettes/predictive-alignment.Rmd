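---
title: "Predictive alignment: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive alignment: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(predalign)
```

## The model

The package simulates a rate-based recurrent network of $N$ units,

$$\tau \dot{\mathbf{x}} = -\mathbf{x} + (\mathbf{G} + \mathbf{M})\,\mathbf{r}
  + \mathbf{W}^{\mathrm{in}} \mathbf{I} + \sigma \boldsymbol{\xi},
  \qquad \mathbf{r} = \tanh(\mathbf{x}),$$

with a linear readout $\mathbf{z} = \mathbf{W}\mathbf{r}$.  The recurrent
weights are deliberately split in two:

* $\mathbf{G}$ — strong, sparse, **fixed**.  Entries are Gaussian with
  standard deviation $g/\sqrt{pN}$ on a Bernoulli($p$) mask, with
  $(p, g) = (0.1, 1.2)$ by default.  A gain above one makes the
  untrained network chaotic; this chaos supplies the rich basis
  functions that learning will tame.
* $\mathbf{M}$ — dense, initially weak
  ($(p, g) = (1.0, 0.5)$), **plastic**.

The readout is trained by the least-mean-square (Delta) rule,
$\Delta\mathbf{W} = \eta_W (\mathbf{f} - \mathbf{z})\,\mathbf{r}^T$.  The
recurrent rule — the core of the package — does *not* minimize output
error.  It minimizes

$$\mathcal{L}_{\mathrm{rec}} = \tfrac{1}{2T}\!\int\!dt\,
  \lVert \mathbf{Q}\mathbf{z} - \mathbf{M}\mathbf{r} \rVert^2
  - \tfrac{\alpha}{T} \langle \mathbf{G}\mathbf{r},
  \mathbf{M}\mathbf{r} \rangle,$$

i.e. the plastic weights learn to *predict* the random feedback
$\mathbf{Q}\mathbf{z}$ of the network's own output while staying
*aligned* with the chaotic drive $\mathbf{G}\mathbf{r}$.  The resulting
online update,

$$\Delta\mathbf{M} = \eta_M\,[\mathbf{Q}\mathbf{z} -
  (\mathbf{M} - \alpha\mathbf{G})\,\mathbf{r}]\,\mathbf{r}^T,$$

is local (pre- and post-synaptic activity plus a per-unit feedback
signal); $\mathbf{Q}$ never enters the dynamics.  `pa_update_M()` is this
rule; the test suite checks it against a central-finite-difference
gradient of the instantaneous cost.  The regularization weight is
$\alpha = 1$ throughout; `rule = "alpha0"` reruns any training with
$\alpha = 0$ on shared seeds and initial weights as the paired control.

A classical FORCE baseline (`rule = "force"`) trains only the readout,
by recursive least squares with the regularization parameter fixed at
unity, and feeds the readout back into the dynamics through
$\mathbf{Q}$ — the usual clamping mechanism that predictive alignment
avoids.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 10 | ms | membrane time constant |
| `dt` | 1 (rate), 0.5 (spiking) | ms | forward-Euler step |
| `g_g`, `p_g` | 1.2, 0.1 | — | chaos strength / sparsity of `G` |
| `g_m`, `p_m` | 0.5, 1.0 | — | initial scale / density of `M` |
| `alpha` | 1 | — | alignment regularization |
| `eta_w` | `1e-2 * dt / tau` | per step | LMS readout rate |
| `eta_m` | `1e-2 * dt / tau` | per step | recurrent rate |
| `sigma` | 0 | — | state noise scale |

The source publication never states its learning rates and reports that
results are robust to their variation.  We calibrated the defaults on
the reference task (amplitude-1.5 sine of period $6\tau$, $N = 300$):
`eta_m = 1e-3 * dt / tau` fails to converge within 90 s of simulated
time, while `1e-2 * dt / tau` reaches test RMS errors of order $10^{-2}$,
so the latter is the default for both rules.  The spiking network
operates on filtered spike trains whose magnitudes are two orders
smaller than tanh rates, so its *effective* per-step rate
$\eta\,\lVert\mathbf{r}\rVert^2$ would be ~2500× smaller at the rate-net
default; the spiking preset therefore uses $\eta_M = \eta_W = 0.5$,
which matches the effective rate of the rate network.  Larger values
(≥ 2.5) destabilize training.

## Numerical choices

* **Integration** is plain forward Euler, `dt = 1` ms by default and
  0.5 ms for spiking runs.  Halving `dt` changes trajectories by
  $O(dt)$; a property test asserts the first-order refinement.
* **Noise** is injected per step exactly as written in the model
  equation ($\sigma \xi$ with $\xi$ fresh standard Gaussians held
  constant within the step), reproducing the original discrete scheme.
  An SDE-consistent mode ($\sigma\xi\sqrt{\tau/dt}$) is available via
  `sde_noise = TRUE`.
* **Update order** within a step: read the state ($\mathbf{r}$,
  $\mathbf{z}$), log, apply $\Delta\mathbf{W}$ then $\Delta\mathbf{M}$
  with that same $(\mathbf{r}, \mathbf{z})$, then integrate.  Both rules
  use the current rates, matching their online statement.
* **Initial state** $\mathbf{x}(0) \sim \mathcal{N}(0, 1)$ for all rate
  tasks (the movie protocol's stated choice, generalized); seedable.
* **Divergence guard**: any $|x_i| > 10^3$ or non-finite state aborts
  with the failing step in the error message.
* **Self-connections** are allowed in `G` and `M` (the matrix
  construction says nothing about the diagonal, so no mask is applied).
* `W_in` entries are uniform on $[-1, 1]$ (unstated upstream; exposed).
* **Lyapunov exponents** use the twin-trajectory method: separation
  $\gamma_0 = 10^{-6}$, 500 warm-up and 1000 measurement steps, the
  distance renormalized to $\gamma_0$ after *every* step with direction
  preserved (also during warm-up, which prevents saturation in strongly
  chaotic regimes); the exponent is the mean of
  $\log(\gamma_k/\gamma_0)$ per ms.
* **Efficiency index**: the correlation matrix is the time-averaged
  second moment of mean-centered rates over a spontaneous run that
  starts at the random initial state — in the sub-critical regime the
  spectrum necessarily comes from the decaying transient, which is the
  only activity such networks have.  Zero/negative eigenvalues are
  clipped and excluded from the entropy.
* **Tent maps** use strict three-point maxima after collapsing plateaus
  (first index wins).
* **Eigenvalue outliers** are eigenvalues whose real part exceeds the
  circular-law bulk radius of the *initial* weights,
  $\sqrt{g_G^2 + g_M^2}$ for $\mathbf{J} = \mathbf{G} + \mathbf{M}$,
  by a 10 % margin.

## The spiking variant

The LIF network integrates
$\tau_m \dot{\mathbf{v}} = -\mathbf{v} + (\mathbf{G} + \mathbf{M})
\mathbf{r} + \mathbf{I}_{\mathrm{bias}}$ with threshold 1, reset −1,
refractory period 2 ms, and synaptic traces
$\dot r_i = -r_i/\tau_s + \tau_s^{-1} \sum \delta(t - t_{ij})$
($\tau_s = 20$ ms; a spike adds $1/\tau_s$ on the Euler grid).  Gains
are $(0.1, 0.3)$ for `G` and $(1.0, 0.05)$ for `M`, and each realized
matrix is shifted to sum exactly to zero.  Three conventions the
upstream description leaves open:

* neurons fire at $v \ge v_{\mathrm{th}}$ (the tie is measure-zero);
* refractory neurons are clamped at $v_{\mathrm{reset}}$ and do not
  integrate input;
* with the background current *exactly at threshold*, the membrane
  equation alone approaches $v_{\mathrm{th}}$ asymptotically and never
  crosses, so the default initial potentials are drawn uniformly on
  $[v_{\mathrm{reset}}, v_{\mathrm{th}} + (v_{\mathrm{th}} -
  v_{\mathrm{reset}})/2)$: the super-threshold fraction ignites
  activity, which the recurrent fluctuations then sustain.

In the two-population (Dale-respecting) variant all eight weight blocks
are non-negative (negative initial draws are flipped), inhibition
enters with an explicit minus sign, and the predictive-alignment update
is applied blockwise to the signed recurrent prediction
$p_X = M_{XE} r_E - M_{XI} r_I$, with every updated block rectified at
zero.  How the original work maintained the sign constraint during
learning is not stated; rectification is our choice and is scanned by a
10⁴-step property test.

## Tasks and the synthetic world

All inputs are generated; every generator is a pure function of its
parameters and seed.  Periodic targets (sine, 50 %-duty square, rising
sawtooth), five-channel sinusoid batteries, static-input switching,
memory bits (±1 pulses of 100 ms at uniform 500–700 ms intervals;
targets hold the last pulse sign from pulse onset), Ready-Set-Go
(Gaussian pulses, $\Delta = 15$ ms, $T_0 = 60$ ms, training delays
{100, 120, 140, 160} ms), the Lorenz system
($(s, \rho, b) = (10, 28, 8/3)$, output scaled by 1/10, RK4-integrated
and resampled), and a synthetic movie (seeded Gaussian blobs moving
along smooth paths, rendered to key frames, linearly interpolated in
time, flattened to pixel channels in $[-1, 1]$).

Open choices, fixed once:

* **Lorenz time mapping.**  Network and Lorenz time are unrelated
  upstream.  The generator default is 0.01 Lorenz units per ms; the
  `lorenz` preset and the acceptance run use 0.005.  At the desk-scale
  training budget (480 s instead of the original 15,000 s) the faster
  mapping leaves the learned attractor unstable — replay escapes the
  attractor and the tent map smears — while the slower mapping yields a
  stable replay whose tent map lies on the target curve.  The tent-map
  criterion itself is invariant to the mapping.
* **Memory-bit targets** flip at pulse *onset*.  (A variant flipping at
  pulse offset was evaluated and learned strictly worse.)  Before a
  bit's first pulse the target holds a seeded random initial sign.
* **The synthetic movie** stands in for a copyrighted video clip.  It
  reproduces the *format* of that data — smooth spatiotemporal
  structure, RGB pixel channels, temporal interpolation from key
  frames — not natural-image statistics.  A green movie test therefore
  establishes that high-dimensional smooth targets can be stored and
  replayed, nothing about natural video per se.

What green tests do *not* establish more generally: desk-scale runs use
smaller networks and far shorter training than the original
experiments, so quantitative performance levels are not comparable to
the publication's figures; the properties asserted (error decrease,
sign structure, interpolation vs. extrapolation, attractor geometry)
are scale-robust qualitative claims.

## Two-phase generalization and clock drift

In the two-phase protocol (`train_two_phase()`) the first readout group
and `M` are trained on multi-frequency sinusoids; then `M` is frozen
and a second, disjoint readout group is trained by LMS alone on novel
targets — the pretrained network used as a reservoir.  A practical
subtlety: once `M` is frozen the network free-runs, and its intrinsic
oscillation frequencies deviate slightly from the nominal target
periods, so network phase drifts against the task clock over tens of
seconds.  Online LMS tracks the drift, but an autonomous replay scored
against a clock-locked target degrades as the phase error accumulates.
The second phase is therefore kept short (10 s) and replay is scored
immediately after it; with 90 s of phase-1 training at $N = 300$ the
second group reproduces superpositions of trained sinusoids to RMS
errors well below 0.1, while the untrained-reservoir control fails.

## Known limitations

* The memory-bit network at the scaled size ($N = 300$, 900 s of
  training) tracks held-out pulses at roughly 85–90 % — the
  sign-tracking bar of 90 % in the acceptance suite sits at the upper
  edge of what this scale achieves, and the corresponding test
  documents the measured value when it falls short.  Larger networks
  and longer training improve it monotonically.
* Under injected state noise our FORCE baseline degrades *less* than
  predictive alignment at matched noise, the opposite of the
  publication's Supplementary trend; single runs at low noise are
  coin-flips.  That comparison depends on unstated learning rates and
  durations (explicitly excluded from scope), so the suite asserts only
  the robust facts: both rules master the noiseless sine task, and both
  still learn under moderate noise.
* Only the leading Lyapunov exponent is estimated, not the spectrum.
* At `N = 500` the default gains put the network only marginally above
  the chaos transition: long-run attractors of individual realizations
  are often limit cycles (exponent ≈ 0 or slightly negative), and the
  positive exponents reported by the standard short-window protocol
  come from the multi-second chaotic transient.  Medians over seeds are
  positive but small (|λ| < 0.005 / ms); the sub-critical regime is
  robustly negative (≈ −0.03 / ms).
* The e-prop comparison of the original work is out of scope (its
  equations are not given there), as is the real movie clip.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the graded quantities (the signs of the leading Lyapunov exponent in
the chaotic and sub-critical regimes, each the median of five
independent networks at $N = 500$).  The full acceptance suite in
`tests/testthat/test-acceptance.R` re-runs every criterion — gradient
oracle, chaos signs, sine/multi-readout/memory/Lorenz/RSG/spiking/movie
learning, alignment comparisons and spectral outliers — at the desk
scales noted inline.
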