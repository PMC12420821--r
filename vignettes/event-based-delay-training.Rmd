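---
title: "Event-based co-training of weights and delays in spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based co-training of weights and delays in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snndelays)
```

## The model

`snndelays` trains feed-forward spiking neural networks in which every
quantity that crosses a layer boundary is a spike time. Each neuron is a
leaky integrate-and-fire (LIF) unit with exponential current-based
synapses: the membrane potential $u$ obeys

$$\tau_m \dot u = (E_\ell - u) + \frac{\tau_m}{\tau_s}\,
  \frac{I_s(t)}{g_\ell}, \qquad
  I_s(t) = \sum_i \Theta(t - t_i)\, w_i\, e^{-(t - t_i)/\tau_s},$$

with membrane time constant $\tau_m$, synaptic time constant $\tau_s$,
leak potential $E_\ell$ and leak conductance $g_\ell$. The synaptic
coupling carries a $\tau_m/\tau_s$ normalization so that the membrane
response to one input spike is the closed kernel
$\kappa(\Delta) = 2(e^{-\Delta/2\tau_s} - e^{-\Delta/\tau_s})$ when
$\tau_m = 2\tau_s$ (peak value $w/2$ per unit weight) and the alpha
kernel $(\Delta/\tau_s) e^{-\Delta/\tau_s}$ when $\tau_m = \tau_s$ (peak
$w/e$); this convention is what makes the coefficient sums below come out
as stated, and the test suite verifies that the ODE, the kernel sum and
the closed-form spike times all agree to better than $10^{-8}$.

The refractory period is infinite, so every neuron fires at most once and
no reset dynamics enter. Internally everything is normalized:
$g_\ell = 1$, $E_\ell = 0$, $g_\ell\vartheta = 1$, and times are in units
of $\tau_s$. Physical values only appear at configuration boundaries
(`neuron_constants()`).

### Closed-form first-spike times

For a fixed *causal set* of inputs — those arriving before the output
spike — the threshold condition is analytic. With
$a_1 = 2\sum_i w_i e^{t_i/\tau_s}$ and
$a_2 = 2\sum_i w_i e^{t_i/2\tau_s}$ (sums over the causal set), the
$\tau_m = 2\tau_s$ crossing is the root of a quadratic in
$z = e^{-T/2\tau_s}$:

$$T = 2\tau_s \ln\!\left[\frac{2 a_1}{a_2 +
  \sqrt{a_2^2 - 4 a_1 g_\ell\vartheta}}\right].$$

For $\tau_m = \tau_s$, with $b = \sum_i w_i (t_i/\tau_s) e^{t_i/\tau_s}$,
the crossing inverts through the Lambert W function:

$$T = \tau_s\left\{\frac{b}{a_1} - \mathcal{W}\!\left[
  -\frac{g_\ell\vartheta}{a_1} e^{b/a_1}\right]\right\}.$$

Two branch/root choices were genuinely open and are fixed as follows,
then *asserted against an independent membrane oracle* rather than
trusted from the derivation: the larger $z$-root of the quadratic (the
"+" root as printed above) is the earlier, rising-flank crossing; and the
principal Lambert W branch likewise selects the earliest crossing. No
real root, $a_1 \le 0$, or a non-positive logarithm argument all mean "no
spike", represented by the IEEE `Inf` sentinel so that earliest-spike
readout needs no special cases.

The causal set itself is found event by event (`first_spike()`): sort the
arrivals, and for each prefix of $k$ arrivals accept the closed-form
candidate $T$ iff $t_{(k)} \le T < t_{(k+1)}$. Boundaries are taken with
relative tolerance $10^{-12}$, ties in arrival time break by input index
(stable sort), and discriminants within a relative $10^{-12}$ band below
zero are treated as exact tangency. Arrivals beyond $500\,\tau_s$ are
treated as never arriving to keep the exponential sums inside double
range; task spike times live within a few $\tau_s$.

### Exact gradients

Because $T$ is an explicit function of weights and arrival times, the
backward pass is exact and *event-based*: it consumes only the cached
spike times, weights and delays — no membrane traces exist anywhere in
the package. The partials follow from differentiating the closed forms
($\mathcal{W}'(x) = \mathcal{W}/(x(1+\mathcal{W}))$ for ratio 1).
Non-causal inputs get exactly zero gradient. Useful identities that the
tests assert numerically: $\sum_i \partial T/\partial t_i = 1$ (shift
equivariance), and $\partial T/\partial w_i \le 0$ for causal excitatory
inputs.

The gradient field is exact but *piecewise*: when an input enters or
leaves the causal set, or a neuron (de)silences, the loss is
discontinuous. Gradients are computed for the recorded causal set without
smoothing; a global gradient-norm clip (default 10) guards the optimizer
against the unbounded derivatives that occur near grazing crossings.
Silent neurons propagate zero gradient, and a small positive bump
(default $5\times 10^{-3}$ per update, scaled by the fraction of the
batch for which the unit was silent) is added to the incoming weights of
silent units to revive them — without it, dead units are unrecoverable in
time-to-first-spike networks. Both magnitudes are configurable choices,
not derived quantities.

### Delays

Transmission delays are additive in spike times, $t^d = t + d$, so their
derivatives are identity pass-throughs — this is what makes exact delay
training cheap. Three placements are supported per connection block
(`delay_params()`): **axonal** (one $d$ per presynaptic neuron,
parameters scale with layer width), **dendritic** (one per postsynaptic
neuron, also linear), and **synaptic** (one per connection, quadratic in
width). Combining dendritic and axonal delays on the same neuron is
redundant — LIF dynamics are time-shift invariant, so delaying all of a
neuron's inputs by $d$ equals delaying its output by $d$ — and the test
suite asserts this equivalence for both the forward pass and the loss
gradient. Delay layers sit ahead of every neuron layer by default
(`delay_blocks = "all"`); restricting them to the input block is a config
switch.

Delays are kept in $(0, \lambda)$ by the logistic reparameterization
$d = \lambda\,\sigma(\theta_d)$, trained through
$\partial d/\partial\theta_d = \lambda\sigma(1-\sigma)$. Raw parameters
start at $\theta_d = 0$ (centered, $d = \lambda/2$) with $\sigma = 0.1$
jitter to break symmetry. The default bound $\lambda = 2\tau_s$ equals
the default encoding span, so a delay can move any input across the full
temporal window of the data; the benefit of trainable delays grows with
the temporal scale of the input, and $\lambda$ is the knob a span sweep
varies alongside it.

## The task and the generator

The bundled benchmark is the procedurally generated Yin-Yang
classification task: points on the unit disc labelled `yin`, `yang` or
`dot` by the classic interlocking geometry (outer radius 0.5, two
half-discs of radius 0.25, two dot circles of radius 0.1; dot membership
decided first). The generator rejection-samples the disc with per-sample
class goals cycling through the three classes, so any $n$ divisible by 3
is exactly balanced. The frozen probe-grid fixture shipped with the
package (`inst/extdata/yinyang_probe_synthetic.csv`) was computed with an
independent implementation of the same published geometry and pins the
generator's labels; it is a synthetic stand-in, not an export of the
original dataset's code. The label-name mapping (`yin` for the "upper"
interlocking half) is a package convention; class balance makes results
independent of it.

Each point is encoded as four input spike times
$t_0 + \mathrm{span}\cdot(x, y, 1-x, 1-y)$ — a larger coordinate spikes
later, its mirror earlier. The span (earliest-to-latest possible input
spike, default $2\tau_s$) sets the temporal scale of the data; no bias
spike is added. What the generator does *not* emulate: real-world input
noise, class imbalance, or any temporal structure beyond this static
encoding — passing tests on it demonstrates the training machinery, not
performance on natural data.

## Training

The loss is the time-invariant separation MSE

$$L = \tfrac{1}{2}\sum_{n \ne n^\star}
  \left[(t_n - t_{n^\star}) - \Delta_t\right]^2,$$

which asks every wrong-label output neuron to fire $\Delta_t$ (default
$0.2\tau_s$) after the correct one; only differences enter, so a uniform
shift of all outputs changes nothing. The predicted class is the earliest
output spike (ties to the lowest index; an all-silent output counts as an
error). A silent *wrong* neuron contributes no loss (it is already
maximally late); a silent *correct* neuron is handled by substituting the
sample's latest finite output plus $\Delta_t$ as a proxy — pushing wrong
neurons later while the weight bump revives the silent unit. This proxy
rule is a package choice; it matters only transiently, since trained
label neurons fire.

The optimizer is Adam with separate learning rates for weights and raw
delay parameters. The defaults (`lr_w = 0.02`, `lr_theta = 0.03` with a 0.99 per-epoch
decay, batch 50) come from a small grid search on the 4-30-3 Yin-Yang configuration
and are recorded in `inst/configs/`; learning-rate tuning per
configuration is part of the method's own protocol. Weight initialization
draws from $\mathcal{N}(6/n_\mathrm{pre},\, (1.5/\sqrt{n_\mathrm{pre}})^2)$
— an empirically tuned fan-in scaling chosen so that hidden and output
neurons fire for a majority of inputs at initialization. Training is
deterministic given the config seed; datasets (default 5000/1000/1000
train/validation/test) are regenerated per seed; there is no early
stopping, but the best-validation checkpoint is reported alongside the
final model.

```{r, eval = FALSE}
cfg <- train_config(hidden = 30, delay_kind = "axonal", epochs = 150,
                    seed = 1)
res <- run_experiment(cfg)
res$test_err
```

`sweep_experiments()` runs grids of (hidden size, delay kind, span,
$\lambda$) over seeds and returns one tidy row per run;
`sweep_summary()` reduces to medians and interquartile ranges per cell,
the study's reporting convention. Parameter-matched comparisons pair
delay-augmented and weight-only cells of equal `count_parameters()`
total.

## Hardware-noise simulation mode

`noise_spec()` configures the three effect families of analog
neuromorphic substrates, applied to spike times and parameters only —
never to membrane state, so the event-based contract is preserved:

* **trial-to-trial variation** — Gaussian jitter on every emitted spike
  time (inputs included) and optionally on effective delays, redrawn per
  trial;
* **fixed-pattern noise** — a static multiplicative weight deviation,
  frozen per device seed;
* **quantization** — weights and delays snapped to $2^{\mathrm{bits}}$
  uniform levels (defaults 6-bit weights over a symmetric per-layer
  range, 8-bit delays over $[0, \lambda]$); idempotent, error at most
  half a step.

Default magnitudes (jitter $0.01\tau_s$, 5 % fixed-pattern spread) are
placeholders for exploring the model's behavior — they are **not**
calibrated measurements of any particular chip. Training *under* noise
(chip-in-the-loop style, gradients computed from the noisy spike times)
is supported by passing a `noise` spec to `train_config()`.

## Numerical choices and limitations

* Spike/no-spike verdicts and crossing times are validated against an
  independent oracle (`oracle_first_spike()`): bracketed root-finding on
  the analytic kernel-sum membrane, which is exact between input events;
  the kernel sum itself is validated against `deSolve` integration of the
  membrane ODE. Root refinement happens on the kernel expression, not on
  the stepped trace, so no integrator bias enters the $10^{-6}$
  closed-form comparisons.
* Gradient checks use central differences at $h = 10^{-6}$ and are
  meaningful only away from causal-set boundaries, where the loss is
  smooth; the checks filter such points.
* Only single-spike dynamics are implemented (infinite refractory
  period): no resets, no multi-spike codes, no conductance-based
  synapses, and only $\tau_m/\tau_s \in \{1, 2\}$ (other ratios have no
  closed form).
* The test suite and the bundled acceptance script run scaled-down study
  conditions (hidden sizes 10–12, 1500–2000 training samples, 60–150
  epochs, 5 seeds) so that a full run completes in minutes on one core;
  the config files ship the full-size reference conditions (hidden 30,
  5000 samples, 300 epochs, 10 seeds) for users who want the complete
  study.
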