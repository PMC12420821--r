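# snndelays

Exact, event-based co-training of synaptic weights and transmission
delays in spiking neural networks, implemented entirely in spike time.

## The problem

Spiking networks carry information in *when* neurons fire. Training them
with surrogate gradients requires discretizing time and recording
membrane potentials everywhere — expensive, approximate, and a poor fit
for neuromorphic hardware whose only observable output is spikes.
For leaky integrate-and-fire (LIF) neurons with exponential
current-based synapses and single-spike (time-to-first-spike, TTFS)
coding, the first-spike time has a closed form, so both the forward and
the backward pass can operate purely on spike times, exactly.

This package implements that program in R, with trainable transmission
delays alongside the weights. It is aimed at computational
neuroscientists and neuromorphic-hardware researchers who want an
auditable, dependency-light reference implementation with an independent
numerical oracle for every closed form.

## The model

With normalized leak ($g_\ell = 1$, $E_\ell = 0$) and causal inputs
$\{(w_i, t_i)\}$, the first threshold crossing for $\tau_m = 2\tau_s$ is

$$T = 2\tau_s \ln\!\left[\frac{2 a_1}{a_2 + \sqrt{a_2^2 - 4 a_1
g_\ell\vartheta}}\right], \qquad
a_1 = 2\sum_i w_i e^{t_i/\tau_s},\quad a_2 = 2\sum_i w_i e^{t_i/2\tau_s},$$

and for $\tau_m = \tau_s$ it inverts through the Lambert W function.
Exact derivatives of $T$ with respect to weights and input times
back-propagate a spike-time loss; transmission delays enter additively
($t^d = t + d$, so $\partial t^d/\partial d = 1$) in three flavors —
axonal (per presynaptic neuron), dendritic (per postsynaptic neuron),
synaptic (per connection) — bounded by the logistic reparameterization
$d = \lambda\,\sigma(\theta_d)$. The training loss asks every wrong
output neuron to fire $\Delta_t$ after the correct one:

$$L = \tfrac12 \sum_{n\neq n^\star}\left[(t_n - t_{n^\star}) -
\Delta_t\right]^2 .$$

The benchmark task is the procedurally generated Yin-Yang dataset,
encoded as four input spike times $t_0 + \mathrm{span}\cdot(x, y, 1-x,
1-y)$. A configurable hardware-noise mode (spike jitter, fixed-pattern
weight noise, 6-bit weight / 8-bit delay quantization) supports
hardware-aware simulation; its default magnitudes are placeholders, not
chip calibrations.

See the vignette (`vignettes/event-based-delay-training.Rmd`) for the
full account of the model, its assumptions and numerical choices.

## Worked example

```r
library(snndelays)

# a single neuron: subthreshold first input, crossing after the second
nc <- neuron_constants(tau_s = 1, tau_ratio = 2)
fs <- first_spike(arrival_times = c(0, 1), weights = c(1.5, 3), nc)
fs
#> first spike at T = 1.0961 (causal inputs: 1, 2)
oracle_first_spike(c(0, 1), c(1.5, 3), nc)   # independent membrane oracle
#> [1] 1.096104

# train a 4-10-3 network with axonal delays on Yin-Yang (scaled down)
cfg <- train_config(hidden = 10, delay_kind = "axonal", epochs = 150,
                    n_train = 1500, n_val = 500, n_test = 500, seed = 1)
res <- run_experiment(cfg)
res$test_err
#> [1] 5.4
unlist(count_parameters(res$model))
#> weights  delays   total
#>      70      14      84
```

The printed test error is the percentage of held-out Yin-Yang points
whose earliest-firing output neuron is not the true class; 70 weights
plus 14 axonal delays make up the 84 trainable parameters. Training the
same budget without delays (`delay_kind = "none"`, `hidden = 12`, also
84 parameters) gives a median error of 6.6 % over five seeds versus
4.6 % with axonal delays — the parameter-matched delay benefit that the
acceptance script quantifies.

A command-line front end wraps the same functions:

```sh
inst/cli/snndelays-cli train --config inst/configs/default.yaml --out run/
inst/cli/snndelays-cli validate
```

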