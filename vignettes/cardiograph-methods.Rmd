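---
title: "Modelling multimodal cardiovascular trajectories as typed temporal graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multimodal cardiovascular trajectories as typed temporal graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiograph)
```

# The modelling problem

A cardiovascular episode is recorded as three interleaved streams on one
clock: physiological state vectors $x_t \in \mathbb{R}^d$ sampled at
irregular times, discrete clinical events $(\tau_k, z_k)$ with categorical
labels, and timed interventions $(\rho_j, u_j)$. `cardiograph` represents
one episode as a typed graph and learns a latent trajectory
$s_t \in \mathbb{R}^D$ per state sample, supervised by next-state
forecasting and regularized by a family of alignment, smoothness and
event-structure losses. This vignette explains the model, the choices the
implementation had to make where the formulation leaves room, and what the
synthetic validation does and does not establish.

# Graph construction

Nodes are exactly the records: one per state sample, event, and action,
ordered by time, then kind, then input order, so construction is
deterministic. Edges come from three sources:

* **Temporal backbone.** Consecutive state nodes are always connected (two
  directed edges), regardless of the co-occurrence window. Without this the
  graph can disconnect in time and isolated state nodes would receive no
  messages; the backbone is also exempt from edge filtering.
* **Co-occurrence.** Any two nodes within `window` seconds are bidirected.
  The window (default 2.5 s at 1 Hz sampling, i.e. roughly two neighbours on
  each side) controls the locality of attention; widening it grows the edge
  set linearly.
* **Causal priors.** A rule table (source kind/label, target kind/label,
  `max_lag_s`, base weight) adds a directed edge from each matching source
  to every matching later target within the lag, weighted
  $w \cdot e^{-\Delta t / \text{max\_lag}}$ — an exponential stand-in for
  pharmacodynamic delay. Rules are directional in time: the source must
  precede the target. Duplicate directed pairs keep their first insertion
  (backbone, then co-occurrence, then causal).

Stored edge weights are provenance metadata only; message passing uses
learned attention, so filtering (`filter_edges`) is the only consumer of the
weights besides inspection.

# The encoder

Typed initialization uses one two-layer MLP per node kind (tanh hidden
layer of width $D$, linear output; Xavier-uniform initialization under a
mandatory seed). Propagation then runs $L$ rounds of

$$h_v \leftarrow \sigma\Big(\sum_{u \in N(v)} \alpha_{uv}\, W^{(l)} h_u\Big),
\qquad
\alpha_{uv} = \mathrm{softmax}_{u \in N(v)}
\big({-\lambda\,|t_v - t_u|\;\psi^\top [h_u \| h_v]}\big),$$

with $N(v)$ the in-neighbourhood. Three consequences of taking this form
literally deserve note:

* Temporal decay and semantic similarity are coupled *multiplicatively
  inside one exponent*. A negative similarity score therefore *increases*
  the weight of distant neighbours. We implement the printed product;
  `clamp_attention = TRUE` clamps the similarity factor at zero for users
  who prefer a monotone decay. The default is the literal form.
* There is no self-term: a node's own previous embedding enters its update
  only through its neighbours. This matters downstream (see the forecast
  head).
* The update is undefined for a node with no in-edges; such nodes keep
  their previous embedding.

Per-node layer averages $h^{agg}_v = \tfrac1L \sum_{l=1}^L h^{(l)}_v$ feed a
contextual gate: the fused state at time $t$ is
$\tilde h_t = h^{agg}_{x_t} + \sum_{v \in C_t} \gamma_{v,t} h^{agg}_v$ where
$C_t$ contains every event and action node *strictly* before $t$ and
$\gamma_{v,t}$ is a logistic gate on $[h^{agg}_v \| h^{agg}_{x_t}]$.

The counterfactual simulation operator

$$S(h, u, \Delta t) = h + \eta\, e^{-\lambda_{sim} \Delta t}
\tanh(W_s [h \| u] + b_s)$$

perturbs a latent state by a bounded, exponentially decaying response; the
sup-norm deviation never exceeds $\eta e^{-\lambda_{sim}\Delta t}$ and is
non-increasing in $\Delta t$, which the tests assert on random inputs. The
two decay rates $\lambda$ (attention) and $\lambda_{sim}$ (simulation) are
distinct hyperparameters, both in units of 1/seconds, defaults 0.5.

# Bi-temporal fusion and latent geometry

Attention pooling produces a trajectory summary
$H_p = \sum_t \alpha_t \tilde h_t$ (a convex combination; weights sum to 1).
Forward and backward GRUs over the fused sequence give contexts $r_t, b_t$,
fused as $c_t = W_f [r_t \| b_t] + b_f$ and added back:
$s_t = \tilde h_t + c_t$. The GRUs use the standard update/reset/candidate
equations with zero initial state; the backward scan is the forward GRU run
on the reversed sequence with its own parameters.

Because the pooled vector $H_p$ feeds no loss term, the pooling parameters
receive zero gradient under the shipped objective; they exist for downstream
trajectory-level tasks. This is a limitation of the objective as formulated,
not of the implementation.

The latent-geometry constraint asks that latent distances
$d_{lat}(t_1,t_2) = \|s_{t_1} - s_{t_2}\|_2$ track the observed
physiological path length
$\Delta_{obs}(t_1,t_2) = \int \|\dot x\|_2\,dt$, discretized as the
telescoping sum of segment lengths (exact for sampling along a line). A
hard constraint is incompatible with gradient training, so it is relaxed to
the squared hinge $\sum \max(0, |d_{lat} - \Delta_{obs}| - \epsilon)^2$
over all consecutive index pairs plus 4 seeded random non-adjacent pairs
(both counts per stride). The tolerance defaults to
$\epsilon = 0.1$ latent units. The latent and observed quantities live in
different spaces; the package compares them at scale 1 by default and leaves
rescaling to the user (the hinge with a generous $\epsilon$ absorbs modest
scale mismatch).

A multi-resolution view — never given a formula in the source formulation —
is realized by evaluating the arc-length and geometry terms on the full
sequence and on strided subsequences (strides 1, 2, 4) and summing. This is
an interpretation, clearly flagged as such.

# The objective

Eleven named components form the loss bundle: `prediction` (one-step MSE, or
L1 via `loss_type`), `align` and `soft_align` (cross-patient, after linear
interpolation onto a common 32-point normalized-time grid / monotone
nearest-index mapping), `prior` ($\sum_t \|f(s_t) - p_t\|^2$ with a
learnable affine $f$), `arc`, `geometry`, `stage_sep`
($\sum_{i<j} e^{-\|\mu_i-\mu_j\|^2}$ over $K$ contiguous equal segments),
`event_anchor` / `anchor_sep` (learned attractor centers per event label;
$\sum_{i<j} 1/(\|c_i-c_j\|^2 + \varepsilon)$ with $\varepsilon = 0.01$),
`interv_orient` ($\|\delta - G(u,\Delta t)\|^2$ against a registered
exponential response field), and `laplacian` ($\mathrm{Tr}(H^\top L H)$ on
the undirected unit-weight support, equal to the per-edge squared
differences).

Two normalization conventions coexist deliberately. The exported loss
functions implement the printed sums exactly — that is what the closed-form
identity tests assert. The *training* bundle divides each structural term by
its number of summands (grid points, time steps, pairs, edges, events) so
that the weight attached to a term does not silently scale with sequence
length or cohort density.

**Counterfactual bridge.** The intervention-orientation loss needs a
counterfactual final state $\hat s_{t'}$. We simulate from the last fused
state at or before the intervention, $\hat h_{t'} = S(\tilde h_{t_{pre}},
u_j, t' - \rho_j)$ with $t'$ the first state time after $\rho_j$, and pass
$\hat h_{t'}$ through the same bi-temporal fusion holding all other time
steps fixed. Because the other $\tilde h$ are fixed, $r_{t'-1}$ and
$b_{t'+1}$ are unchanged, so the recompute is exactly two single GRU steps
plus the fusion map — cheap and exact. Per training step at most
`max_interventions` (default 2) earliest interventions per patient enter the
loss.

**Response-field registry.** $G(u, \Delta t) = A\,\|u\|_2\,
e^{-\Delta t/\tau}$ with a fixed latent direction $A$ and time constant
$\tau$ per field. For synthetic cohorts the default registry encodes each
generative kernel's state-space direction in the first $d$ latent
coordinates with $\tau = 1/\lambda^*$ — a synthetic stand-in for
clinician-supplied pharmacodynamic expectations, not a learned object.

**Pairing.** Cross-patient terms pair each patient with a seeded random
partner sharing its condition label, re-sampled per step.

# Training: balance, curriculum, determinism

The forecast head is a zero-initialized affine readout of $s_t$. Its default
form is *residual*: $\hat x_{t+h} = x_t + \mathrm{readout}(s_t)$, so the
untrained model reproduces the last-value-carried-forward baseline exactly
and training can only be judged by what it adds. The *absolute* head
($\hat x = \mathrm{readout}(s_t)$) is available via `head = "absolute"`.
The residual default exists because the propagation rule has no self-term:
a node's own state reaches $s_t$ only via neighbours, so an absolute readout
of an untrained encoder starts far behind the trivial baseline.

Loss balance is the one place where measurement drove the design. At
matched (per-summand-normalized) values, the structural terms carry
parameter-gradient norms roughly two orders of magnitude larger than the
forecasting term, whose gradient is damped by the zero readout and by small
residuals. Weighted naively (structural 0.1 each), the ten regularizers
out-pull supervision by about 100:1 and the trained forecaster never leaves
the baseline. The reference configuration (`reference_config()`) therefore
trains supervision-only for the first half of the run and then enables all
structural terms at weight 0.001 — an instance of the curriculum mechanism
(piecewise-constant weight schedules with closed left endpoints) that the
training engine provides generically. `default_loss_weights()` keeps the
conventional 0.1 for interactive use.

Training is single-threaded and bit-deterministic given the config seed: the
partner sampling and patient order use a package-local linear congruential
generator, all parameter initialization is seeded, and the history of two
identical runs is identical to the last bit. Optimization is Adam at
learning rate $10^{-3}$.

All gradients come from a compact reverse-mode tape (`R/autodiff.R`) with
dense-matrix nodes and hand-derived backward passes for the fused GRU scan
and the segment softmax/sum primitives used by per-node attention. Every
custom backward pass, and every loss component end to end, is checked
against central differences (relative tolerance $10^{-3}$; observed errors
are below $10^{-6}$). The hinge, absolute-value and square-root terms are
differentiable almost everywhere; the tests probe random points, which avoid
the measure-zero kinks.

# The synthetic cohort generator

The generator defines the study conditions for every test: a deterministic
latent base $b_{t+1} = A b_t + \text{drift}$ with $A$ block-rotational at
spectral radius 0.95 (slowly decaying oscillations, a stylized stand-in for
coupled cardiovascular channels), additive intervention kernels
$\eta^* e^{-\lambda^*(t-\rho_j)}\,\text{direction}$ with unit-norm
directions (the amplitude lives in $\eta^* = 0.8$; $\lambda^* = 0.5$),
per-step Bernoulli event and action processes (rates 0.03 and 0.02 per
label), i.i.d. Gaussian observation noise ($\sigma = 0.1$), a threshold
anomaly rule on channel 1 (threshold 0.6, about 6 % prevalence under the
defaults), and condition groups differing by a small drift offset. The
default cohort is 50 patients by 100 steps at 1 Hz with $d = 6$ channels;
the model defaults are $D = 16$, $L = 2$, $K = 4$.

The kernel intentionally shares the simulation operator's amplitude-decay
form, which makes parameter recovery well-posed: fitting
$a\,e^{-\lambda \Delta t}$ to 200 sampled responses (closed-form amplitude
given $\lambda$, one-dimensional profiled least squares over $\lambda$,
$\hat\eta = \|a\|_2$ by the unit-norm convention) recovers $\eta^*$ and
$\lambda^*$ within a few percent at the default noise.

What the generator does *not* emulate: physiological waveform morphology,
heavy-tailed or heteroscedastic noise (a flag-gated extension point),
state-dependent intervention policies, missingness, or any clinical realism
in the event features. The ASD-like preset shrinks the dynamics gain of a
designated HRV channel and raises a sympathetic-proxy baseline — structure
only, no claim of clinical fidelity. Consequently, passing tests establish
internal correctness (formulas, gradients, determinism, identifiability
under the stated kernel) and sane end-to-end behaviour, not clinical
performance.

# Numerical and degenerate-input choices

* Softmaxes (attention, pooling) subtract the per-group maximum before
  exponentiation; weights are exactly normalized.
* Isolated nodes skip the propagation update; empty context sets contribute
  an empty sum; an empty prior table yields no causal edges.
* `stage_statistics` requires at least $K$ points; training clamps $K$ to
  the sequence length and drops the separation term if fewer than two
  segments remain.
* Unknown event labels in `event_anchor_loss` and unknown field names in the
  registry are errors, never silent zeros.
* Sequence length 1: pooling returns the single step with weight 1; the
  arc-length and geometry terms are zero.
* JSONL round trips are byte-stable: canonical key order and full
  (17-significant-digit) float serialization.

# Known limitations

* The attention exponent's product form (decay times similarity) is kept as
  printed; with unlucky parameters it can prefer distant neighbours.
* $H_p$ is untrained under the shipped objective (no loss consumes it).
* The latent/observed scale in the geometry term is fixed at 1; a learnable
  scale is a natural extension.
* Soft temporal alignment uses a monotone nearest-index map on normalized
  time, not a dynamic-programming alignment; the hook (`pi`) accepts any
  monotone map.
* Pure-R training is practical at the reference scale (about 4 s per epoch
  for 50 patients by 100 steps on one CPU) but not at clinical-database
  scale.
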