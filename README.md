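# cardiograph

Typed temporal-graph encoding and trajectory alignment for multimodal
cardiovascular time series.

## The problem

Clinical cardiovascular records mix three kinds of information on one
timeline: continuous physiological state samples (heart-rate variability,
blood-pressure features, ECG-derived channels), discrete clinical events
(tachycardia, hypotension episodes), and timed interventions (a beta-blocker
dose, a fluid bolus). Forecasting a patient's physiological trajectory — and
asking *what would this intervention do* — requires a representation that
keeps the timing, the typing and the causal structure of these records,
which plain sequence models discard. Populations with atypical autonomic
regulation (for example autistic patients, who often show reduced HRV with
sympathetic dominance) make cross-patient generalization an explicit part of
the modelling problem rather than an afterthought.

`cardiograph` is for researchers who want a transparent, fully inspectable
reference implementation of this modelling stack in R: every operator is an
exported function with a documented formula, trained by a built-in
reverse-mode autodiff tape, and validated end to end on seeded synthetic
cohorts with known ground truth.

## The model

Each patient record becomes a typed graph `G_p`: one node per state sample
`x_t`, clinical event `(tau_k, z_k)` and intervention `(rho_j, u_j)`;
bidirected temporal edges join consecutive states and any two nodes within a
co-occurrence window; directed causal edges follow a clinical prior-rule
table with pharmacodynamic time-decay weights `exp(-dt / max_lag)`.

The encoder maps the graph to per-time-step latent states:

- typed initialization `h_v = phi_x(x_t) | phi_e(z_k) | phi_a(u_j)` (one MLP
  per node kind, shared latent space R^D);
- `L` rounds of time-weighted attention propagation
  `h_v <- sigma( sum_u alpha_uv W h_u )` with
  `alpha_uv = softmax_u( -lambda |t_v - t_u| psi' [h_u || h_v] )`;
- layer aggregation `h_v_agg = mean_l h_v^(l)` and contextual gating: the
  state embedding at time `t` absorbs every earlier event/action node `v`
  through a learned sigmoid gate `gamma_vt`;
- a counterfactual simulation operator
  `S(h, u, dt) = h + eta exp(-lambda_sim dt) tanh(W_s [h || u] + b_s)`
  whose perturbation is bounded by `eta exp(-lambda_sim dt)` and decays with
  the time since the intervention;
- attention pooling plus forward/backward GRU context fused as
  `c_t = W_f [r_t || b_t] + b_f`, giving final states `s_t = h~_t + c_t`.

Training aligns latent trajectories with a family of structural losses —
cross-patient alignment on a normalized-time grid, clinical-prior
projection, arc-length smoothness, stage-centroid separation, soft temporal
alignment, intervention-orientation against a parametric response field,
event attractor anchors with anchor separation, graph-Laplacian smoothness,
and a latent-geometry hinge tying latent distances to observed physiological
path lengths — around a supervised next-state forecasting loss, under a
curriculum schedule. All gradients come from the package's own autodiff
tape; the optimizer is Adam.

## Worked example

```r
library(cardiograph)

spec   <- synthetic_cohort_spec(n_patients = 10, steps = 60, d = 6, seed = 42)
cohort <- generate_cohort(spec)
cohort$trajectories[[1]]
#> <patient_trajectory p001: 60 states (d=6), 5 events, 7 actions, T=59 s>

graph <- build_graph(cohort$trajectories[[1]], make_prior_table(spec), window = 2.5)
graph
#> <cardio_graph p001: 72 nodes (state 60, event 5, action 7), 392 edges (26 causal)>

config <- reference_config(seed = 42, epochs = 10)
fit    <- train(cohort, config)
round(tail(fit$history[, c("epoch", "prediction", "laplacian", "geometry", "total")], 3), 4)
#>    epoch prediction laplacian geometry  total
#> 8      8     0.0314    0.0327   7.3430 0.0487
#> 9      9     0.0314    0.0293   7.3312 0.0478
#> 10     10    0.0313    0.0273   7.2736 0.0471

metrics <- evaluate(fit$params, cohort, config)
unlist(metrics[c("accuracy", "recall", "f1", "rmse")])
#>  accuracy    recall        f1      rmse
#> 0.7966102 0.3333333 0.1549296 0.1770146

lvcf_mse(cohort$trajectories)   # last-value-carried-forward baseline (MSE)
#> [1] 0.03317175
```

The history rows are end-of-epoch evaluations of each loss component
(`prediction` is the one-step forecast MSE; the structural columns are the
per-summand-normalized regularizers) and `total` is the curriculum-weighted
objective actually optimized. `evaluate()` reports anomaly-detection
metrics from thresholding the forecast-residual norm against the cohort's
ground-truth labels, plus the forecast RMSE. In this short 10-epoch run the
forecast MSE (`0.177^2 ≈ 0.031`) is already slightly below the
last-value baseline (`0.033`); the packaged 20-epoch reference run reaches
roughly 60 % of the baseline error.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cardiograph", package = "cardiograph"))')
Rscript $CLI simulate --spec spec.yaml --out runs/sim
Rscript $CLI train    --config run.yaml --cohort runs/sim/cohort.jsonl \
                      --truth runs/sim/ground_truth.json --out runs/fit
Rscript $CLI evaluate --checkpoint runs/fit/checkpoint.json --cohort runs/sim/cohort.jsonl \
                      --truth runs/sim/ground_truth.json --config run.yaml --out runs/eval
```

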