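# Shared fixtures: tiny trajectories, controlled parameter sets and random
# graphs, all built in code.

# trajectory with evenly spaced scalar-or-vector states and optional records
toy_trajectory <- function(ts = 0:4, d = 2, events = NULL, actions = NULL,
                           states = NULL, id = "toy") {
  if (is.null(states)) {
    states <- matrix(seq_len(length(ts) * d) / 10, ncol = d)
  }
  patient_trajectory(id, ts, states, events = events, actions = actions)
}

# parameters with seeded Xavier weights for a given geometry
toy_params <- function(d = 2, d_e = 2, d_a = 2, D = 3, L = 2, seed = 42,
                       labels = c("A", "B"), ...) {
  init_params(model_dims(d = d, d_e = d_e, d_a = d_a, D = D, L = L, ...),
              labels, seed = seed)
}

# set a two-layer MLP to an exact affine map: out = x W + b
set_mlp_affine <- function(params, which, W, b = 0) {
  D <- params$dims$D
  mlp <- params$theta[[which]]
  big <- 1e6
  mlp$W1 <- matrix(0, nrow(mlp$W1), D)
  mlp$b1 <- matrix(0, 1, D)
  # use near-linear region of tanh: scale down then back up
  eps <- 1e-4
  mlp$W1[seq_len(nrow(W)), seq_len(ncol(W))] <- W * eps
  mlp$W2 <- diag(1 / eps, D)
  mlp$b2 <- matrix(rep(b, length.out = D), 1, D)
  params$theta[[which]] <- mlp
  params
}

# random small trajectory + graph for property tests
random_graph_case <- function(seed, max_states = 5, d = 2, d_e = 2, d_a = 2,
                              window = 2.5) {
  set.seed(seed)
  n <- sample(2:max_states, 1)
  ts <- cumsum(runif(n, 0.5, 1.5))
  traj <- patient_trajectory(
    paste0("rg", seed), ts, matrix(rnorm(n * d), ncol = d),
    events = if (runif(1) < 0.5)
      list(t = runif(1, ts[1], ts[n]), label = "A",
           z = matrix(rnorm(d_e), 1)),
    actions = if (runif(1) < 0.5)
      list(t = runif(1, ts[1], ts[n]), label = "act",
           u = matrix(rnorm(d_a), 1)))
  priors <- causal_prior_table("action", "*", "state", "*", 4, 1)
  list(traj = traj, graph = build_graph(traj, priors, window = window))
}

# numeric gradient of f at x (central differences)
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# default-ish small cohort for train/evaluate tests
toy_cohort <- function(n_patients = 4, steps = 20, d = 3, seed = 77, ...) {
  generate_cohort(synthetic_cohort_spec(
    n_patients = n_patients, steps = steps, d = d,
    event_rate = 0.1, action_rate = 0.08, seed = seed, ...))
}
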