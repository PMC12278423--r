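# CGSE: typed node initialization, time-weighted attention propagation,
# layer aggregation, contextual gating, and the counterfactual simulation
# operator. These are the reference (plain numeric) implementations; the
# training path in model.R reproduces the same maps on the autodiff tape and
# is tested to agree with these to high precision.

mlp_forward <- function(x, mlp) {
  x <- as_mat(x)
  h <- tanh(sweep(x %*% mlp$W1, 2L, as.numeric(mlp$b1), "+"))
  sweep(h %*% mlp$W2, 2L, as.numeric(mlp$b2), "+")
}

node_payloads <- function(graph, traj, dims) {
  n <- nrow(graph$nodes)
  list(
    state_rows = which(graph$nodes$kind == "state"),
    event_rows = which(graph$nodes$kind == "event"),
    action_rows = which(graph$nodes$kind == "action"),
    x = traj$states[graph$nodes$ref[graph$nodes$kind == "state"], , drop = FALSE],
    z = traj$events$z[graph$nodes$ref[graph$nodes$kind == "event"], , drop = FALSE],
    u = traj$actions$u[graph$nodes$ref[graph$nodes$kind == "action"], , drop = FALSE]
  )
}

#' Initialize node embeddings by semantic type
#'
#' Each node's layer-0 embedding is produced by the embedding MLP of its kind:
#' `phi_x` for physiological state samples, `phi_e` for clinical events,
#' `phi_a` for intervention actions. All three map into the shared latent
#' space of dimension `D`.
#'
#' @param graph A `cardio_graph`.
#' @param traj The `patient_trajectory` the graph was built from (payloads).
#' @param params A `cgse_params`.
#' @return An `encoder_state` with `per_layer[[1]]` (layer 0) filled: an
#'   `n_nodes x D` matrix ordered by node id.
#' @export
init_node_embeddings <- function(graph, traj, params) {
  dims <- params$dims
  pl <- node_payloads(graph, traj, dims)
  if (length(pl$state_rows) && ncol(pl$x) != dims$d)
    stop("init_node_embeddings: state dimension mismatch (expected d=", dims$d, ")")
  if (length(pl$event_rows) && ncol(pl$z) != dims$d_e)
    stop("init_node_embeddings: event feature dimension mismatch (expected d_e=", dims$d_e, ")")
  if (length(pl$action_rows) && ncol(pl$u) != dims$d_a)
    stop("init_node_embeddings: action feature dimension mismatch (expected d_a=", dims$d_a, ")")
  H <- matrix(0, nrow(graph$nodes), dims$D)
  if (length(pl$state_rows)) H[pl$state_rows, ] <- mlp_forward(pl$x, params$theta$phi_x)
  if (length(pl$event_rows)) H[pl$event_rows, ] <- mlp_forward(pl$z, params$theta$phi_e)
  if (length(pl$action_rows)) H[pl$action_rows, ] <- mlp_forward(pl$u, params$theta$phi_a)
  structure(list(per_layer = list(H), aggregated = NULL, fused = NULL,
                 fused_times = NULL), class = "encoder_state")
}

attention_scores <- function(H, graph, params, src, dst) {
  psi <- as.numeric(params$theta$psi)
  D <- params$dims$D
  sim <- H[src, , drop = FALSE] %*% psi[1:D] + H[dst, , drop = FALSE] %*% psi[(D + 1):(2 * D)]
  if (params$dims$clamp_attention) sim <- pmax(sim, 0)
  dtv <- abs(graph$nodes$time[dst] - graph$nodes$time[src])
  as.numeric(-params$dims$lambda_attn * dtv * sim)
}

#' Temporal-attention coefficients of one node
#'
#' Softmax over the in-neighborhood `N(v)` of the score
#' `-lambda * |t_v - t_u| * psi' [h_u || h_v]`, coupling temporal distance and
#' semantic similarity. Weights are strictly positive and sum to one.
#'
#' @param H `n_nodes x D` embedding matrix for the current layer.
#' @param graph A `cardio_graph`.
#' @param params A `cgse_params`.
#' @param v Target node id (must have at least one in-neighbor).
#' @return Named numeric vector of weights over the in-neighbors of `v`.
#' @export
attention_coefficients <- function(H, graph, params, v) {
  nb <- in_neighbors(graph, v)
  if (!length(nb)) stop("attention_coefficients: node ", v, " has no neighbors")
  s <- attention_scores(H, graph, params, nb, rep(v, length(nb)))
  e <- exp(s - max(s))
  stats::setNames(e / sum(e), nb)
}

#' One attention-weighted propagation layer
#'
#' `h_v <- sigma( sum_u alpha_uv W^(l) h_u )` over in-neighbors. Nodes without
#' in-neighbors keep their previous embedding (the update is undefined for an
#' empty neighborhood).
#'
#' @param H Current `n_nodes x D` embeddings.
#' @param graph A `cardio_graph`.
#' @param params A `cgse_params`.
#' @param l Layer index in `1..L`.
#' @return Updated `n_nodes x D` matrix.
#' @export
propagate_layer <- function(H, graph, params, l) {
  if (l < 1L || l > params$dims$L) stop("propagate_layer: no parameters for layer ", l)
  W <- params$theta$W_layers[[l]]
  sigma <- activation_fn(params$dims$activation)
  e <- graph$edges
  n <- nrow(graph$nodes)
  if (!nrow(e)) return(H)
  s <- attention_scores(H, graph, params, e$src, e$dst)
  # per-target softmax, stabilised
  smax <- tapply(s, e$dst, max)
  ex <- exp(s - smax[as.character(e$dst)])
  den <- tapply(ex, e$dst, sum)
  alpha <- as.numeric(ex / den[as.character(e$dst)])
  msg <- alpha * (H[e$src, , drop = FALSE] %*% W)
  agg <- matrix(0, n, ncol(H))
  acc <- rowsum(msg, group = e$dst)
  agg[as.integer(rownames(acc)), ] <- acc
  out <- sigma(agg)
  isolated <- setdiff(seq_len(n), unique(e$dst))
  if (length(isolated)) out[isolated, ] <- H[isolated, , drop = FALSE]
  out
}

#' Average node embeddings over propagation layers
#'
#' `h_v^agg = (1/L) sum_{l=1..L} h_v^(l)` (layer 0 excluded).
#'
#' @param state An `encoder_state` with layers `1..L` computed.
#' @param L Number of layers to average (`>= 1`).
#' @return `n_nodes x D` matrix.
#' @export
aggregate_layers <- function(state, L) {
  if (L < 1L) stop("aggregate_layers: L must be >= 1")
  if (length(state$per_layer) < L + 1L)
    stop("aggregate_layers: layers 1..", L, " not computed")
  Reduce(`+`, state$per_layer[2:(L + 1L)]) / L
}

#' Contextual gate coefficient
#'
#' `gamma = sigmoid( w_g' [h_v_agg || h_x_agg] + b_g )`, strictly inside
#' `(0, 1)`.
#'
#' @param h_v_agg Aggregated embedding of the context (event/action) node.
#' @param h_x_agg Aggregated embedding of the state node.
#' @param params A `cgse_params`.
#' @return Scalar in `(0, 1)`.
#' @export
gate_coefficient <- function(h_v_agg, h_x_agg, params) {
  z <- sum(as.numeric(params$theta$w_g) * c(as.numeric(h_v_agg), as.numeric(h_x_agg))) +
    as.numeric(params$theta$b_g)
  1 / (1 + exp(-z))
}

#' Fuse a state embedding with its preceding clinical context
#'
#' `h~_t = h_agg(x_t) + sum_{v in C_t} gamma_{v,t} h_agg(v)` where `C_t` is
#' the set of event and action nodes strictly preceding time `t`.
#'
#' @param state An `encoder_state` with `aggregated` filled.
#' @param graph A `cardio_graph`.
#' @param t A state timestamp of the trajectory.
#' @param params A `cgse_params`.
#' @return Fused embedding (length-`D` numeric vector).
#' @export
contextual_fusion <- function(state, graph, t, params) {
  A <- state$aggregated
  sn <- which(graph$nodes$kind == "state" & abs(graph$nodes$time - t) < 1e-12)
  if (!length(sn)) stop("contextual_fusion: t is not a state timestamp")
  ctx <- which(graph$nodes$kind != "state" & graph$nodes$time < t)
  h <- A[sn[1], ]
  for (v in ctx) {
    g <- gate_coefficient(A[v, ], A[sn[1], ], params)
    h <- h + g * A[v, ]
  }
  h
}

#' Counterfactual intervention simulation operator
#'
#' `S(h, u, dt) = h + eta * exp(-lambda_sim * dt) * tanh(W_s [h || u] + b_s)`.
#' The perturbation decays exponentially with the elapsed time since the
#' intervention and is bounded by `eta * exp(-lambda_sim * dt)` in sup norm.
#'
#' @param h Latent vector (length `D`).
#' @param u Action feature vector (length `d_a`).
#' @param dt Elapsed seconds since the intervention (`>= 0`).
#' @param params A `cgse_params`.
#' @return Length-`D` numeric vector.
#' @export
simulate_intervention <- function(h, u, dt, params) {
  if (dt < 0) stop("simulate_intervention: dt must be >= 0")
  th <- params$theta
  resp <- tanh(as.numeric(c(h, u) %*% th$W_s) + as.numeric(th$b_s))
  as.numeric(h) + as.numeric(th$eta) * exp(-params$dims$lambda_sim * dt) * resp
}

#' Run the full encoder on one trajectory
#'
#' Composes typed initialization, `L` attention-propagation layers, layer
#' aggregation and contextual fusion, yielding one fused embedding per state
#' timestamp.
#'
#' @param traj A `patient_trajectory`.
#' @param graph Its `cardio_graph`.
#' @param params A `cgse_params`.
#' @return An `encoder_state` with `per_layer` (`0..L`), `aggregated`
#'   (`n_nodes x D`) and `fused` (`n_states x D`, rows ordered by time).
#' @export
encode_trajectory <- function(traj, graph, params) {
  state <- init_node_embeddings(graph, traj, params)
  H <- state$per_layer[[1]]
  for (l in seq_len(params$dims$L)) {
    H <- propagate_layer(H, graph, params, l)
    state$per_layer[[l + 1L]] <- H
  }
  state$aggregated <- aggregate_layers(state, params$dims$L)
  fused <- matrix(0, length(traj$timestamps), params$dims$D)
  for (i in seq_along(traj$timestamps))
    fused[i, ] <- contextual_fusion(state, graph, traj$timestamps[i], params)
  state$fused <- fused
  state$fused_times <- traj$timestamps
  state
}
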