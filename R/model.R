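# Tape-based training forward pass. Reproduces the numeric encoder/fusion
# maps (encoder.R, fusion.R) on the autodiff tape and assembles every loss
# component; agreement between the two paths is asserted in the test suite.

# Precompute everything about one patient that does not depend on parameters.
compile_patient <- function(traj, graph, dims, opts, prior_targets = NULL) {
  nodes <- graph$nodes
  n_nodes <- nrow(nodes)
  Tn <- length(traj$timestamps)
  state_node <- nodes$id[nodes$kind == "state"]
  state_node <- state_node[order(nodes$time[state_node])]
  event_node <- nodes$id[nodes$kind == "event"]
  action_node <- nodes$id[nodes$kind == "action"]

  # node id -> row in rbind(states, events, actions) embedding blocks
  # (each block is in trajectory record order; nodes$ref points into it)
  n_ev <- length(event_node)
  perm <- integer(n_nodes)
  perm[state_node] <- nodes$ref[state_node]
  perm[event_node] <- Tn + nodes$ref[event_node]
  perm[action_node] <- Tn + n_ev + nodes$ref[action_node]

  e <- graph$edges
  edge_decay <- -dims$lambda_attn * abs(nodes$time[e$dst] - nodes$time[e$src])
  isolated <- setdiff(seq_len(n_nodes), unique(e$dst))
  iso_mask <- matrix(1, n_nodes, dims$D)
  if (length(isolated)) iso_mask[isolated, ] <- 0

  # gating context pairs: (non-state node, state index) with t_ctx < t_state
  ctx_nodes <- c(event_node, action_node)
  cp_ctx <- integer(0); cp_state <- integer(0)
  for (v in ctx_nodes) {
    later <- which(traj$timestamps > nodes$time[v] + 0)
    later <- later[nodes$time[v] < traj$timestamps[later]]
    if (length(later)) {
      cp_ctx <- c(cp_ctx, rep(v, length(later)))
      cp_state <- c(cp_state, later)
    }
  }

  # normalized-time interpolation onto the common alignment grid
  n_grid <- opts$n_grid
  if (Tn > 1L) {
    tau <- (traj$timestamps - traj$timestamps[1]) /
      (traj$timestamps[Tn] - traj$timestamps[1])
    grid <- seq(0, 1, length.out = n_grid)
    lo <- pmax(pmin(findInterval(grid, tau), Tn - 1L), 1L)
    hi <- lo + 1L
    wgt <- (grid - tau[lo]) / (tau[hi] - tau[lo])
    wgt[!is.finite(wgt)] <- 0
  } else {
    tau <- 0
    lo <- rep(1L, n_grid); hi <- rep(1L, n_grid); wgt <- rep(0, n_grid)
  }

  # multi-resolution stride views: arc-length dtau and geometry pairs
  strides <- opts$strides
  stride_views <- lapply(strides, function(st) {
    idx <- seq(1L, Tn, by = st)
    if (length(idx) < 2L) return(NULL)
    taus <- tau[idx]
    pairs <- geometry_pairs(length(idx), opts$n_rand_pairs, opts$pair_seed)
    dobs <- vapply(seq_len(nrow(pairs)), function(k) {
      observed_change(traj, traj$timestamps[idx[pairs[k, 1]]],
                      traj$timestamps[idx[pairs[k, 2]]])
    }, numeric(1))
    list(idx = idx, dtau_inv = 1 / diff(taus),
         pi = idx[pairs[, 1]], pj = idx[pairs[, 2]], dobs = dobs)
  })
  stride_views <- Filter(Negate(is.null), stride_views)

  # contiguous equal segments for stage statistics
  stage_K <- min(dims$K, Tn)
  size <- Tn %/% stage_K
  stage_group <- pmin(((seq_len(Tn) - 1L) %/% max(size, 1L)) + 1L, stage_K)
  stage_count <- tabulate(stage_group, stage_K)

  # events: anchor label index and nearest state index
  ev <- NULL
  if (length(event_node)) {
    ev <- list(
      state_idx = vapply(nodes$time[event_node],
                         function(tt) which.min(abs(traj$timestamps - tt)), integer(1)),
      label = nodes$label[event_node])
  }

  # interventions: pre/post state indices and elapsed time
  iv <- NULL
  if (length(action_node)) {
    keep <- list()
    for (vn in action_node) {
      rho <- nodes$time[vn]
      post <- which(traj$timestamps > rho)
      pre <- which(traj$timestamps <= rho)
      if (!length(post) || !length(pre)) next
      keep[[length(keep) + 1L]] <- list(
        u = traj$actions$u[nodes$ref[vn], ],
        label = nodes$label[vn],
        pre = max(pre), post = min(post),
        dt = traj$timestamps[min(post)] - rho)
    }
    if (length(keep)) iv <- keep[seq_len(min(length(keep), opts$max_interventions))]
  }

  und <- undirected_support(graph)

  list(traj = traj, graph = graph, Tn = Tn, n_nodes = n_nodes,
       state_node = state_node, perm = perm,
       edge_src = e$src, edge_dst = e$dst, edge_decay = edge_decay,
       iso_mask = iso_mask, cp_ctx = cp_ctx, cp_state = cp_state,
       interp = list(lo = lo, hi = hi, w = wgt),
       stride_views = stride_views,
       stage_group = stage_group, stage_count = stage_count, stage_K = stage_K,
       events = ev, interventions = iv,
       lap_u = und$u, lap_v = und$v,
       prior_targets = prior_targets,
       x = traj$states, z = traj$events$z, u = traj$actions$u,
       times = traj$timestamps)
}

register_theta <- function(tape, theta) {
  rapply(theta, function(m) tp_leaf(tape, m), classes = "matrix", how = "replace")
}

tape_mlp <- function(x, mlp) {
  h <- tp_tanh(tp_add_rowvec(tp_matmul(x, mlp$W1), mlp$b1))
  tp_add_rowvec(tp_matmul(h, mlp$W2), mlp$b2)
}

tape_activation <- function(a, name) {
  switch(name, tanh = tp_tanh(a), relu = tp_relu(a), sigmoid = tp_sigmoid(a),
         identity = a)
}

# encoder + fusion forward for one compiled patient; returns tape nodes
patient_forward <- function(tape, th, cp, dims, opts) {
  D <- dims$D
  xin <- tp_leaf(tape, cp$x)
  blocks <- tape_mlp(xin, th$phi_x)
  if (!is.null(cp$z) && nrow(cp$z)) {
    blocks <- tp_rbind(blocks, tape_mlp(tp_leaf(tape, cp$z), th$phi_e))
  }
  if (!is.null(cp$u) && nrow(cp$u)) {
    blocks <- tp_rbind(blocks, tape_mlp(tp_leaf(tape, cp$u), th$phi_a))
  }
  H <- tp_rows(blocks, cp$perm)  # node-id order

  psi1 <- tp_rows(th$psi, 1:D)
  psi2 <- tp_rows(th$psi, (D + 1):(2 * D))
  decay <- tp_leaf(tape, matrix(cp$edge_decay, ncol = 1L))
  maskc <- tp_leaf(tape, cp$iso_mask)
  invmask <- tp_leaf(tape, 1 - cp$iso_mask)

  layers <- vector("list", dims$L)
  for (l in seq_len(dims$L)) {
    Hu <- tp_rows(H, cp$edge_src)
    Hv <- tp_rows(H, cp$edge_dst)
    sim <- tp_add(tp_matmul(Hu, psi1), tp_matmul(Hv, psi2))
    if (dims$clamp_attention) sim <- tp_relu(sim)
    scores <- tp_mul(sim, decay)
    alpha <- tp_segment_softmax(scores, cp$edge_dst)
    msg <- tp_colmul(tp_matmul(Hu, th$W_layers[[l]]), alpha)
    agg <- tp_segment_sum(msg, cp$edge_dst, cp$n_nodes)
    act <- tape_activation(agg, dims$activation)
    H <- tp_add(tp_mul(act, maskc), tp_mul(H, invmask))
    layers[[l]] <- H
  }
  Hagg <- tp_scale(Reduce(tp_add, layers), 1 / dims$L)

  Hx <- tp_rows(Hagg, cp$state_node)          # per-state aggregated embeddings
  if (length(cp$cp_ctx)) {
    ctxA <- tp_rows(Hagg, cp$cp_ctx)
    stA <- tp_rows(Hx, cp$cp_state)
    gz <- tp_add_rowvec(tp_matmul(tp_cbind(ctxA, stA), th$w_g), th$b_g)
    gates <- tp_sigmoid(gz)
    ctx_sum <- tp_segment_sum(tp_colmul(ctxA, gates), cp$cp_state, cp$Tn)
    h_tilde <- tp_add(Hx, ctx_sum)
  } else {
    h_tilde <- Hx
  }

  # trajectory pooling (part of the representation; feeds no loss term)
  pscore <- tp_matmul(tp_tanh(tp_matmul(h_tilde, th$W_q)), th$q)
  pw <- tp_segment_softmax(pscore, rep(1L, cp$Tn))
  H_p <- tp_segment_sum(tp_colmul(h_tilde, pw), rep(1L, cp$Tn), 1L)

  r <- tp_gru(h_tilde, th$gru_f)
  rev_idx <- rev(seq_len(cp$Tn))
  brev <- tp_gru(tp_rows(h_tilde, rev_idx), th$gru_b)
  b <- tp_rows(brev, rev_idx)
  cmat <- tp_add_rowvec(tp_matmul(tp_cbind(r, b), th$W_f), th$b_f)
  s <- tp_add(h_tilde, cmat)

  list(H = H, Hagg = Hagg, h_tilde = h_tilde, r = r, b = b, c = cmat, s = s,
       H_p = H_p)
}

# simulation operator on tape: h (1 x D) + eta exp(-lambda dt) tanh([h||u]Ws+bs)
tape_simulate <- function(h, u_const, dt, th, dims) {
  cat_in <- tp_cbind(h, u_const)
  pert <- tp_tanh(tp_add_rowvec(tp_matmul(cat_in, th$W_s), th$b_s))
  tp_add(h, tp_scale(tp_scale_node(pert, th$eta), exp(-dims$lambda_sim * dt)))
}

# per-patient loss components on tape
patient_losses <- function(tape, th, fw, cp, dims, opts, registry) {
  zero <- function() tp_leaf(tape, matrix(0, 1L, 1L))
  s <- fw$s
  Tn <- cp$Tn

  # prediction: h-step-ahead forecast of the observed state
  h <- opts$horizon
  pred_loss <- zero()
  if (Tn > h) {
    pred <- tp_add_rowvec(tp_matmul(tp_rows(s, 1:(Tn - h)), th$W_o), th$b_o)
    if (identical(dims$head, "residual"))
      pred <- tp_add(pred, tp_leaf(tape, cp$x[1:(Tn - h), , drop = FALSE]))
    target <- tp_leaf(tape, cp$x[(h + 1):Tn, , drop = FALSE])
    res <- tp_sub(pred, target)
    if (!is.null(opts$risk_center)) {
      wts <- exp(-(cp$times[1:(Tn - h)] - opts$risk_center)^2 / (2 * opts$risk_sigma^2))
      res_sq <- tp_mul(tp_rowsumsq(res), tp_leaf(tape, matrix(wts, ncol = 1L)))
      pred_loss <- tp_scale(tp_sum(res_sq), 1 / ((Tn - h) * dims$d))
    } else if (identical(opts$loss_type, "l1")) {
      pred_loss <- tp_scale(tp_sum(tp_abs(res)), 1 / ((Tn - h) * dims$d))
    } else {
      pred_loss <- tp_scale(tp_sumsq(res), 1 / ((Tn - h) * dims$d))
    }
  }

  # clinical prior projection (per-time-step mean)
  prior <- zero()
  if (!is.null(cp$prior_targets)) {
    f <- tp_add_rowvec(tp_matmul(s, th$W_p), th$b_p)
    prior <- tp_scale(tp_sumsq(tp_sub(f, tp_leaf(tape, cp$prior_targets))), 1 / Tn)
  }

  # multi-resolution arc length and geometry hinge; each term is normalized
  # by its number of summands so the curriculum weights are scale-free in the
  # sequence length
  arc <- zero(); geom <- zero()
  n_arc <- 0L; n_geom <- 0L
  for (sv in cp$stride_views) {
    sd <- tp_sub(tp_rows(s, sv$idx[-1]), tp_rows(s, sv$idx[-length(sv$idx)]))
    arc <- tp_add(arc, tp_sum(tp_mul(tp_rowsumsq(sd),
                                     tp_leaf(tape, matrix(sv$dtau_inv, ncol = 1L)))))
    n_arc <- n_arc + length(sv$idx) - 1L
    pd <- tp_sub(tp_rows(s, sv$pi), tp_rows(s, sv$pj))
    dlat <- tp_sqrt(tp_rowsumsq(pd))
    gap <- tp_abs(tp_sub(dlat, tp_leaf(tape, matrix(sv$dobs, ncol = 1L))))
    geom <- tp_add(geom, tp_sumsq(tp_relu(tp_add_const(gap, -dims$epsilon_geom))))
    n_geom <- n_geom + length(sv$pi)
  }
  if (n_arc > 0L) arc <- tp_scale(arc, 1 / n_arc)
  if (n_geom > 0L) geom <- tp_scale(geom, 1 / n_geom)

  # stage separation from contiguous-segment centroids
  stage_sep <- zero()
  K <- cp$stage_K
  if (K >= 2L) {
    mu <- tp_colmul(tp_segment_sum(s, cp$stage_group, K),
                    tp_leaf(tape, matrix(1 / cp$stage_count, ncol = 1L)))
    ij <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
    dmu <- tp_sub(tp_rows(mu, ij[, 1]), tp_rows(mu, ij[, 2]))
    stage_sep <- tp_sum(tp_exp(tp_scale(tp_rowsumsq(dmu), -1)))
  }

  # event anchors
  event_anchor <- zero()
  if (!is.null(cp$events)) {
    lab_idx <- match(cp$events$label, opts$event_labels)
    ok <- !is.na(lab_idx)
    if (any(ok)) {
      sE <- tp_rows(s, cp$events$state_idx[ok])
      cE <- tp_rows(th$anchors, lab_idx[ok])
      event_anchor <- tp_scale(tp_sumsq(tp_sub(sE, cE)), 1 / sum(ok))
    }
  }

  # Laplacian smoothness of the aggregated node embeddings
  laplacian <- zero()
  if (length(cp$lap_u)) {
    laplacian <- tp_scale(tp_sumsq(tp_sub(tp_rows(fw$Hagg, cp$lap_u),
                                          tp_rows(fw$Hagg, cp$lap_v))),
                          1 / length(cp$lap_u))
  }

  # intervention orientation via the counterfactual bridge: simulate from the
  # last pre-intervention fused state, splice into the fusion at the first
  # post-intervention step (single GRU steps; all other time steps fixed)
  interv <- zero()
  ivs <- Filter(function(iv) !is.null(registry$fields[[iv$label]]),
                cp$interventions %||% list())
  if (length(ivs)) {
    D <- dims$D
    for (ivn in ivs) {
      u_const <- tp_leaf(tape, matrix(ivn$u, nrow = 1L))
      hpre <- tp_rows(fw$h_tilde, ivn$pre)
      hhat <- tape_simulate(hpre, u_const, ivn$dt, th, dims)
      tpr <- ivn$post
      rprev <- if (tpr > 1L) tp_rows(fw$r, tpr - 1L) else tp_leaf(tape, matrix(0, 1L, D))
      bnext <- if (tpr < Tn) tp_rows(fw$b, tpr + 1L) else tp_leaf(tape, matrix(0, 1L, D))
      rhat <- tp_gru_step(hhat, rprev, th$gru_f)
      bhat <- tp_gru_step(hhat, bnext, th$gru_b)
      chat <- tp_add_rowvec(tp_matmul(tp_cbind(rhat, bhat), th$W_f), th$b_f)
      shat <- tp_add(hhat, chat)
      delta <- tp_sub(shat, tp_rows(fw$s, tpr))
      g <- eval_field(registry, ivn$label, ivn$u, ivn$dt)
      interv <- tp_add(interv, tp_sumsq(tp_sub(delta, tp_leaf(tape, matrix(g, nrow = 1L)))))
    }
    interv <- tp_scale(interv, 1 / length(ivs))
  }

  list(prediction = pred_loss, prior = prior, arc = arc, geometry = geom,
       stage_sep = stage_sep, event_anchor = event_anchor,
       laplacian = laplacian, interv_orient = interv)
}

# pairwise alignment components between two forwarded patients
pair_losses <- function(tape, fw_p, fw_q, cp_p, cp_q) {
  interp_node <- function(fw, cp) {
    lo <- tp_rows(fw$s, cp$interp$lo)
    hi <- tp_rows(fw$s, cp$interp$hi)
    tp_add(tp_colmul(lo, tp_leaf(tape, matrix(1 - cp$interp$w, ncol = 1L))),
           tp_colmul(hi, tp_leaf(tape, matrix(cp$interp$w, ncol = 1L))))
  }
  align <- tp_scale(tp_sumsq(tp_sub(interp_node(fw_p, cp_p),
                                    interp_node(fw_q, cp_q))),
                    1 / length(cp_p$interp$lo))
  pi_map <- nearest_index_alignment(cp_p$times, cp_q$times)
  soft <- tp_scale(tp_sumsq(tp_sub(fw_p$s, tp_rows(fw_q$s, pi_map))), 1 / cp_p$Tn)
  list(align = align, soft_align = soft)
}

anchor_sep_node <- function(tape, th, dims, n_labels) {
  if (n_labels < 2L) return(tp_leaf(tape, matrix(0, 1L, 1L)))
  ij <- which(upper.tri(matrix(0, n_labels, n_labels)), arr.ind = TRUE)
  dC <- tp_sub(tp_rows(th$anchors, ij[, 1]), tp_rows(th$anchors, ij[, 2]))
  tp_sum(tp_inv(tp_add_const(tp_rowsumsq(dC), dims$eps_anchor)))
}
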