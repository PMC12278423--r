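test_that("node initialization dispatches on node type", {
  traj <- toy_trajectory(ts = c(0, 1, 2), d = 2,
                         states = matrix(c(1, 1, 1, 1, 2, 2), ncol = 2, byrow = TRUE),
                         events = list(t = 0.5, label = "A", z = matrix(3, 1, 2)))
  g <- build_graph(traj, causal_prior_table(), window = 0.6)
  p <- toy_params(d = 2, D = 3)
  st <- init_node_embeddings(g, traj, p)
  H0 <- st$per_layer[[1]]
  s1 <- which(g$nodes$kind == "state" & g$nodes$time == 0)
  s2 <- which(g$nodes$kind == "state" & g$nodes$time == 1)
  # identical inputs give identical embeddings
  expect_equal(H0[s1, ], H0[s2, ])
  # event node goes through phi_e: zero out phi_e and only it vanishes
  p0 <- p
  p0$theta$phi_e$W2 <- p0$theta$phi_e$W2 * 0
  p0$theta$phi_e$b2 <- p0$theta$phi_e$b2 * 0
  H0z <- init_node_embeddings(g, traj, p0)$per_layer[[1]]
  ev <- which(g$nodes$kind == "event")
  expect_equal(H0z[ev, ], rep(0, 3))
  expect_equal(H0z[s1, ], H0[s1, ])
  # dimension mismatch is rejected
  pbad <- toy_params(d = 5, D = 3)
  expect_error(init_node_embeddings(g, traj, pbad), "dimension mismatch")
})

test_that("an affine embedding MLP reproduces the identity map", {
  traj <- toy_trajectory(ts = c(0, 1), d = 3,
                         states = matrix(c(0.3, -0.2, 0.5, 1, 2, 3), 2, byrow = TRUE))
  p <- toy_params(d = 3, D = 3)
  p <- set_mlp_affine(p, "phi_x", diag(3))
  g <- build_graph(traj, causal_prior_table(), window = 0.5)
  H0 <- init_node_embeddings(g, traj, p)$per_layer[[1]]
  expect_equal(H0, traj$states, tolerance = 1e-7)
})

test_that("attention weights are a proper softmax over the neighborhood", {
  case <- random_graph_case(5)
  p <- toy_params()
  H <- init_node_embeddings(case$graph, case$traj, p)$per_layer[[1]]
  v <- case$graph$edges$dst[1]
  w <- attention_coefficients(H, case$graph, p, v)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # single neighbor means weight one
  traj <- toy_trajectory(ts = c(0, 10), d = 2)
  g1 <- build_graph(traj, causal_prior_table(), window = 1)
  H1 <- init_node_embeddings(g1, traj, p)$per_layer[[1]]
  expect_equal(unname(attention_coefficients(H1, g1, p, 1L)), 1)
  # equal time gaps and identical embeddings split evenly
  traj3 <- toy_trajectory(ts = c(0, 1, 2), d = 2,
                          states = matrix(1, 3, 2))
  g3 <- build_graph(traj3, causal_prior_table(), window = 1.5)
  H3 <- init_node_embeddings(g3, traj3, p)$per_layer[[1]]
  w3 <- attention_coefficients(H3, g3, p, 2L)  # middle node, two neighbors
  expect_equal(unname(w3), c(0.5, 0.5), tolerance = 1e-12)
  # isolated node is an error
  expect_error(attention_coefficients(H1, g1, p, 99L), "no neighbors")
})

test_that("softmax of hand-set exponent arguments matches direct evaluation", {
  # exponents (-0.5, -1.0): weights e^-0.5 and e^-1, normalized
  e <- exp(c(-0.5, -1))
  expect_equal(e / sum(e), c(0.6225, 0.3775), tolerance = 1e-4)
  # realized through the encoder: two neighbors at equal |dt|, psi picking
  # out a single coordinate that differs between the neighbors
  traj <- toy_trajectory(ts = c(0, 1, 2), d = 1,
                         states = matrix(c(0.5, 0, 1.0), ncol = 1))
  p <- toy_params(d = 1, D = 1, L = 1, lambda_attn = 1)
  p <- set_mlp_affine(p, "phi_x", matrix(1, 1, 1))
  p$theta$psi <- matrix(c(1, 0), 2, 1)  # score = -1 * |dt| * h_u
  g <- build_graph(traj, causal_prior_table(), window = 1.5)
  H <- init_node_embeddings(g, traj, p)$per_layer[[1]]
  w <- attention_coefficients(H, g, p, 2L)
  expect_equal(unname(w), c(0.6225, 0.3775), tolerance = 1e-4)
})

test_that("propagation matches a hand-computed star graph", {
  # 3-node path 1-2-3 (window small so only backbone), W = identity,
  # activation identity: h_2' = a_12 h_1 + a_32 h_3
  traj <- toy_trajectory(ts = c(0, 1, 2), d = 2,
                         states = matrix(c(1, 0, 0, 0, 0, 1), 3, byrow = TRUE))
  p <- toy_params(d = 2, D = 2, L = 1, activation = "identity")
  p <- set_mlp_affine(p, "phi_x", diag(2))
  p$theta$W_layers[[1]] <- diag(2)
  g <- build_graph(traj, causal_prior_table(), window = 0.5)
  H0 <- init_node_embeddings(g, traj, p)$per_layer[[1]]
  w <- attention_coefficients(H0, g, p, 2L)
  H1 <- propagate_layer(H0, g, p, 1L)
  expect_equal(H1[2, ], w[["1"]] * H0[1, ] + w[["3"]] * H0[3, ], tolerance = 1e-9)
  # single-neighbor node copies its neighbor under identity transform
  expect_equal(H1[1, ], H0[2, ], tolerance = 1e-9)
  # zero inputs stay zero under tanh
  p2 <- toy_params(d = 2, D = 2, L = 1)
  expect_equal(propagate_layer(matrix(0, 3, 2), g, p2, 1L), matrix(0, 3, 2))
  # unknown layer index is rejected
  expect_error(propagate_layer(H0, g, p, 7L), "layer")
})

test_that("layer aggregation averages layers 1..L", {
  st <- structure(list(per_layer = list(matrix(9, 1, 2),      # layer 0 ignored
                                        matrix(c(1, 0), 1, 2),
                                        matrix(c(0, 1), 1, 2))),
                  class = "encoder_state")
  expect_equal(aggregate_layers(st, 2L), matrix(c(0.5, 0.5), 1, 2))
  expect_equal(aggregate_layers(st, 1L), matrix(c(1, 0), 1, 2))
  expect_error(aggregate_layers(st, 0L), "L")
})

test_that("gate coefficient is a logistic in the open unit interval", {
  p <- toy_params(D = 2)
  p$theta$w_g <- matrix(0, 4, 1)
  p$theta$b_g <- matrix(0, 1, 1)
  expect_equal(gate_coefficient(c(1, 2), c(3, 4), p), 0.5)
  # logistic at 1
  p$theta$b_g <- matrix(1, 1, 1)
  expect_equal(gate_coefficient(c(0, 0), c(0, 0), p), 1 / (1 + exp(-1)),
               tolerance = 1e-9)
  expect_equal(round(gate_coefficient(c(0, 0), c(0, 0), p), 4), 0.7311)
  # saturation stays inside (0,1)
  p$theta$b_g <- matrix(10, 1, 1)
  g <- gate_coefficient(c(0, 0), c(0, 0), p)
  expect_true(g > 0.99 && g < 1)
  for (seed in 1:20) {
    set.seed(seed)
    pr <- toy_params(D = 2, seed = seed)
    gg <- gate_coefficient(rnorm(2), rnorm(2), pr)
    expect_true(gg > 0 && gg < 1)
  }
})

test_that("contextual fusion adds gated context strictly before t", {
  traj <- toy_trajectory(ts = c(0, 1, 2), d = 2,
                         events = list(t = 1.5, label = "A", z = matrix(1, 1, 2)))
  g <- build_graph(traj, causal_prior_table(), window = 0.6)
  p <- toy_params(d = 2, D = 3)
  st <- encode_trajectory(traj, g, p)
  # t = 0: no preceding context
  h0 <- contextual_fusion(st, g, 0, p)
  sn0 <- which(g$nodes$kind == "state" & g$nodes$time == 0)
  expect_equal(h0, st$aggregated[sn0, ])
  # a closed gate removes the context contribution
  pz <- p
  pz$theta$w_g <- pz$theta$w_g * 0
  pz$theta$b_g <- matrix(-1e9, 1, 1)
  stz <- encode_trajectory(traj, g, pz)
  sn2 <- which(g$nodes$kind == "state" & g$nodes$time == 2)
  expect_equal(contextual_fusion(stz, g, 2, pz), stz$aggregated[sn2, ])
  # gamma = 0.5, h_v = (2,0,0), h_x = 0 gives h~ = (1,0,0)
  A <- st$aggregated * 0
  ev <- which(g$nodes$kind == "event")
  A[ev, ] <- c(2, 0, 0)
  st2 <- st; st2$aggregated <- A
  p5 <- p
  p5$theta$w_g <- p5$theta$w_g * 0
  p5$theta$b_g <- matrix(0, 1, 1)  # gate 0.5
  expect_equal(contextual_fusion(st2, g, 2, p5), c(1, 0, 0))
})

test_that("simulation operator decays and is bounded by eta exp(-lambda dt)", {
  p <- toy_params(D = 3, d_a = 2, lambda_sim = 1)
  p$theta$eta <- matrix(0.5, 1, 1)
  h <- c(0.3, -0.2, 0.1); u <- c(1, -1)
  # eta = 0 is the identity
  p0 <- p; p0$theta$eta <- matrix(0, 1, 1)
  expect_equal(simulate_intervention(h, u, 2, p0), h)
  # bound at dt = 1: 0.5 * e^-1
  dev <- max(abs(simulate_intervention(h, u, 1, p) - h))
  expect_lte(dev, 0.5 * exp(-1) + 1e-12)
  expect_lte(0.5 * exp(-1), 0.1840)  # the stated envelope value
  # non-increasing deviation over a dt grid
  devs <- vapply(seq(0, 5, length.out = 20),
                 function(dt) max(abs(simulate_intervention(h, u, dt, p) - h)),
                 numeric(1))
  expect_true(all(diff(devs) <= 1e-12))
  expect_error(simulate_intervention(h, u, -1, p), "dt")
})

test_that("whole-encoder pass is deterministic", {
  case <- random_graph_case(9)
  p <- toy_params()
  s1 <- encode_trajectory(case$traj, case$graph, p)
  s2 <- encode_trajectory(case$traj, case$graph, p)
  expect_identical(s1, s2)
})
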