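test_that("alignment loss is a symmetric squared distance on the grid", {
  s <- matrix(rnorm(12), 4, 3)
  expect_equal(alignment_loss(s, s), 0)
  s2 <- s; s2[, 1] <- s2[, 1] + 1
  expect_equal(alignment_loss(s[1:3, ], s2[1:3, ]), 3)
  expect_equal(alignment_loss(s, s2), alignment_loss(s2, s))
  expect_error(alignment_loss(s, s[1:2, ]), "equal shape")
})

test_that("normalized-time resampling interpolates linearly", {
  ts <- c(0, 1, 4)
  s <- matrix(c(0, 1, 4), ncol = 1)  # s = t: linear in time
  rs <- resample_normalized(s, ts, n_grid = 9)
  expect_equal(as.numeric(rs), seq(0, 4, length.out = 9), tolerance = 1e-12)
})

test_that("prior loss is quadratic in the residuals", {
  proj <- prior_projection(diag(2), c(0, 0), matrix(0, 1, 2))
  expect_equal(prior_loss(matrix(c(1, 1), 1, 2), proj), 2)
  expect_equal(prior_loss(matrix(c(0, 0), 1, 2), proj), 0)
  # scaling residuals by 2 quadruples the loss
  expect_equal(prior_loss(matrix(c(2, 2), 1, 2), proj), 8)
  expect_error(prior_projection(diag(2), c(0, 0), matrix(0, 1, 3)), "dimension")
})

test_that("arc length telescopes and vanishes on constant paths", {
  expect_equal(arc_length_loss(matrix(1, 5, 2), 0:4), 0)
  # two points distance 1 over dtau = 1
  expect_equal(arc_length_loss(rbind(c(0, 0), c(1, 0)), c(0, 1)), 1)
  # collinear midpoint refinement leaves the quadrature unchanged
  s2 <- rbind(c(0, 0), c(2, 0))
  s3 <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(arc_length_loss(s2, c(0, 2)), arc_length_loss(s3, c(0, 1, 2)),
               tolerance = 1e-12)
  expect_equal(arc_length_loss(matrix(0, 1, 2), 0), 0)
})

test_that("stage statistics equal brute-force per-segment moments", {
  # 4 scalar points (0,0,2,2), K=2: means (0,2), zero covariance
  seg <- stage_statistics(matrix(c(0, 0, 2, 2), ncol = 1), 2L)
  expect_equal(as.numeric(seg$centroids), c(0, 2))
  expect_equal(seg$covariances[[1]][1, 1], 0)
  expect_equal(seg$covariances[[2]][1, 1], 0)
  # K=1 is the whole-sequence mean and population covariance
  set.seed(5)
  S <- matrix(rnorm(20), 5, 4)
  s1 <- stage_statistics(S, 1L)
  expect_equal(as.numeric(s1$centroids), colMeans(S))
  Xc <- sweep(S, 2, colMeans(S))
  expect_equal(s1$covariances[[1]], crossprod(Xc) / 5, tolerance = 1e-12)
  # random inputs, uneven segments: brute force agreement
  S2 <- matrix(rnorm(21), 7, 3)
  st <- stage_statistics(S2, 3L)
  for (k in 1:3) {
    idx <- st$segments[[k]]
    expect_equal(st$centroids[k, ], colMeans(S2[idx, , drop = FALSE]),
                 tolerance = 1e-12)
    Xc <- sweep(S2[idx, , drop = FALSE], 2, colMeans(S2[idx, , drop = FALSE]))
    expect_equal(st$covariances[[k]], crossprod(Xc) / length(idx),
                 tolerance = 1e-12)
    expect_equal(st$covariances[[k]], t(st$covariances[[k]]), tolerance = 1e-9)
    ev <- eigen(st$covariances[[k]], only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
  }
  # segments partition the index range
  expect_equal(sort(unlist(st$segments)), 1:7)
  expect_error(stage_statistics(S2, 0L), "positive")
  expect_error(stage_statistics(S2, 9L), "shorter")
})

test_that("stage separation is exp(-squared distance) summed over pairs", {
  segc <- list(centroids = matrix(0, 3, 2))
  expect_equal(stage_separation_loss(segc), 3)   # 3 coincident pairs
  seg2 <- list(centroids = rbind(c(0, 0), c(1, 0)))
  expect_equal(stage_separation_loss(seg2), exp(-1))
  expect_equal(round(stage_separation_loss(seg2), 4), 0.3679)
  # strictly decreasing as a pair moves apart
  seg3 <- list(centroids = rbind(c(0, 0), c(1.5, 0)))
  expect_lt(stage_separation_loss(seg3), stage_separation_loss(seg2))
})

test_that("soft alignment matches hand evaluation under monotone maps", {
  s_p <- rbind(c(1, 0), c(0, 1))
  s_q <- rbind(c(1, 0), c(1, 1))
  expect_equal(soft_alignment_loss(s_p, s_p, 1:2), 0)
  expect_equal(soft_alignment_loss(s_p, s_q, c(1, 2)), 0 + 1)
  # degenerate constant map onto a zero target sums the squared norms
  z <- matrix(0, 1, 2)
  expect_equal(soft_alignment_loss(s_p, z, c(1, 1)), sum(s_p^2))
  expect_error(soft_alignment_loss(s_p, s_q, c(1, 7)), "pi")
  # nearest-index map is monotone non-decreasing
  pi_map <- nearest_index_alignment(c(0, 1, 2, 5), c(0, 2.5, 5))
  expect_true(all(diff(pi_map) >= 0))
  expect_equal(pi_map[1], 1L)
  expect_equal(pi_map[4], 3L)
})

test_that("intervention effect and orientation loss are exact", {
  expect_equal(intervention_effect(c(2, 1), c(1, 1)), c(1, 0))
  expect_equal(intervention_effect(c(1, 1), c(1, 1)), c(0, 0))
  expect_equal(intervention_effect(c(1, 1), c(2, 1)),
               -intervention_effect(c(2, 1), c(1, 1)))
  reg <- register_field(vector_field_registry(), "null", c(0, 0), tau = 1)
  expect_equal(intervention_orientation_loss(c(0.6, 0.8), c(1), 0, reg, "null"), 1)
  reg2 <- register_field(vector_field_registry(), "f", c(1, 0), tau = 2)
  g <- eval_field(reg2, "f", u = c(3, 4), dt = 2)  # |u| = 5, decay e^-1
  expect_equal(g, c(5 * exp(-1), 0))
  expect_equal(intervention_orientation_loss(g, c(3, 4), 2, reg2, "f"), 0)
  expect_error(eval_field(reg2, "nope", 1, 1), "unknown field")
  # rotation invariance of the squared-norm mismatch
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d <- c(0.2, -0.4)
  expect_equal(sum((R %*% (d - g))^2), sum((d - g)^2), tolerance = 1e-12)
  # registered fields vanish at long lags
  expect_lt(max(abs(eval_field(reg2, "f", c(3, 4), 1e3))), 1e-12)
})

test_that("event anchors pull states and separate centers", {
  an <- event_anchors(rbind(c(0, 0), c(3, 4)), c("MI", "HF"), eps_anchor = 0.01)
  expect_equal(event_anchor_loss(c(0, 0), an, "MI"), 0)
  expect_equal(event_anchor_loss(c(2, 0), an, "MI"), 4)
  expect_error(event_anchor_loss(c(0, 0), an, "unknown"), "unknown event label")
  # coincident centers: 1/eps
  anc <- event_anchors(matrix(1, 2, 2), c("a", "b"), eps_anchor = 0.01)
  expect_equal(anchor_separation_loss(anc), 100)
  # distance 1: 1/(1 + eps)
  an1 <- event_anchors(rbind(c(0, 0), c(1, 0)), c("a", "b"), eps_anchor = 0.01)
  expect_equal(anchor_separation_loss(an1), 1 / 1.01, tolerance = 1e-12)
  expect_equal(round(anchor_separation_loss(an1), 4), 0.9901)
  # strictly decreasing as centers move apart
  an2 <- event_anchors(rbind(c(0, 0), c(2, 0)), c("a", "b"), eps_anchor = 0.01)
  expect_lt(anchor_separation_loss(an2), anchor_separation_loss(an1))
  expect_error(event_anchors(matrix(0, 2, 2), c("a", "b"), eps_anchor = 0), "eps")
})

test_that("laplacian smoothness equals the edge-sum oracle", {
  # 2-node path with scalar embeddings 0 and 1
  traj <- toy_trajectory(ts = c(0, 1), d = 1)
  g <- build_graph(traj, causal_prior_table(), window = 0.5)
  expect_equal(laplacian_smoothness(matrix(c(0, 1), 2, 1), g), 1)
  expect_equal(laplacian_smoothness(matrix(5, 2, 1), g), 0)
  # random graphs: trace form vs explicit edge sum
  for (seed in 1:12) {
    case <- random_graph_case(seed, max_states = 5)
    set.seed(seed + 100)
    H <- matrix(rnorm(nrow(case$graph$nodes) * 3), ncol = 3)
    tr_form <- laplacian_smoothness(H, case$graph)
    und <- cardiograph:::undirected_support(case$graph)
    edge_sum <- 0
    for (k in seq_len(nrow(und))) {
      edge_sum <- edge_sum + sum((H[und$u[k], ] - H[und$v[k], ])^2)
    }
    expect_equal(tr_form, edge_sum, tolerance = 1e-9)
  }
})

test_that("total objective is the weighted sum over all named components", {
  comps <- stats::setNames(rep(0, length(loss_component_names())),
                           loss_component_names())
  comps["prediction"] <- 2
  w <- default_loss_weights()
  b <- total_objective(comps, w)
  expect_equal(b$total, 2)
  # doubling weights doubles the total
  comps["align"] <- 3; comps["arc"] <- 1
  b1 <- total_objective(comps, w)
  b2 <- total_objective(comps, w * 2)
  expect_equal(b2$total, 2 * b1$total)
  # hand dot product
  expect_equal(b1$total, sum(w[names(comps)] * comps))
  expect_equal(b1$total, sum(b1$weights * b1$components), tolerance = 1e-9)
  expect_error(total_objective(comps[-1], w), "missing components")
  wneg <- w; wneg["arc"] <- -1
  expect_error(total_objective(comps, wneg), "nonnegative")
})

test_that("quadratic losses are 2-homogeneous with the stated zeros", {
  set.seed(13)
  for (i in 1:10) {
    s <- matrix(rnorm(8), 4, 2)
    t_ <- matrix(rnorm(8), 4, 2)
    expect_equal(alignment_loss(2 * s, 2 * t_) -
                   4 * alignment_loss(s, t_), 0, tolerance = 1e-9)
    expect_gte(alignment_loss(s, t_), 0)
    expect_gte(arc_length_loss(s, 0:3), 0)
    expect_equal(arc_length_loss(2 * s, 0:3), 4 * arc_length_loss(s, 0:3),
                 tolerance = 1e-9)
  }
})
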