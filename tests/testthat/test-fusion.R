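test_that("attention pooling is a convex combination", {
  p <- toy_params(D = 2)
  h <- matrix(c(1, 0, 0, 1, 2, 2), 3, 2, byrow = TRUE)
  pool <- attention_pool(h, p)
  expect_equal(sum(pool$weights), 1, tolerance = 1e-12)
  expect_true(all(pool$weights > 0))
  # convex hull: pooled vector is the weighted mean
  expect_equal(pool$H_p, as.numeric(crossprod(h, pool$weights)))
  # single step pools to itself with weight one
  p1 <- attention_pool(h[1, , drop = FALSE], p)
  expect_equal(p1$H_p, h[1, ])
  expect_equal(p1$weights, 1)
  # q = 0 gives uniform weights and the sequence mean
  pz <- p; pz$theta$q <- matrix(0, 2, 1)
  pu <- attention_pool(h, pz)
  expect_equal(pu$weights, rep(1 / 3, 3))
  expect_equal(pu$H_p, colMeans(h))
  expect_error(attention_pool(matrix(0, 0, 2), p), "empty")
})

test_that("softmax of scores (0, ln 3) weights the steps 1:3", {
  # realized with W_q near-identity on D=1 and q = 1: score = tanh(h)
  e <- exp(c(0, log(3)))
  expect_equal(e / sum(e), c(0.25, 0.75))
})

test_that("zero-weight GRUs produce zero context", {
  p <- toy_params(D = 3)
  for (nm in names(p$theta$gru_f)) p$theta$gru_f[[nm]] <- p$theta$gru_f[[nm]] * 0
  for (nm in names(p$theta$gru_b)) p$theta$gru_b[[nm]] <- p$theta$gru_b[[nm]] * 0
  h <- matrix(rnorm(12), 4, 3)
  ctx <- bidirectional_context(h, p)
  expect_equal(ctx$r, matrix(0, 4, 3))
  expect_equal(ctx$b, matrix(0, 4, 3))
})

test_that("backward context equals forward context on the reversed sequence", {
  p <- toy_params(D = 3)
  p$theta$gru_b <- p$theta$gru_f
  set.seed(4)
  h <- matrix(rnorm(15), 5, 3)
  ctx <- bidirectional_context(h, p)
  ctx_rev <- bidirectional_context(h[5:1, , drop = FALSE], p)
  expect_equal(ctx$b, ctx_rev$r[5:1, , drop = FALSE], tolerance = 1e-12)
  # a length-1 sequence depends on that input only
  c1 <- bidirectional_context(h[2, , drop = FALSE], p)
  c2 <- bidirectional_context(rbind(h[2, ]), p)
  expect_equal(c1$r, c2$r)
})

test_that("bi-temporal fusion is the stated affine map", {
  p <- toy_params(D = 2)
  r <- c(1, 0); b <- c(0, 1)
  # W_f = 0 returns the bias
  p0 <- p; p0$theta$W_f <- matrix(0, 4, 2); p0$theta$b_f <- matrix(c(5, 6), 1, 2)
  expect_equal(fuse_bitemporal(r, b, p0), c(5, 6))
  # projection onto the forward context
  pp <- p; pp$theta$W_f <- rbind(diag(2), matrix(0, 2, 2))
  pp$theta$b_f <- matrix(0, 1, 2)
  expect_equal(fuse_bitemporal(r, b, pp), r)
  # hand-set 4x2 map matches plain matrix arithmetic
  W <- matrix(1:8 / 10, 4, 2)
  ph <- p; ph$theta$W_f <- W; ph$theta$b_f <- matrix(c(0.5, -0.5), 1, 2)
  expect_equal(fuse_bitemporal(r, b, ph),
               as.numeric(c(r, b) %*% W) + c(0.5, -0.5))
})

test_that("final state addition and latent distance behave as stated", {
  expect_equal(final_state(c(1, 2), c(3, 4)), c(4, 6))
  expect_equal(final_state(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(final_state(c(1, -2), c(-1, 2)), c(0, 0))
  expect_equal(latent_distance(c(1, 1), c(1, 1)), 0)
  expect_equal(latent_distance(c(3, 4), c(0, 0)), 5)
  set.seed(8)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(latent_distance(a, b), sqrt(sum((a - b)^2)))
  # triangle inequality on random triples
  for (i in 1:25) {
    x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
    expect_lte(latent_distance(x, z),
               latent_distance(x, y) + latent_distance(y, z) + 1e-12)
  }
})

test_that("observed change telescopes on linear ramps", {
  # scalar channel 0 -> 2 linearly: path length 2 for any sampling
  ts <- c(0, 0.3, 1.1, 2, 3)
  x <- matrix(2 * ts / 3, ncol = 1)
  traj <- patient_trajectory("ramp", ts, x)
  expect_equal(observed_change(traj, 0, 3), 2, tolerance = 1e-12)
  # refinement invariance on collinear samples
  ts2 <- sort(c(ts, 0.7, 1.7, 2.4))
  traj2 <- patient_trajectory("ramp2", ts2, matrix(2 * ts2 / 3, ncol = 1))
  expect_equal(observed_change(traj2, 0, 3), observed_change(traj, 0, 3),
               tolerance = 1e-12)
  # constant states travel no distance
  trajc <- toy_trajectory(ts = 0:3, d = 2, states = matrix(1, 4, 2))
  expect_equal(observed_change(trajc, 0, 3), 0)
  expect_error(observed_change(traj, 2, 2), "t1")
})

test_that("geometry penalty hinges at the tolerance", {
  ts <- 0:2
  traj <- patient_trajectory("g", ts, matrix(0, 3, 2))  # Delta_obs = 0
  p <- toy_params(D = 2, epsilon_geom = 0.5)
  # d_lat = Delta_obs everywhere: zero penalty
  s0 <- matrix(0, 3, 2)
  expect_equal(geometry_penalty(s0, traj, p, cbind(1, 2)), 0)
  # |d - Delta| = eps exactly: still zero (boundary inside tolerance)
  s_eps <- rbind(c(0, 0), c(0.5, 0), c(0.5, 0))
  expect_equal(geometry_penalty(s_eps, traj, p, cbind(1, 2)), 0)
  # single pair with d = 2, Delta = 0.5, eps = 0.5: (1.0)^2
  trajd <- patient_trajectory("g2", ts, matrix(c(0, 0.5, 0.5), ncol = 1))
  pd <- toy_params(d = 1, D = 2, epsilon_geom = 0.5)
  s2 <- rbind(c(0, 0), c(2, 0), c(2, 0))
  expect_equal(geometry_penalty(s2, trajd, pd, cbind(1, 2)), 1, tolerance = 1e-12)
  # non-increasing in eps
  vals <- vapply(c(0, 0.25, 0.5, 1, 2), function(eps) {
    pe <- toy_params(d = 1, D = 2, epsilon_geom = eps)
    geometry_penalty(s2, trajd, pe, cbind(1, 2))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("full fusion pass matches a straight-line oracle", {
  p <- toy_params(D = 3)
  set.seed(11)
  h <- matrix(rnorm(12), 4, 3)
  fu <- fuse_trajectory(h, p, timestamps = 0:3)
  th <- p$theta
  # oracle: direct loops over the definitions, no shared code
  sc <- as.numeric(tanh(h %*% th$W_q) %*% th$q)
  al <- exp(sc - max(sc)); al <- al / sum(al)
  Hp <- colSums(h * al)
  gru_ref <- function(X, pp) {
    hh <- rep(0, 3); out <- matrix(0, nrow(X), 3)
    for (t in seq_len(nrow(X))) {
      z <- 1 / (1 + exp(-(X[t, ] %*% pp$Wz + hh %*% pp$Uz + pp$bz)))
      r <- 1 / (1 + exp(-(X[t, ] %*% pp$Wr + hh %*% pp$Ur + pp$br)))
      n <- tanh(X[t, ] %*% pp$Wn + (r * hh) %*% pp$Un + pp$bn)
      hh <- as.numeric((1 - z) * n + z * hh)
      out[t, ] <- hh
    }
    out
  }
  r_ref <- gru_ref(h, th$gru_f)
  b_ref <- gru_ref(h[4:1, , drop = FALSE], th$gru_b)[4:1, , drop = FALSE]
  c_ref <- sweep(cbind(r_ref, b_ref) %*% th$W_f, 2, as.numeric(th$b_f), "+")
  expect_equal(fu$pool_weights, al, tolerance = 1e-6)
  expect_equal(fu$H_p, Hp, tolerance = 1e-6)
  expect_equal(fu$r, r_ref, tolerance = 1e-6)
  expect_equal(fu$b, b_ref, tolerance = 1e-6)
  expect_equal(fu$s, h + c_ref, tolerance = 1e-6)
})
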