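# Trajectory-level attention pooling, forward/backward GRU context,
# bi-temporal fusion, and the latent-geometry constraint.

#' Temporal attention pooling
#'
#' `alpha_t = softmax_t( q' tanh(W_q h~_t) )`, `H_p = sum_t alpha_t h~_t`.
#' The pooled vector lies in the convex hull of the inputs.
#'
#' @param h_tilde `T x D` matrix of fused per-time-step embeddings.
#' @param params A `cgse_params`.
#' @return List with `H_p` (length-`D` vector) and `weights` (length `T`,
#'   positive, summing to one).
#' @export
attention_pool <- function(h_tilde, params) {
  h_tilde <- as_mat(h_tilde)
  if (!nrow(h_tilde)) stop("attention_pool: empty sequence")
  th <- params$theta
  s <- as.numeric(tanh(h_tilde %*% th$W_q) %*% th$q)
  e <- exp(s - max(s))
  w <- e / sum(e)
  list(H_p = as.numeric(crossprod(h_tilde, w)), weights = w)
}

gru_forward_numeric <- function(X, p) {
  Tn <- nrow(X); D <- ncol(p$Wz)
  H <- matrix(0, Tn, D)
  h <- numeric(D)
  for (t in seq_len(Tn)) {
    z <- 1 / (1 + exp(-(X[t, ] %*% p$Wz + h %*% p$Uz + as.numeric(p$bz))))
    r <- 1 / (1 + exp(-(X[t, ] %*% p$Wr + h %*% p$Ur + as.numeric(p$br))))
    n <- tanh(X[t, ] %*% p$Wn + (r * h) %*% p$Un + as.numeric(p$bn))
    h <- as.numeric((1 - z) * n + z * h)
    H[t, ] <- h
  }
  H
}

#' Forward and backward recurrent context
#'
#' Scans the fused sequence with a forward GRU (increasing time, zero initial
#' state) and a backward GRU (decreasing time), giving per-step context
#' vectors `r_t` and `b_t`.
#'
#' @param h_tilde `T x D` matrix.
#' @param params A `cgse_params`.
#' @return List with matrices `r` and `b` (`T x D`).
#' @export
bidirectional_context <- function(h_tilde, params) {
  h_tilde <- as_mat(h_tilde)
  if (!nrow(h_tilde)) stop("bidirectional_context: empty sequence")
  r <- gru_forward_numeric(h_tilde, params$theta$gru_f)
  rev_idx <- rev(seq_len(nrow(h_tilde)))
  b <- gru_forward_numeric(h_tilde[rev_idx, , drop = FALSE], params$theta$gru_b)
  list(r = r, b = b[rev_idx, , drop = FALSE])
}

#' Bi-temporal fusion of forward and backward context
#'
#' `c_t = W_f [r_t || b_t] + b_f` (row convention: `c = [r || b] W_f + b_f`).
#'
#' @param r_t,b_t Context vectors or `T x D` matrices.
#' @param params A `cgse_params`.
#' @return Fused context with the same number of rows.
#' @export
fuse_bitemporal <- function(r_t, b_t, params) {
  rb <- cbind(as_mat(r_t), as_mat(b_t))
  out <- sweep(rb %*% params$theta$W_f, 2L, as.numeric(params$theta$b_f), "+")
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Final per-step state representation
#'
#' `s_t = h~_t + c_t`.
#'
#' @param h_tilde_t Fused embedding(s). @param c_t Bi-temporal context.
#' @return Same shape as the inputs.
#' @export
final_state <- function(h_tilde_t, c_t) {
  unname(h_tilde_t + c_t)
}

#' Euclidean latent distance
#' @param s_a,s_b Latent vectors.
#' @return Nonnegative scalar.
#' @export
latent_distance <- function(s_a, s_b) {
  sqrt(sum((as.numeric(s_a) - as.numeric(s_b))^2))
}

#' Run pooling, recurrence and fusion over a fused sequence
#'
#' @param h_tilde `T x D` matrix of fused embeddings.
#' @param params A `cgse_params`.
#' @param timestamps Optional state timestamps carried along.
#' @return A `fused_trajectory`: `H_p`, `pool_weights`, `r`, `b`, `c`, `s`,
#'   `timestamps`.
#' @export
fuse_trajectory <- function(h_tilde, params, timestamps = NULL) {
  pool <- attention_pool(h_tilde, params)
  ctx <- bidirectional_context(h_tilde, params)
  cmat <- fuse_bitemporal(ctx$r, ctx$b, params)
  cmat <- as_mat(cmat)
  structure(list(H_p = pool$H_p, pool_weights = pool$weights,
                 r = ctx$r, b = ctx$b, c = cmat,
                 s = final_state(as_mat(h_tilde), cmat),
                 timestamps = timestamps),
            class = "fused_trajectory")
}

# pair selection for the geometry penalty: all consecutive index pairs plus
# n_rand seeded non-adjacent pairs
geometry_pairs <- function(n_steps, n_rand = 4L, seed = 1L) {
  pairs <- if (n_steps >= 2L) cbind(seq_len(n_steps - 1L), 2:n_steps) else
    matrix(integer(0), 0L, 2L)
  if (n_rand > 0L && n_steps >= 4L) {
    rng <- local_rng(seed)
    extra <- matrix(0L, n_rand, 2L)
    for (k in seq_len(n_rand)) {
      i <- rng$int(n_steps - 2L)
      j <- i + 1L + rng$int(n_steps - i - 1L)
      extra[k, ] <- c(i, j)
    }
    pairs <- rbind(pairs, extra)
  }
  pairs
}

#' Latent-geometry penalty
#'
#' Soft relaxation of the constraint `|d_lat(t1,t2) - Delta_obs(t1,t2)| <= eps`
#' as a squared hinge summed over index pairs:
#' `sum max(0, |d_lat - Delta_obs| - eps)^2`. Zero exactly when every pair
#' satisfies the constraint.
#'
#' @param s_seq `T x D` matrix of final states.
#' @param traj The `patient_trajectory` (for the observed path lengths).
#' @param params A `cgse_params` (uses `dims$epsilon_geom`).
#' @param pairs Two-column integer matrix of time-step index pairs
#'   (`i < j`); defaults to consecutive pairs plus 4 seeded random pairs.
#' @return Nonnegative scalar.
#' @export
geometry_penalty <- function(s_seq, traj, params, pairs = NULL) {
  s_seq <- as_mat(s_seq)
  if (is.null(pairs)) pairs <- geometry_pairs(nrow(s_seq))
  if (!nrow(pairs)) return(0)
  eps <- params$dims$epsilon_geom
  total <- 0
  ts <- traj$timestamps
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dl <- latent_distance(s_seq[i, ], s_seq[j, ])
    dobs <- observed_change(traj, ts[i], ts[j])
    total <- total + max(0, abs(dl - dobs) - eps)^2
  }
  total
}

# tiny deterministic RNG (xorshift-free LCG) so helper sampling never touches
# the global .Random.seed
local_rng <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483647L) + 1L)
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(unif = nxt, int = function(n) as.integer(floor(nxt() * n)) + 1L)
}
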