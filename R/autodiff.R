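# Minimal reverse-mode autodiff over dense matrices.
#
# Every tracked value is a matrix node on a tape; ops append nodes in
# topological order, each carrying a backward closure that maps the gradient
# of the output to gradients of its parents. backward() sweeps the tape in
# reverse, accumulating by parent id. Scalars are 1x1 matrices.
#
# The op set is intentionally small: what the encoder, fusion and loss layers
# need, plus fused segment-softmax / segment-sum (for per-node attention over
# edge lists) and a fused GRU scan with a hand-derived BPTT backward. All
# backward passes are verified against central differences in the test suite.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()     # forward values
  tp$parents <- list()  # integer vectors of parent ids
  tp$backs <- list()    # backward closures: function(grad) -> list of parent grads
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, parents = integer(0), back = NULL) {
  # force arguments before claiming an id: nested op calls inside `value` or
  # `parents` must append their nodes first, keeping the tape topological
  force(value); force(parents); force(back)
  i <- tape$n + 1L
  tape$n <- i
  tape$vals[[i]] <- value
  tape$parents[[i]] <- parents
  tape$backs[[i]] <- back
  list(tape = tape, id = i)
}

tp_value <- function(x) x$tape$vals[[x$id]]

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1L)
}

# leaf (constant or parameter) node
tp_leaf <- function(tape, value) tp_node(tape, as_mat(value))

tp_add <- function(a, b) {
  va <- tp_value(a); vb <- tp_value(b)
  tp_node(a$tape, va + vb, c(a$id, b$id), function(g) list(g, g))
}

tp_sub <- function(a, b) {
  tp_node(a$tape, tp_value(a) - tp_value(b), c(a$id, b$id),
          function(g) list(g, -g))
}

tp_mul <- function(a, b) {
  va <- tp_value(a); vb <- tp_value(b)
  tp_node(a$tape, va * vb, c(a$id, b$id),
          function(g) list(g * vb, g * va))
}

# multiply a matrix node by a 1x1 scalar node
tp_scale_node <- function(a, s) {
  va <- tp_value(a); vs <- as.numeric(tp_value(s))
  tp_node(a$tape, va * vs, c(a$id, s$id),
          function(g) list(g * vs, matrix(sum(g * va), 1L, 1L)))
}

# multiply by an R constant
tp_scale <- function(a, k) {
  tp_node(a$tape, tp_value(a) * k, a$id, function(g) list(g * k))
}

tp_add_const <- function(a, k) {
  tp_node(a$tape, tp_value(a) + k, a$id, function(g) list(g))
}

tp_matmul <- function(a, b) {
  va <- tp_value(a); vb <- tp_value(b)
  tp_node(a$tape, va %*% vb, c(a$id, b$id),
          function(g) list(g %*% t(vb), t(va) %*% g))
}

# add a 1 x m bias row to every row of an n x m matrix
tp_add_rowvec <- function(a, b) {
  va <- tp_value(a); vb <- tp_value(b)
  tp_node(a$tape, sweep(va, 2L, as.numeric(vb), "+"), c(a$id, b$id),
          function(g) list(g, matrix(colSums(g), 1L)))
}

tp_tanh <- function(a) {
  y <- tanh(tp_value(a))
  tp_node(a$tape, y, a$id, function(g) list(g * (1 - y * y)))
}

tp_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-tp_value(a)))
  tp_node(a$tape, y, a$id, function(g) list(g * y * (1 - y)))
}

tp_exp <- function(a) {
  y <- exp(tp_value(a))
  tp_node(a$tape, y, a$id, function(g) list(g * y))
}

tp_abs <- function(a) {
  v <- tp_value(a)
  tp_node(a$tape, abs(v), a$id, function(g) list(g * sign(v)))
}

tp_relu <- function(a) {
  v <- tp_value(a)
  tp_node(a$tape, pmax(v, 0) * (abs(v) > 0), a$id, function(g) list(g * (v > 0)))
}

tp_sqrt <- function(a) {
  y <- sqrt(tp_value(a))
  tp_node(a$tape, y, a$id, function(g) list(g * 0.5 / pmax(y, 1e-300)))
}

# elementwise reciprocal
tp_inv <- function(a) {
  v <- tp_value(a)
  tp_node(a$tape, 1 / v, a$id, function(g) list(-g / (v * v)))
}

tp_sum <- function(a) {
  v <- tp_value(a)
  tp_node(a$tape, matrix(sum(v), 1L, 1L), a$id,
          function(g) list(matrix(as.numeric(g), nrow(v), ncol(v))))
}

tp_sumsq <- function(a) {
  v <- tp_value(a)
  tp_node(a$tape, matrix(sum(v * v), 1L, 1L), a$id,
          function(g) list(2 * as.numeric(g) * v))
}

# row-wise sums of squares: n x m -> n x 1
tp_rowsumsq <- function(a) {
  v <- tp_value(a)
  tp_node(a$tape, matrix(rowSums(v * v), ncol = 1L), a$id,
          function(g) list(2 * as.numeric(g) * v))
}

# scale each row of X (n x m) by the matching entry of a column node w (n x 1)
tp_colmul <- function(X, w) {
  vx <- tp_value(X); vw <- as.numeric(tp_value(w))
  tp_node(X$tape, vx * vw, c(X$id, w$id), function(g) {
    list(g * vw, matrix(rowSums(g * vx), ncol = 1L))
  })
}

# gather rows (duplicates allowed); backward scatter-adds
tp_rows <- function(a, idx) {
  v <- tp_value(a)
  idx <- as.integer(idx)
  tp_node(a$tape, v[idx, , drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(v), ncol(v))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

tp_cbind <- function(a, b) {
  va <- tp_value(a); vb <- tp_value(b)
  na <- ncol(va)
  tp_node(a$tape, cbind(va, vb), c(a$id, b$id), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, (na + 1L):ncol(g), drop = FALSE])
  })
}

tp_rbind <- function(a, b) {
  va <- tp_value(a); vb <- tp_value(b)
  na <- nrow(va)
  tp_node(a$tape, rbind(va, vb), c(a$id, b$id), function(g) {
    list(g[seq_len(na), , drop = FALSE],
         g[(na + 1L):nrow(g), , drop = FALSE])
  })
}

# softmax within groups over an n x 1 score column; groups in 1..ngroups,
# stabilised with a per-group max shift
tp_segment_softmax <- function(scores, groups) {
  s <- as.numeric(tp_value(scores))
  groups <- as.integer(groups)
  gmax <- tapply(s, groups, max)
  e <- exp(s - gmax[as.character(groups)])
  gsum <- tapply(e, groups, sum)
  w <- e / gsum[as.character(groups)]
  wv <- matrix(w, ncol = 1L)
  tp_node(scores$tape, wv, scores$id, function(g) {
    gv <- as.numeric(g)
    dot <- tapply(w * gv, groups, sum)
    list(matrix(w * (gv - dot[as.character(groups)]), ncol = 1L))
  })
}

# sum rows of X by group into an ngroups x m matrix (zero rows for absent ids)
tp_segment_sum <- function(X, groups, ngroups) {
  v <- tp_value(X)
  groups <- as.integer(groups)
  out <- matrix(0, ngroups, ncol(v))
  acc <- rowsum(v, group = groups)
  out[as.integer(rownames(acc)), ] <- acc
  tp_node(X$tape, out, X$id, function(g) list(g[groups, , drop = FALSE]))
}

# --- fused GRU scan ---------------------------------------------------------
#
# Row convention; X is T x Din, hidden size D. Update equations:
#   z_t = sigmoid(x_t Wz + h_{t-1} Uz + bz)
#   r_t = sigmoid(x_t Wr + h_{t-1} Ur + br)
#   n_t = tanh(x_t Wn + (r_t * h_{t-1}) Un + bn)
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1},    h_0 = 0
# Returns the T x D matrix of hidden states. Backward is hand-derived BPTT.
# Scan is always forward; callers reverse rows (tp_rows) for the backward GRU.
tp_gru <- function(X, p) {
  xv <- tp_value(X)
  Wz <- tp_value(p$Wz); Uz <- tp_value(p$Uz); bz <- as.numeric(tp_value(p$bz))
  Wr <- tp_value(p$Wr); Ur <- tp_value(p$Ur); br <- as.numeric(tp_value(p$br))
  Wn <- tp_value(p$Wn); Un <- tp_value(p$Un); bn <- as.numeric(tp_value(p$bn))
  Tn <- nrow(xv); D <- ncol(Wz)
  H <- matrix(0, Tn, D); Z <- matrix(0, Tn, D); R <- matrix(0, Tn, D)
  N <- matrix(0, Tn, D)
  Xz <- xv %*% Wz; Xr <- xv %*% Wr; Xn <- xv %*% Wn
  h <- numeric(D)
  for (t in seq_len(Tn)) {
    z <- 1 / (1 + exp(-(Xz[t, ] + h %*% Uz + bz)))
    r <- 1 / (1 + exp(-(Xr[t, ] + h %*% Ur + br)))
    n <- tanh(Xn[t, ] + (r * h) %*% Un + bn)
    h <- (1 - z) * n + z * h
    Z[t, ] <- z; R[t, ] <- r; N[t, ] <- n; H[t, ] <- h
  }
  parents <- c(X$id, p$Wz$id, p$Uz$id, p$bz$id, p$Wr$id, p$Ur$id, p$br$id,
               p$Wn$id, p$Un$id, p$bn$id)
  back <- function(g) {
    gX <- matrix(0, Tn, ncol(xv))
    gWz <- matrix(0, nrow(Wz), D); gUz <- matrix(0, D, D); gbz <- numeric(D)
    gWr <- matrix(0, nrow(Wr), D); gUr <- matrix(0, D, D); gbr <- numeric(D)
    gWn <- matrix(0, nrow(Wn), D); gUn <- matrix(0, D, D); gbn <- numeric(D)
    gh <- numeric(D)
    for (t in rev(seq_len(Tn))) {
      gh <- gh + g[t, ]
      hprev <- if (t > 1L) H[t - 1L, ] else numeric(D)
      z <- Z[t, ]; r <- R[t, ]; n <- N[t, ]
      gz <- gh * (hprev - n)
      gn <- gh * (1 - z)
      ghp <- gh * z
      gan <- gn * (1 - n * n)
      grh <- gan %*% t(Un)              # grad wrt (r * hprev)
      gr <- as.numeric(grh) * hprev
      ghp <- ghp + as.numeric(grh) * r
      gaz <- gz * z * (1 - z)
      gar <- gr * r * (1 - r)
      ghp <- ghp + as.numeric(gaz %*% t(Uz)) + as.numeric(gar %*% t(Ur))
      x <- xv[t, ]
      gWz <- gWz + outer(x, gaz); gUz <- gUz + outer(hprev, gaz); gbz <- gbz + gaz
      gWr <- gWr + outer(x, gar); gUr <- gUr + outer(hprev, gar); gbr <- gbr + gar
      gWn <- gWn + outer(x, gan); gUn <- gUn + outer(r * hprev, gan); gbn <- gbn + gan
      gX[t, ] <- gaz %*% t(Wz) + gar %*% t(Wr) + gan %*% t(Wn)
      gh <- ghp
    }
    list(gX, gWz, gUz, matrix(gbz, 1L), gWr, gUr, matrix(gbr, 1L),
         gWn, gUn, matrix(gbn, 1L))
  }
  tp_node(X$tape, H, parents, back)
}

# one GRU step from an explicit previous hidden state node (1 x D);
# used for counterfactual recomputes. Built from generic ops.
tp_gru_step <- function(x, hprev, p) {
  z <- tp_sigmoid(tp_add(tp_add(tp_matmul(x, p$Wz), tp_matmul(hprev, p$Uz)), p$bz))
  r <- tp_sigmoid(tp_add(tp_add(tp_matmul(x, p$Wr), tp_matmul(hprev, p$Ur)), p$br))
  n <- tp_tanh(tp_add(tp_add(tp_matmul(x, p$Wn), tp_matmul(tp_mul(r, hprev), p$Un)), p$bn))
  one_minus_z <- tp_add_const(tp_scale(z, -1), 1)
  tp_add(tp_mul(one_minus_z, n), tp_mul(z, hprev))
}

# reverse sweep from a scalar root; returns list of gradients indexed by node id
tp_backward <- function(root) {
  tape <- root$tape
  grads <- vector("list", tape$n)
  rv <- tape$vals[[root$id]]
  grads[[root$id]] <- matrix(1, nrow(rv), ncol(rv))
  for (i in seq(root$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    pa <- tape$parents[[i]]
    if (!length(pa)) next
    pg <- tape$backs[[i]](g)
    for (k in seq_along(pa)) {
      j <- pa[k]
      grads[[j]] <- if (is.null(grads[[j]])) pg[[k]] else grads[[j]] + pg[[k]]
    }
  }
  grads
}
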