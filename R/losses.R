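# DCTA loss terms and statistics: cross-patient alignment, clinical priors,
# arc-length smoothness, stage statistics and separation, soft temporal
# alignment, intervention orientation, event anchors, anchor separation, and
# graph-Laplacian smoothness.

#' Names of the loss-bundle components
#' @return Character vector of component names.
#' @export
loss_component_names <- function() {
  c("align", "prior", "arc", "stage_sep", "soft_align", "interv_orient",
    "event_anchor", "anchor_sep", "laplacian", "geometry", "prediction")
}

#' Default loss weights
#'
#' Prediction loss weighted 1, every structural/regularization term 0.1.
#' @return Named numeric vector over [loss_component_names()].
#' @export
default_loss_weights <- function() {
  w <- stats::setNames(rep(0.1, length(loss_component_names())), loss_component_names())
  w["prediction"] <- 1
  w
}

#' Resample a latent sequence onto a normalized-time grid
#'
#' Linearly interpolates each latent channel of `s` (sampled at `timestamps`)
#' onto `n_grid` equispaced points of normalized time
#' `tau = (t - t_min) / (t_max - t_min)`, so trajectories with different
#' sampling become pointwise comparable.
#'
#' @param s `T x D` matrix. @param timestamps Length-`T` increasing times.
#' @param n_grid Grid size (default 32).
#' @return `n_grid x D` matrix.
#' @export
resample_normalized <- function(s, timestamps, n_grid = 32L) {
  s <- as_mat(s)
  if (nrow(s) == 1L) return(s[rep(1L, n_grid), , drop = FALSE])
  tau <- (timestamps - timestamps[1]) / (timestamps[length(timestamps)] - timestamps[1])
  grid <- seq(0, 1, length.out = n_grid)
  apply(s, 2L, function(col) stats::approx(tau, col, xout = grid)$y)
}

#' Cross-patient alignment loss
#'
#' `sum_t || s_t^(p) - s_t^(q) ||^2` over sequences already resampled to a
#' common grid (see [resample_normalized()]). Symmetric in its arguments.
#'
#' @param s_p,s_q Equal-shape latent matrices.
#' @return Nonnegative scalar.
#' @export
alignment_loss <- function(s_p, s_q) {
  s_p <- as_mat(s_p); s_q <- as_mat(s_q)
  if (nrow(s_p) != nrow(s_q) || ncol(s_p) != ncol(s_q))
    stop("alignment_loss: sequences must have equal shape after resampling")
  sum((s_p - s_q)^2)
}

#' Clinical prior projection
#'
#' An affine map `f(s) = s W + b` from the latent space into a clinical
#' feature space, paired with per-time-step prior targets `p_t`.
#'
#' @param W `D x d_prior` matrix. @param b Length-`d_prior` bias.
#' @param p `T x d_prior` matrix of prior targets.
#' @return A `prior_projection`.
#' @export
prior_projection <- function(W, b, p) {
  p <- as_mat(p)
  if (ncol(W) != ncol(p)) stop("prior_projection: f output dimension must equal prior dimension")
  structure(list(W = W, b = as.numeric(b), p = p), class = "prior_projection")
}

#' Clinical-prior loss
#'
#' `sum_t || f(s_t) - p_t ||^2`, penalizing latent states whose clinical
#' projection drifts from known priors.
#'
#' @param s_seq `T x D` latent matrix. @param proj A [prior_projection()].
#' @return Nonnegative scalar.
#' @export
prior_loss <- function(s_seq, proj) {
  s_seq <- as_mat(s_seq)
  f <- sweep(s_seq %*% proj$W, 2L, proj$b, "+")
  sum((f - proj$p)^2)
}

#' Arc-length (squared-speed) regularizer
#'
#' Discretizes `int_0^1 ||d gamma/d tau||^2 d tau` over the latent path on
#' normalized time as `sum_i ||s_{i+1}-s_i||^2 / dtau_i`. Invariant to
#' collinear refinement of a straight-line path.
#'
#' @param s_seq `T x D` latent matrix.
#' @param timestamps Length-`T` increasing times.
#' @return Nonnegative scalar; 0 when fewer than 2 steps.
#' @export
arc_length_loss <- function(s_seq, timestamps) {
  s_seq <- as_mat(s_seq)
  n <- nrow(s_seq)
  if (n < 2L) return(0)
  tau <- (timestamps - timestamps[1]) / (timestamps[n] - timestamps[1])
  d <- diff(s_seq)
  sum(rowSums(d * d) / diff(tau))
}

#' Per-stage centroids and covariances
#'
#' Splits the time index into `K` contiguous equal-size segments (remainder to
#' the last) and computes the centroid and population covariance
#' (`1/|I_k|` normalization, outer-product form) of each.
#'
#' @param s_seq `T x D` latent matrix with `T >= K`.
#' @param K Number of segments (`>= 1`).
#' @return A `stage_segmentation`: `K`, `segments` (list of index vectors),
#'   `centroids` (`K x D`), `covariances` (list of `D x D` matrices).
#' @export
stage_statistics <- function(s_seq, K) {
  s_seq <- as_mat(s_seq)
  n <- nrow(s_seq)
  if (K <= 0L) stop("stage_statistics: K must be positive")
  if (n < K) stop("stage_statistics: sequence shorter than K")
  size <- n %/% K
  segments <- lapply(seq_len(K), function(k) {
    from <- (k - 1L) * size + 1L
    to <- if (k == K) n else k * size
    from:to
  })
  centroids <- matrix(0, K, ncol(s_seq))
  covariances <- vector("list", K)
  for (k in seq_len(K)) {
    X <- s_seq[segments[[k]], , drop = FALSE]
    mu <- colMeans(X)
    centroids[k, ] <- mu
    Xc <- sweep(X, 2L, mu)
    covariances[[k]] <- crossprod(Xc) / nrow(X)
  }
  structure(list(K = K, segments = segments, centroids = centroids,
                 covariances = covariances), class = "stage_segmentation")
}

#' Stage-separation loss
#'
#' `sum_{i<j} exp(-||mu_i - mu_j||^2)`: strictly positive, decreasing as any
#' pair of stage centroids moves apart.
#'
#' @param seg A [stage_statistics()] result (or list with `centroids`).
#' @return Positive scalar.
#' @export
stage_separation_loss <- function(seg) {
  mu <- as_mat(seg$centroids)
  K <- nrow(mu)
  total <- 0
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    total <- total + exp(-sum((mu[i, ] - mu[j, ])^2))
  total
}

#' Monotone nearest-index temporal alignment
#'
#' Maps each time of patient `p` to the index of the nearest normalized time
#' of patient `q`; monotone non-decreasing by construction.
#'
#' @param ts_p,ts_q Increasing timestamp vectors.
#' @return Integer vector of length `length(ts_p)` with values in
#'   `1..length(ts_q)`.
#' @export
nearest_index_alignment <- function(ts_p, ts_q) {
  norm01 <- function(x) if (length(x) == 1L) 0 else (x - x[1]) / (x[length(x)] - x[1])
  tp <- norm01(ts_p); tq <- norm01(ts_q)
  vapply(tp, function(t) which.min(abs(tq - t)), integer(1))
}

#' Soft temporal alignment loss
#'
#' `sum_{t_p} || s^(p)_{t_p} - s^(q)_{pi(t_p)} ||^2` for a monotone index map
#' `pi` (see [nearest_index_alignment()]).
#'
#' @param s_p,s_q Latent matrices. @param pi Integer map from rows of `s_p`
#'   to rows of `s_q`.
#' @return Nonnegative scalar.
#' @export
soft_alignment_loss <- function(s_p, s_q, pi) {
  s_p <- as_mat(s_p); s_q <- as_mat(s_q)
  pi <- as.integer(pi)
  if (length(pi) != nrow(s_p) || any(pi < 1L) || any(pi > nrow(s_q)))
    stop("soft_alignment_loss: pi must map every row of s_p into s_q")
  sum((s_p - s_q[pi, , drop = FALSE])^2)
}

#' Counterfactual intervention effect
#'
#' `delta = s_hat(t') - s(t')`: the latent displacement attributed to an
#' intervention.
#'
#' @param s_hat_tprime Counterfactual state. @param s_tprime Factual state.
#' @return Numeric vector.
#' @export
intervention_effect <- function(s_hat_tprime, s_tprime) {
  as.numeric(s_hat_tprime) - as.numeric(s_tprime)
}

#' Registry of parametric cardiovascular response fields
#'
#' Each registered field is an exponential-response map
#' `G(u, dt) = A * ||u||_2 * exp(-dt / tau)` with a fixed latent direction `A`
#' and time constant `tau` (seconds), a parametric stand-in for expected
#' pharmacodynamic responses (e.g. the heart-rate-lowering direction of a
#' beta-blocker). All fields vanish as `dt -> Inf`.
#'
#' @param fields Named list of `list(direction=, tau=)` entries.
#' @return A `vector_field_registry`.
#' @export
vector_field_registry <- function(fields = list()) {
  structure(list(fields = fields), class = "vector_field_registry")
}

#' Register a response field
#' @param registry A [vector_field_registry()].
#' @param name Field name. @param direction Latent direction (length `D`).
#' @param tau Positive time constant (s).
#' @return The updated registry.
#' @export
register_field <- function(registry, name, direction, tau) {
  stopifnot(tau > 0)
  registry$fields[[name]] <- list(direction = as.numeric(direction), tau = tau)
  registry
}

#' Evaluate a registered response field
#' @param registry A [vector_field_registry()]. @param name Field name.
#' @param u Action feature vector. @param dt Elapsed seconds.
#' @return Latent response vector.
#' @export
eval_field <- function(registry, name, u, dt) {
  f <- registry$fields[[name]]
  if (is.null(f)) stop("eval_field: unknown field '", name, "'")
  f$direction * sqrt(sum(as.numeric(u)^2)) * exp(-dt / f$tau)
}

#' Intervention-orientation loss
#'
#' `|| delta - G(u, dt) ||^2`: aligns the simulated intervention effect with
#' the domain response field.
#'
#' @param delta Latent effect vector (see [intervention_effect()]).
#' @param u Action features. @param dt Elapsed seconds.
#' @param registry A [vector_field_registry()]. @param field Field name.
#' @return Nonnegative scalar.
#' @export
intervention_orientation_loss <- function(delta, u, dt, registry, field) {
  g <- eval_field(registry, field, u, dt)
  sum((as.numeric(delta) - g)^2)
}

#' Event anchor set
#'
#' One latent attractor center per event label, plus the small positive
#' constant used by the separation regularizer.
#'
#' @param centers `n_labels x D` matrix. @param labels Character labels.
#' @param eps_anchor Positive constant.
#' @return An `event_anchors`.
#' @export
event_anchors <- function(centers, labels, eps_anchor = 0.01) {
  centers <- as_mat(centers)
  if (eps_anchor <= 0) stop("event_anchors: eps_anchor must be > 0")
  if (nrow(centers) != length(labels)) stop("event_anchors: one center per label")
  structure(list(centers = centers, labels = as.character(labels),
                 eps_anchor = eps_anchor), class = "event_anchors")
}

#' Event-anchor loss
#'
#' `|| s_{tau_k} - c_k ||^2` for the anchor of the event's label; an unknown
#' label is an error, never a silent zero.
#'
#' @param s_at_event Latent state at the event time.
#' @param anchors An [event_anchors()]. @param label Event label.
#' @return Nonnegative scalar.
#' @export
event_anchor_loss <- function(s_at_event, anchors, label) {
  k <- match(label, anchors$labels)
  if (is.na(k)) stop("event_anchor_loss: unknown event label '", label, "'")
  sum((as.numeric(s_at_event) - anchors$centers[k, ])^2)
}

#' Anchor-separation loss
#'
#' `sum_{i<j} 1 / (||c_i - c_j||^2 + eps)`: penalizes coincident attractor
#' centers, strictly decreasing as any pair moves apart.
#'
#' @param anchors An [event_anchors()].
#' @return Positive scalar (0 when fewer than two centers).
#' @export
anchor_separation_loss <- function(anchors) {
  C <- anchors$centers
  m <- nrow(C)
  total <- 0
  if (m >= 2L) for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    total <- total + 1 / (sum((C[i, ] - C[j, ])^2) + anchors$eps_anchor)
  total
}

#' Graph-Laplacian smoothness of node embeddings
#'
#' `Tr(H' L H)` with `L` the unnormalized Laplacian of the graph's undirected
#' unit-weight support; equals the sum over undirected edges of
#' `||h_u - h_v||^2`.
#'
#' @param H `n_nodes x D` embedding matrix (rows ordered by node id).
#' @param graph A `cardio_graph`.
#' @return Nonnegative scalar.
#' @export
laplacian_smoothness <- function(H, graph) {
  H <- as_mat(H)
  L <- graph_laplacian(graph)
  sum(diag(t(H) %*% L %*% H))
}

#' Assemble a loss bundle
#'
#' Collects the named loss components and nonnegative weights into a
#' `loss_bundle` with `total = sum(weight * value)`.
#'
#' @param components Named numeric vector covering [loss_component_names()].
#' @param weights Named nonnegative weights over the same names.
#' @return A `loss_bundle` with fields `components`, `weights`, `total`.
#' @export
total_objective <- function(components, weights = default_loss_weights()) {
  nms <- loss_component_names()
  missing_c <- setdiff(nms, names(components))
  if (length(missing_c))
    stop("total_objective: missing components: ", paste(missing_c, collapse = ", "))
  if (any(weights[nms] < 0, na.rm = TRUE) || any(is.na(weights[nms])))
    stop("total_objective: weights must be nonnegative and complete")
  components <- components[nms]
  weights <- weights[nms]
  structure(list(components = components, weights = weights,
                 total = sum(weights * components)), class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat("<loss_bundle total =", format(x$total, digits = 6), ">\n")
  print(round(x$components, 6))
  invisible(x)
}
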