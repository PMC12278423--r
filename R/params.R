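#' Model dimensions and hyperparameters
#'
#' Collects the architecture sizes and fixed hyperparameters shared by the
#' encoder, fusion and loss layers.
#'
#' @param d State dimension. @param d_e Event feature dimension. @param d_a
#'   Action feature dimension. @param D Embedding dimension. @param L Number
#'   of propagation layers. @param K Number of temporal stage segments.
#' @param lambda_attn Nonnegative temporal-attention decay.
#' @param lambda_sim Nonnegative simulation-operator decay (distinct from
#'   `lambda_attn`).
#' @param activation Nonlinearity for propagation: `"tanh"` (default),
#'   `"relu"`, `"sigmoid"` or `"identity"`.
#' @param clamp_attention If `TRUE`, clamps the similarity score inside the
#'   attention exponent to be nonnegative (off by default; the printed form
#'   multiplies decay and similarity, so a negative similarity would upweight
#'   distant neighbors).
#' @param epsilon_geom Tolerance of the latent-geometry constraint.
#' @param eps_anchor Small positive constant in the anchor-separation loss.
#' @param head Forecast head: `"residual"` (default; the readout predicts the
#'   state increment, `x_hat_{t+h} = x_t + readout(s_t)`, so an untrained
#'   zero readout reproduces the last-value baseline) or `"absolute"`
#'   (`x_hat_{t+h} = readout(s_t)`).
#' @return A named list of class `cgse_dims`.
#' @export
model_dims <- function(d, d_e = 3L, d_a = 2L, D = 16L, L = 2L, K = 4L,
                       lambda_attn = 0.5, lambda_sim = 0.5,
                       activation = "tanh", clamp_attention = FALSE,
                       epsilon_geom = 0.1, eps_anchor = 0.01,
                       head = "residual") {
  stopifnot(d >= 1, d_e >= 1, d_a >= 1, D >= 1, L >= 1, K >= 1,
            lambda_attn >= 0, lambda_sim >= 0, epsilon_geom >= 0,
            eps_anchor > 0)
  structure(list(d = as.integer(d), d_e = as.integer(d_e), d_a = as.integer(d_a),
                 D = as.integer(D), L = as.integer(L), K = as.integer(K),
                 lambda_attn = lambda_attn, lambda_sim = lambda_sim,
                 activation = match.arg(activation, c("tanh", "relu", "sigmoid", "identity")),
                 clamp_attention = isTRUE(clamp_attention),
                 epsilon_geom = epsilon_geom, eps_anchor = eps_anchor,
                 head = match.arg(head, c("residual", "absolute"))),
            class = "cgse_dims")
}

xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

mlp_init <- function(nin, D) {
  list(W1 = xavier(nin, D), b1 = matrix(0, 1L, D),
       W2 = xavier(D, D), b2 = matrix(0, 1L, D))
}

gru_init <- function(nin, D) {
  list(Wz = xavier(nin, D), Uz = xavier(D, D), bz = matrix(0, 1L, D),
       Wr = xavier(nin, D), Ur = xavier(D, D), br = matrix(0, 1L, D),
       Wn = xavier(nin, D), Un = xavier(D, D), bn = matrix(0, 1L, D))
}

#' Initialize all model parameters
#'
#' Xavier-uniform initialization (seeded) for the three node-type embedding
#' MLPs, the per-layer propagation transforms and attention vector, the
#' contextual gate, the intervention-simulation operator, attention pooling,
#' the forward/backward GRUs, bi-temporal fusion, the forecast readout, the
#' clinical-prior projection and the event-anchor centers.
#'
#' @param dims A `cgse_dims` from [model_dims()].
#' @param event_labels Character vector of event labels (anchor centers are
#'   created one per label).
#' @param seed Required integer seed.
#' @return A `cgse_params` list; every matrix in it is trainable, the entries
#'   of `dims` are fixed hyperparameters.
#' @export
init_params <- function(dims, event_labels = character(0), seed) {
  if (missing(seed)) stop("init_params: seed is required")
  set.seed(as.integer(seed))
  D <- dims$D
  n_lab <- max(1L, length(event_labels))
  p <- list(
    phi_x = mlp_init(dims$d, D),
    phi_e = mlp_init(dims$d_e, D),
    phi_a = mlp_init(dims$d_a, D),
    W_layers = stats::setNames(lapply(seq_len(dims$L), function(l) xavier(D, D)),
                               paste0("l", seq_len(dims$L))),
    psi = xavier(2L * D, 1L),
    w_g = xavier(2L * D, 1L),
    b_g = matrix(0, 1L, 1L),
    W_s = xavier(D + dims$d_a, D),
    b_s = matrix(0, 1L, D),
    eta = matrix(1, 1L, 1L),
    q = xavier(D, 1L),
    W_q = xavier(D, D),
    gru_f = gru_init(D, D),
    gru_b = gru_init(D, D),
    W_f = xavier(2L * D, D),
    b_f = matrix(0, 1L, D),
    # readout starts at zero: under the residual head the untrained model
    # reproduces the last-value baseline exactly
    W_o = matrix(0, D, dims$d),
    b_o = matrix(0, 1L, dims$d),
    W_p = xavier(D, dims$d),
    b_p = matrix(0, 1L, dims$d),
    anchors = xavier(n_lab, D)
  )
  structure(list(dims = dims, event_labels = as.character(event_labels),
                 theta = p, seed = as.integer(seed)),
            class = "cgse_params")
}

# flatten the trainable matrices into a named list (stable order)
flatten_params <- function(theta, prefix = "") {
  out <- list()
  for (nm in names(theta)) {
    v <- theta[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.matrix(v)) {
      out[[key]] <- v
    } else if (is.list(v)) {
      if (is.null(names(v))) names(v) <- seq_along(v)
      out <- c(out, flatten_params(v, key))
    }
  }
  out
}

unflatten_params <- function(theta, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    theta[[path]] <- flat[[key]]
  }
  theta
}

#' Write a parameter checkpoint
#'
#' Serializes the full parameter set, dimensions and event labels as JSON with
#' full double precision, plus a format version and a config hash, so runs are
#' reproducible from text-only artifacts.
#'
#' @param params A `cgse_params`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(params, path) {
  flat <- flatten_params(params$theta)
  payload <- list(
    format = "cardiograph-checkpoint",
    version = 1L,
    config_hash = params_hash(params),
    dims = unclass(params$dims),
    event_labels = params$event_labels,
    seed = params$seed,
    theta = lapply(flat, function(m) list(dim = dim(m), data = as.numeric(m)))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a parameter checkpoint
#' @param path Checkpoint file written by [write_checkpoint()].
#' @return A `cgse_params`.
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cardiograph-checkpoint"))
    stop("read_checkpoint: unrecognized checkpoint format")
  dims <- do.call(model_dims, payload$dims[c("d", "d_e", "d_a", "D", "L", "K",
                                             "lambda_attn", "lambda_sim",
                                             "activation", "clamp_attention",
                                             "epsilon_geom", "eps_anchor",
                                             "head")])
  labels <- as.character(payload$event_labels)
  params <- init_params(dims, labels, seed = payload$seed)
  flat <- lapply(payload$theta, function(e) matrix(e$data, e$dim[1], e$dim[2]))
  names(flat) <- names(payload$theta)
  params$theta <- unflatten_params(params$theta, flat)
  params
}

# order-stable hash of dims + parameter shapes, for checkpoint provenance
params_hash <- function(params) {
  flat <- flatten_params(params$theta)
  desc <- paste(c(unlist(unclass(params$dims)), names(flat),
                  unlist(lapply(flat, dim))), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(desc) * (seq_len(nchar(desc, type = "bytes")) %% 97 + 1)) %% .Machine$integer.max)
}

activation_fn <- function(name) {
  switch(name,
         tanh = tanh,
         relu = function(x) pmax(x, 0),
         sigmoid = function(x) 1 / (1 + exp(-x)),
         identity = identity)
}
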