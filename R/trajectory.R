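#' Construct a patient trajectory
#'
#' A `patient_trajectory` is the raw multimodal record for one patient: a
#' time-indexed sequence of physiological state vectors, a set of timestamped
#' clinical events with feature vectors and categorical labels, and a set of
#' timestamped intervention actions with feature vectors. Timestamps are
#' continuous seconds on `[0, episode_duration]`.
#'
#' @param patient_id Opaque identifier (coerced to character).
#' @param timestamps Strictly increasing numeric vector of state times (s).
#' @param states Numeric matrix, one row per timestamp, `d` columns.
#' @param events Data frame with columns `t` (numeric), `label` (character)
#'   and a numeric feature matrix in attribute-free columns `z1..z_de`, or a
#'   list with elements `t`, `label`, `z` (matrix). `NULL` for none.
#' @param actions Data frame with columns `t` (numeric), optional `label`,
#'   and feature columns `u1..u_da`, or a list with `t`, `label`, `u`.
#'   `NULL` for none.
#' @param episode_duration Total episode length `T` (s); defaults to the last
#'   state timestamp.
#' @return An object of class `patient_trajectory`.
#' @export
patient_trajectory <- function(patient_id, timestamps, states,
                               events = NULL, actions = NULL,
                               episode_duration = NULL) {
  states <- as.matrix(states)
  timestamps <- as.numeric(timestamps)
  ev <- normalize_records(events, feat = "z", label_required = TRUE)
  ac <- normalize_records(actions, feat = "u", label_required = FALSE)
  if (is.null(episode_duration)) {
    cand <- c(timestamps, ev$t, ac$t)
    episode_duration <- if (length(cand)) max(cand) else NA_real_
  }
  traj <- structure(list(
    patient_id = as.character(patient_id)[1],
    timestamps = timestamps,
    states = unname(states),
    events = list(t = ev$t, label = ev$label, z = unname(ev$feat)),
    actions = list(t = ac$t, label = ac$label, u = unname(ac$feat)),
    episode_duration = as.numeric(episode_duration)[1]
  ), class = "patient_trajectory")
  validate_trajectory(traj)
  traj
}

# Accept either a data.frame (t, label, feature columns) or list(t, label, z/u)
normalize_records <- function(x, feat, label_required) {
  if (is.null(x)) {
    return(list(t = numeric(0), label = character(0),
                feat = matrix(numeric(0), nrow = 0, ncol = 0)))
  }
  if (is.data.frame(x)) {
    fc <- setdiff(names(x), c("t", "label"))
    m <- as.matrix(x[, fc, drop = FALSE])
    storage.mode(m) <- "double"
    lab <- if ("label" %in% names(x)) as.character(x$label) else rep(NA_character_, nrow(x))
    return(list(t = as.numeric(x$t), label = lab, feat = m))
  }
  m <- as.matrix(x[[feat]])
  n <- length(x$t)
  lab <- if (!is.null(x$label)) as.character(x$label) else rep(NA_character_, n)
  list(t = as.numeric(x$t), label = lab, feat = m)
}

#' Validate a patient trajectory against its invariants
#'
#' Checks strictly increasing timestamps, constant state dimension, and that
#' all state/event/action times fall inside `[0, episode_duration]`.
#'
#' @param traj A `patient_trajectory`.
#' @return `traj`, invisibly; errors (naming the patient) otherwise.
#' @export
validate_trajectory <- function(traj) {
  id <- traj$patient_id
  ts <- traj$timestamps
  if (length(ts) == 0L) stop("patient ", id, ": trajectory has no states")
  if (any(diff(ts) <= 0)) stop("patient ", id, ": timestamps not strictly increasing")
  if (!is.matrix(traj$states) || nrow(traj$states) != length(ts))
    stop("patient ", id, ": states must be a matrix with one row per timestamp")
  if (ncol(traj$states) < 1L) stop("patient ", id, ": state dimension d must be >= 1")
  if (any(!is.finite(traj$states))) stop("patient ", id, ": non-finite state values")
  tmax <- traj$episode_duration
  if (any(ts < 0) || any(ts > tmax))
    stop("patient ", id, ": state timestamps outside [0, T]")
  for (side in c("events", "actions")) {
    rec <- traj[[side]]
    if (length(rec$t) && (any(rec$t < 0) || any(rec$t > tmax)))
      stop("patient ", id, ": ", side, " timestamps outside [0, T]")
    if (length(rec$t) != nrow(rec[[if (side == "events") "z" else "u"]]) && length(rec$t) > 0)
      stop("patient ", id, ": ", side, " feature rows do not match times")
  }
  invisible(traj)
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat(sprintf(
    "<patient_trajectory %s: %d states (d=%d), %d events, %d actions, T=%.6g s>\n",
    x$patient_id, length(x$timestamps), ncol(x$states),
    length(x$events$t), length(x$actions$t), x$episode_duration))
  invisible(x)
}

#' Number of state samples in a trajectory
#' @param traj A `patient_trajectory`.
#' @return Integer count of state samples.
#' @export
n_states <- function(traj) length(traj$timestamps)

#' Discrete path length of the observed state sequence
#'
#' Approximates the integral of the state's rate of change between two
#' sampled times by the piecewise-linear path length
#' \eqn{\sum_i \lVert x_{i+1}-x_i \rVert_2} over consecutive samples in
#' `[t1, t2]`. Exact (telescoping) for sampling along a straight line.
#'
#' @param traj A `patient_trajectory`.
#' @param t1,t2 Times in the trajectory's timestamp set, `t1 < t2`.
#' @return Nonnegative scalar.
#' @export
observed_change <- function(traj, t1, t2) {
  if (t1 >= t2) stop("observed_change: t1 must be < t2")
  ts <- traj$timestamps
  idx <- which(ts >= t1 - 1e-12 & ts <= t2 + 1e-12)
  if (length(idx) < 2L) return(0)
  x <- traj$states[idx, , drop = FALSE]
  d <- diff(x)
  sum(sqrt(rowSums(d * d)))
}
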