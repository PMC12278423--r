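# Readers/writers for the trajectory and prior-table formats, plus run
# logging. JSONL writing uses canonical key order and full double precision
# (17 significant digits) so write-read-write is byte-stable.

traj_to_json <- function(traj) {
  rec <- list(
    patient_id = traj$patient_id,
    episode_duration = traj$episode_duration,
    states = lapply(seq_along(traj$timestamps), function(i) {
      list(t = traj$timestamps[i], x = I(as.numeric(traj$states[i, ])))
    }),
    events = lapply(seq_along(traj$events$t), function(k) {
      list(t = traj$events$t[k], label = traj$events$label[k],
           z = I(as.numeric(traj$events$z[k, ])))
    }),
    actions = lapply(seq_along(traj$actions$t), function(j) {
      rec <- list(t = traj$actions$t[j], u = I(as.numeric(traj$actions$u[j, ])))
      if (!is.na(traj$actions$label[j])) rec$label <- traj$actions$label[j]
      rec
    })
  )
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Write a cohort as JSON lines
#'
#' One JSON record per patient with fields `patient_id`, `episode_duration`,
#' `states` (`{t, x}`), `events` (`{t, label, z}`), `actions` (`{t, u}` and
#' optionally `label`). Keys are emitted in canonical order with full double
#' precision, making round trips reproducible byte-for-byte.
#'
#' @param trajectories List of `patient_trajectory` (or a
#'   `synthetic_cohort`).
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(trajectories, path) {
  if (inherits(trajectories, "synthetic_cohort"))
    trajectories <- trajectories$trajectories
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (traj in trajectories) writeLines(traj_to_json(traj), con)
  invisible(path)
}

#' Read a cohort from JSON lines or a CSV trio
#'
#' Every loaded record is validated against the trajectory invariants;
#' malformed records are rejected with a diagnostic naming the patient and
#' line.
#'
#' @param path `.jsonl` file (`format = "jsonl"`) or a directory holding
#'   `states.csv`, `events.csv`, `actions.csv` (`format = "csv-trio"`).
#' @param format Input format; guessed from `path` when missing.
#' @return List of `patient_trajectory`.
#' @export
read_cohort <- function(path, format = c("jsonl", "csv-trio")) {
  if (length(format) > 1L) format <- if (dir.exists(path)) "csv-trio" else "jsonl"
  format <- match.arg(format, c("jsonl", "csv-trio"))
  if (format == "jsonl") read_cohort_jsonl(path) else read_cohort_csv(path)
}

read_cohort_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop("read_cohort: line ", i,
                                             ": invalid JSON (", conditionMessage(e), ")"))
    if (is.null(rec$patient_id)) stop("read_cohort: line ", i, ": missing patient_id")
    states <- rec$states
    ts <- vapply(states, function(s) as.numeric(s$t), numeric(1))
    X <- do.call(rbind, lapply(states, function(s) as.numeric(unlist(s$x))))
    ev <- if (length(rec$events)) {
      list(t = vapply(rec$events, function(e) as.numeric(e$t), numeric(1)),
           label = vapply(rec$events, function(e) as.character(e$label), character(1)),
           z = do.call(rbind, lapply(rec$events, function(e) as.numeric(unlist(e$z)))))
    }
    ac <- if (length(rec$actions)) {
      list(t = vapply(rec$actions, function(a) as.numeric(a$t), numeric(1)),
           label = vapply(rec$actions, function(a)
             if (is.null(a$label)) NA_character_ else as.character(a$label), character(1)),
           u = do.call(rbind, lapply(rec$actions, function(a) as.numeric(unlist(a$u)))))
    }
    out[[i]] <- tryCatch(
      patient_trajectory(rec$patient_id, ts, X, ev, ac,
                         episode_duration = rec$episode_duration),
      error = function(e) stop("read_cohort: line ", i, ": ", conditionMessage(e)))
  }
  out
}

#' Write a cohort as a CSV trio
#'
#' `states.csv` (`patient_id, t, x1..xd`), `events.csv`
#' (`patient_id, t, label, z1..`), `actions.csv` (`patient_id, t, label,
#' u1..`), all keyed by `patient_id`.
#'
#' @param trajectories List of `patient_trajectory` (or `synthetic_cohort`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(trajectories, dir) {
  if (inherits(trajectories, "synthetic_cohort"))
    trajectories <- trajectories$trajectories
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bind_block <- function(getter) do.call(rbind, lapply(trajectories, getter))
  states <- bind_block(function(tr) {
    X <- tr$states
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    cbind(data.frame(patient_id = tr$patient_id, t = tr$timestamps), X)
  })
  events <- bind_block(function(tr) {
    if (!length(tr$events$t)) return(NULL)
    Z <- tr$events$z
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    cbind(data.frame(patient_id = tr$patient_id, t = tr$events$t,
                     label = tr$events$label), Z)
  })
  actions <- bind_block(function(tr) {
    if (!length(tr$actions$t)) return(NULL)
    U <- tr$actions$u
    colnames(U) <- paste0("u", seq_len(ncol(U)))
    cbind(data.frame(patient_id = tr$patient_id, t = tr$actions$t,
                     label = tr$actions$label), U)
  })
  utils::write.csv(states, file.path(dir, "states.csv"), row.names = FALSE)
  utils::write.csv(events %||% data.frame(patient_id = character(0), t = numeric(0),
                                          label = character(0)),
                   file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(actions %||% data.frame(patient_id = character(0), t = numeric(0),
                                           label = character(0)),
                   file.path(dir, "actions.csv"), row.names = FALSE)
  invisible(dir)
}

read_cohort_csv <- function(dir) {
  states <- utils::read.csv(file.path(dir, "states.csv"), stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  actions <- utils::read.csv(file.path(dir, "actions.csv"), stringsAsFactors = FALSE)
  ids <- unique(states$patient_id)
  lapply(ids, function(id) {
    st <- states[states$patient_id == id, , drop = FALSE]
    ev <- events[events$patient_id == id, , drop = FALSE]
    ac <- actions[actions$patient_id == id, , drop = FALSE]
    xcols <- grep("^x[0-9]+$", names(st), value = TRUE)
    mk <- function(df, prefix) {
      if (!nrow(df)) return(NULL)
      fcols <- grep(paste0("^", prefix, "[0-9]+$"), names(df), value = TRUE)
      list(t = df$t,
           label = if ("label" %in% names(df)) as.character(df$label) else NULL,
           feat = as.matrix(df[, fcols, drop = FALSE]))
    }
    ev_l <- mk(ev, "z"); ac_l <- mk(ac, "u")
    tryCatch(
      patient_trajectory(id, st$t, as.matrix(st[, xcols, drop = FALSE]),
                         events = if (!is.null(ev_l))
                           list(t = ev_l$t, label = ev_l$label, z = ev_l$feat),
                         actions = if (!is.null(ac_l))
                           list(t = ac_l$t, label = ac_l$label, u = ac_l$feat)),
      error = function(e) stop("read_cohort: ", conditionMessage(e)))
  })
}

#' Read a causal prior table from CSV
#'
#' Expected columns: `src_kind, src_label, dst_kind, dst_label, max_lag_s,
#' weight`.
#'
#' @param path CSV path.
#' @return A [causal_prior_table()].
#' @export
read_prior_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("src_kind", "src_label", "dst_kind", "dst_label", "max_lag_s", "weight")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_prior_table: missing columns: ", paste(missing_cols, collapse = ", "))
  do.call(causal_prior_table, as.list(df[need]))
}

#' Write a causal prior table to CSV
#' @param priors A [causal_prior_table()]. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prior_table <- function(priors, path) {
  utils::write.csv(as.data.frame(priors), path, row.names = FALSE)
  invisible(path)
}

#' Append a run-log entry
#'
#' Plain-text log line with an ISO-8601 timestamp, the config seed and hash,
#' and the package version of record.
#'
#' @param path Log file (appended). @param config A `run_config`.
#' @param message Event description.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config, message) {
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ver <- as.character(utils::packageVersion("cardiograph"))
  line <- sprintf("%s seed=%d cardiograph=%s | %s", stamp, config$seed, ver, message)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
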