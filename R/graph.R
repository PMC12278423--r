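#' Causal prior rule table
#'
#' A rule table encoding directed causal priors (e.g. from clinical
#' guidelines): each rule links source nodes of a given kind/label pattern to
#' later target nodes of a given kind/label pattern within a maximal lag.
#' Matching is forward in time; the induced edge weight decays with the lag as
#' `exp(-dt / max_lag)`, emulating expected pharmacodynamic delays.
#'
#' @param src_kind,dst_kind Node kinds, each one of `"state"`, `"event"`,
#'   `"action"`.
#' @param src_label,dst_label Label patterns; `"*"` matches any label (state
#'   nodes are unlabeled and match only `"*"`).
#' @param max_lag_s Positive maximal lag in seconds, one per rule.
#' @param weight Nonnegative base weight, one per rule (recycled).
#' @return A `causal_prior_table` (a data frame subclass).
#' @export
causal_prior_table <- function(src_kind = character(0), src_label = character(0),
                               dst_kind = character(0), dst_label = character(0),
                               max_lag_s = numeric(0), weight = numeric(0)) {
  df <- data.frame(src_kind = as.character(src_kind),
                   src_label = as.character(src_label),
                   dst_kind = as.character(dst_kind),
                   dst_label = as.character(dst_label),
                   max_lag_s = as.numeric(max_lag_s),
                   weight = as.numeric(weight),
                   stringsAsFactors = FALSE)
  kinds <- c("state", "event", "action")
  if (nrow(df)) {
    if (!all(df$src_kind %in% kinds) || !all(df$dst_kind %in% kinds))
      stop("causal_prior_table: node kinds must be state/event/action")
    if (any(df$max_lag_s <= 0)) stop("causal_prior_table: max_lag_s must be > 0")
    if (any(df$weight < 0)) stop("causal_prior_table: weights must be >= 0")
  }
  class(df) <- c("causal_prior_table", "data.frame")
  df
}

label_matches <- function(pattern, labels) {
  if (pattern == "*") rep(TRUE, length(labels)) else !is.na(labels) & labels == pattern
}

#' Build the typed cardiovascular graph for one trajectory
#'
#' Creates one node per state sample, clinical event and intervention action,
#' then adds (i) a bidirected temporal backbone between consecutive state
#' nodes, (ii) bidirected co-occurrence edges between any two nodes within
#' `window` seconds of each other, and (iii) directed causal edges for every
#' prior rule matched forward in time within its `max_lag_s`, weighted
#' `rule_weight * exp(-dt / max_lag_s)`. Self-loops are never created and a
#' duplicate directed edge keeps its first (temporal before causal) insertion.
#'
#' @param traj A `patient_trajectory`.
#' @param priors A `causal_prior_table` (may have zero rows).
#' @param window Positive co-occurrence window in seconds.
#' @return A `cardio_graph` with `nodes` and `edges` data frames. Nodes are
#'   ordered by time, then kind (state < event < action), then input order;
#'   `nodes$ref` indexes back into the trajectory's own record lists.
#' @export
build_graph <- function(traj, priors = causal_prior_table(), window) {
  validate_trajectory(traj)
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("build_graph: window must be a positive scalar (seconds)")

  kind <- c(rep("state", length(traj$timestamps)),
            rep("event", length(traj$events$t)),
            rep("action", length(traj$actions$t)))
  time <- c(traj$timestamps, traj$events$t, traj$actions$t)
  ref <- c(seq_along(traj$timestamps), seq_along(traj$events$t),
           seq_along(traj$actions$t))
  label <- c(rep(NA_character_, length(traj$timestamps)),
             traj$events$label, traj$actions$label)
  kind_rank <- c(state = 1L, event = 2L, action = 3L)
  ord <- order(time, kind_rank[kind], seq_along(time))
  nodes <- data.frame(id = seq_along(ord), kind = kind[ord], time = time[ord],
                      ref = ref[ord], label = label[ord], stringsAsFactors = FALSE)

  state_ids <- nodes$id[nodes$kind == "state"]
  state_ids <- state_ids[order(nodes$time[state_ids])]

  src <- integer(0); dst <- integer(0); w <- numeric(0); prov <- character(0)
  backbone <- logical(0)
  add_edges <- function(s, d, wt, pv, bb) {
    src <<- c(src, s); dst <<- c(dst, d); w <<- c(w, wt)
    prov <<- c(prov, rep(pv, length(s))); backbone <<- c(backbone, rep(bb, length(s)))
  }

  # temporal backbone: consecutive state nodes, both directions, always kept
  if (length(state_ids) >= 2L) {
    a <- state_ids[-length(state_ids)]; b <- state_ids[-1L]
    add_edges(c(a, b), c(b, a), rep(1, 2L * length(a)), "temporal", TRUE)
  }

  # co-occurrence: all node pairs within `window`, both directions
  n <- nrow(nodes)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      j <- i + which(nodes$time[(i + 1L):n] - nodes$time[i] <= window)
      if (length(j)) {
        wt <- rep(1, length(j))
        add_edges(rep(nodes$id[i], length(j)), nodes$id[j], wt, "temporal", FALSE)
        add_edges(nodes$id[j], rep(nodes$id[i], length(j)), wt, "temporal", FALSE)
      }
    }
  }

  # causal prior edges: src matched forward in time to dst within max_lag
  for (r in seq_len(nrow(priors))) {
    rule <- priors[r, ]
    si <- which(nodes$kind == rule$src_kind & label_matches(rule$src_label, nodes$label))
    di <- which(nodes$kind == rule$dst_kind & label_matches(rule$dst_label, nodes$label))
    if (!length(si) || !length(di)) next
    for (i in si) {
      dtv <- nodes$time[di] - nodes$time[i]
      hit <- di[dtv > 0 & dtv <= rule$max_lag_s]
      if (length(hit)) {
        dtv <- nodes$time[hit] - nodes$time[i]
        add_edges(rep(nodes$id[i], length(hit)), hit,
                  rule$weight * exp(-dtv / rule$max_lag_s), "causal", FALSE)
      }
    }
  }

  keep <- src != dst & !duplicated(paste(src, dst))
  edges <- data.frame(src = src[keep], dst = dst[keep], weight = w[keep],
                      provenance = prov[keep], backbone = backbone[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 node_index = stats::setNames(nodes$id, nodes$id),
                 patient_id = traj$patient_id),
            class = "cardio_graph")
}

#' @export
print.cardio_graph <- function(x, ...) {
  kc <- table(factor(x$nodes$kind, levels = c("state", "event", "action")))
  cat(sprintf("<cardio_graph %s: %d nodes (state %d, event %d, action %d), %d edges (%d causal)>\n",
              x$patient_id, nrow(x$nodes), kc[["state"]], kc[["event"]], kc[["action"]],
              nrow(x$edges), sum(x$edges$provenance == "causal")))
  invisible(x)
}

#' Filter graph edges by relevance score
#'
#' Keeps edges whose score is at least `threshold`. The temporal backbone
#' (consecutive state nodes) is never removed, so the graph stays connected in
#' time. The node set is unchanged.
#'
#' @param graph A `cardio_graph`.
#' @param relevance Numeric vector of scores, one per row of `graph$edges`
#'   (or named `"src->dst"`); every edge must have a finite score.
#' @param threshold Finite scalar (use `-Inf` to keep everything).
#' @return The filtered `cardio_graph`.
#' @export
filter_edges <- function(graph, relevance, threshold) {
  ne <- nrow(graph$edges)
  if (!is.null(names(relevance))) {
    key <- paste0(graph$edges$src, "->", graph$edges$dst)
    relevance <- relevance[key]
  }
  if (length(relevance) != ne || any(is.na(relevance)))
    stop("filter_edges: every edge needs a relevance score")
  keep <- graph$edges$backbone | (relevance >= threshold)
  graph$edges <- graph$edges[keep, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' In-neighborhood of a node
#'
#' Message passing aggregates over incoming edges: `N(v)` is the set of
#' sources `u` of directed edges `u -> v`.
#'
#' @param graph A `cardio_graph`.
#' @param v Node id.
#' @return Integer vector of neighbor node ids (possibly empty).
#' @export
in_neighbors <- function(graph, v) graph$edges$src[graph$edges$dst == v]

#' Unnormalized graph Laplacian of the undirected support
#'
#' Builds `L = D - A` over the undirected, unit-weight support of the graph
#' (each directed edge contributes the undirected pair once).
#'
#' @param graph A `cardio_graph`.
#' @return A dense numeric matrix `n x n` ordered by node id.
#' @export
graph_laplacian <- function(graph) {
  n <- nrow(graph$nodes)
  und <- undirected_support(graph)
  A <- matrix(0, n, n)
  if (nrow(und)) {
    A[cbind(und$u, und$v)] <- 1
    A[cbind(und$v, und$u)] <- 1
  }
  diag(rowSums(A)) - A
}

# unique undirected edges (u < v) of the support
undirected_support <- function(graph) {
  if (!nrow(graph$edges)) return(data.frame(u = integer(0), v = integer(0)))
  u <- pmin(graph$edges$src, graph$edges$dst)
  v <- pmax(graph$edges$src, graph$edges$dst)
  keep <- !duplicated(paste(u, v))
  data.frame(u = u[keep], v = v[keep])
}
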