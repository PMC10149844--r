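#' Discounted returns of a reward sequence
#'
#' Computes `R_t = sum_{tau = t+1..T} gamma^(tau - t - 1) r_tau` for every
#' step of an episode by exact backward accumulation, where `rewards[t]`
#' is the reward received after step t (i.e. `r_{t+1}`).
#'
#' @param rewards numeric vector of per-step rewards.
#' @param gamma discount factor in `[0, 1]`.
#' @return numeric vector of the same length; empty input yields an empty
#'   result.
#' @examples
#' discounted_returns(c(0, 0, 1), 0.9)  # 0.81 0.90 1.00
#' @export
discounted_returns <- function(rewards, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  n <- length(rewards)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  acc <- 0
  for (t in n:1) {
    acc <- rewards[t] + gamma * acc
    out[t] <- acc
  }
  out
}

#' Episodic-control memory
#'
#' The one-shot learner's store: a Q table keyed by projected state and
#' action, updated at the end of every episode with the max-rule
#' `Q^EC(s,a) <- max(R_t, Q^EC(s,a))` (new entries are set to `R_t`), so
#' stored values never decrease. Because the observation codec is
#' deterministic, revisited states collide exactly and the table is keyed
#' by state identity; the projected vectors drive the nearest-neighbor
#' index used to estimate values of truly novel states (mean Q of the
#' `k` nearest stored projected states, Euclidean distance, ties broken
#' by insertion order).
#'
#' @param codec a [state_codec()] for the maze being learned.
#' @param projection a [projection_matrix()] with `ncol == codec$dim`.
#' @param k neighbor count for novel-state estimates (default 5).
#' @param gamma discount factor (default 0.9).
#' @param capacity maximum number of stored (state, action) entries
#'   (default 50000); least-recently-updated entries are evicted first.
#' @param missing_action how neighbors lacking a value for the queried
#'   action contribute to the k-NN mean: counted as 0 (`"zero"`, default)
#'   or skipped (`"skip"`).
#' @return An environment of class `ec_memory`.
#' @export
ec_memory <- function(codec, projection, k = 5L, gamma = 0.9,
                      capacity = 50000L, missing_action = c("zero", "skip")) {
  missing_action <- match.arg(missing_action)
  if (ncol(projection) != codec$dim) stop("projection/codec dimension mismatch")
  mem <- new.env(parent = emptyenv())
  mem$k <- as.integer(k)
  mem$gamma <- gamma
  mem$capacity <- as.integer(capacity)
  mem$missing_action <- missing_action
  mem$n_states <- codec$n_states
  mem$proj <- project(projection, codec$observations)   # n_states x F
  # all-pairs Euclidean distances in projected space; the deterministic
  # codec makes the state set finite, so the neighbor index is exact
  mem$proj_dist <- as.matrix(stats::dist(mem$proj))
  mem$Q <- matrix(NA_real_, codec$n_states, 6L)
  mem$stored <- integer(0)                              # state ids, insertion order
  mem$is_stored <- logical(codec$n_states)
  mem$stamp <- matrix(0, codec$n_states, 6L)            # last-update clock, for eviction
  mem$clock <- 0
  mem$n_entries <- 0L
  mem$evictions <- 0L
  class(mem) <- "ec_memory"
  mem
}

.ec_knn <- function(mem, s) {
  ns <- length(mem$stored)
  if (ns == 0L) return(integer(0))
  d <- mem$proj_dist[s, mem$stored]
  mem$stored[order(d)[seq_len(min(mem$k, ns))]]
}

#' Episodic-control Q estimate
#'
#' Exact table value when the (state, action) entry is stored; otherwise
#' the mean stored value of that action over the `k` nearest stored
#' states in projected space (all stored states if fewer than `k`);
#' 0 when the memory is empty.
#'
#' @param mem an [ec_memory()].
#' @param state oriented state or state index.
#' @param action action index 1..6, or `NULL` for all six values.
#' @return numeric Q estimate (or length-6 vector when `action = NULL`).
#' @export
ec_q_lookup <- function(mem, state, action = NULL) {
  s <- if (is.list(state)) state$state else as.integer(state)
  q <- mem$Q[s, ]
  if (is.null(action)) {
    if (anyNA(q)) q <- .ec_fill(mem, s, q)
    return(q)
  }
  a <- as.integer(action)
  if (!is.na(q[a])) return(q[a])
  .ec_fill(mem, s, q)[a]
}

.ec_fill <- function(mem, s, q) {
  nn <- .ec_knn(mem, s)
  miss <- which(is.na(q))
  if (length(nn) == 0L) { q[miss] <- 0; return(q) }
  qn <- mem$Q[nn, , drop = FALSE]
  if (mem$missing_action == "zero") {
    qn[is.na(qn)] <- 0
    q[miss] <- colMeans(qn)[miss]
  } else {
    est <- colMeans(qn, na.rm = TRUE)
    est[is.nan(est)] <- 0
    q[miss] <- est[miss]
  }
  q
}

#' Episode-end episodic-control update
#'
#' Applies the max-update to every (state, action) pair of an episode
#' trace: unseen entries are created with the discounted return `R_t` from
#' that step; existing entries are raised to `max(R_t, Q)` and never
#' decreased. Newly seen states enter the neighbor index; the capacity
#' bound is enforced by evicting least-recently-updated entries.
#'
#' @param mem an [ec_memory()].
#' @param trace an episode trace: data.frame with columns `s`, `a`, `s2`,
#'   `r`, `terminal` (one row per step, in order), as produced by
#'   [run_training()] or [as_episode_trace()].
#' @return list with counts `created` and `raised` (invisibly).
#' @export
ec_update <- function(mem, trace) {
  R <- discounted_returns(trace$r, mem$gamma)
  created <- 0L; raised <- 0L
  for (t in seq_along(R)) {
    s <- trace$s[t]; a <- trace$a[t]
    cur <- mem$Q[s, a]
    mem$clock <- mem$clock + 1
    if (is.na(cur)) {
      mem$Q[s, a] <- R[t]
      mem$stamp[s, a] <- mem$clock
      mem$n_entries <- mem$n_entries + 1L
      created <- created + 1L
      if (!mem$is_stored[s]) {
        mem$is_stored[s] <- TRUE
        mem$stored <- c(mem$stored, s)
      }
    } else if (R[t] > cur) {
      mem$Q[s, a] <- R[t]
      mem$stamp[s, a] <- mem$clock
      raised <- raised + 1L
    } else {
      mem$stamp[s, a] <- mem$clock
    }
  }
  while (mem$n_entries > mem$capacity) .ec_evict(mem)
  invisible(list(created = created, raised = raised))
}

.ec_evict <- function(mem) {
  idx <- which(!is.na(mem$Q))
  victim <- idx[which.min(mem$stamp[idx])]
  mem$Q[victim] <- NA_real_
  mem$stamp[victim] <- 0
  mem$n_entries <- mem$n_entries - 1L
  mem$evictions <- mem$evictions + 1L
  s <- ((victim - 1L) %% nrow(mem$Q)) + 1L
  if (all(is.na(mem$Q[s, ]))) {
    mem$is_stored[s] <- FALSE
    mem$stored <- mem$stored[mem$stored != s]
  }
  invisible(NULL)
}

#' Coerce step logs to an episode trace
#'
#' @param s,a,s2,r,terminal parallel per-step vectors (state, action,
#'   next state, reward, terminal flag).
#' @return data.frame trace suitable for [ec_update()].
#' @export
as_episode_trace <- function(s, a, s2, r, terminal) {
  data.frame(s = as.integer(s), a = as.integer(a), s2 = as.integer(s2),
             r = as.numeric(r), terminal = as.logical(terminal))
}

#' Forward-sweep episodic-control oracle
#'
#' Alternative formulation of episodic control used as an exactness check
#' on the incremental table: all episodes are kept verbatim and, for each
#' (state, action) pair, the Q value is the maximum over all occurrences
#' of the pair of the discounted reward accumulated by sweeping forward
#' from that occurrence to its episode's end. On exactly-keyed states the
#' result must equal the incrementally built table entrywise.
#'
#' @param traces list of episode traces (see [as_episode_trace()]).
#' @param gamma discount factor.
#' @param n_states total state count of the maze.
#' @return `n_states x 6` matrix of Q values (`NA` where never visited).
#' @export
ec_oracle <- function(traces, gamma, n_states) {
  Q <- matrix(NA_real_, n_states, 6L)
  for (tr in traces) {
    n <- nrow(tr)
    for (t in seq_len(n)) {
      # forward sweep from occurrence t to the episode end
      val <- 0
      g <- 1
      for (tau in t:n) {
        val <- val + g * tr$r[tau]
        g <- g * gamma
      }
      s <- tr$s[t]; a <- tr$a[t]
      if (is.na(Q[s, a]) || val > Q[s, a]) Q[s, a] <- val
    }
  }
  Q
}

#' Export an episodic-control memory snapshot
#'
#' Joins the Q table through the state registry to a tidy table of
#' (node, heading, action, q), e.g. for reward-propagation maps.
#'
#' @param mem an [ec_memory()].
#' @param maze the owning `tunnel_maze`.
#' @param path optional CSV output path.
#' @return data.frame of stored entries (invisibly written to `path` if
#'   given).
#' @export
ec_snapshot <- function(mem, maze, path = NULL) {
  st <- maze_states(maze)
  idx <- which(!is.na(mem$Q), arr.ind = TRUE)
  out <- data.frame(node = st$node[idx[, 1]], heading = st$heading[idx[, 1]],
                    action = ACTIONS[idx[, 2]], q = mem$Q[idx])
  out <- out[order(out$node, out$heading, out$action), ]
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' @export
print.ec_memory <- function(x, ...) {
  cat(sprintf("episodic-control memory: %d entries over %d states (k = %d, gamma = %g)\n",
              x$n_entries, length(x$stored), x$k, x$gamma))
  invisible(x)
}
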