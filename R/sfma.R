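#' Experience store for sequential replay
#'
#' Deduplicated store of experience tuples `(s, a, s')` with per-tuple
#' visit counts `n(e)`, reward tallies and an inhibition level
#' `I(e) in [0, 1]`, backing the strength x similarity x inhibition
#' replay sampler. Reactivation scores combine three factors:
#'
#' * strength `C(e) = c(e) * (1 + lambda_r * rbar(e))`, with `rbar` the
#'   mean reward of `e` and `c(e)` the visit count -- by default
#'   normalized by the maximum stored count (`strength_norm = "max"`) so
#'   scores stay on an order-1 scale and the inverse temperature sweeps
#'   the documented range; `strength_norm = "none"` keeps raw counts;
#' * similarity `D(e|e') = exp(-d_G / sigma)`, with `d_G` the graph
#'   distance between the anchor nodes of `e` and the last reactivated
#'   `e'` (in reverse mode the candidate's *next* state is anchored
#'   against the predecessor's *current* state, so chains extend backward
#'   along behavior; forward mode mirrors this);
#' * inhibition `1 - I(e)`: a reactivated tuple is fully inhibited and
#'   its inhibition decays by `lambda_i` per reactivation step.
#'
#' @param maze a `tunnel_maze` (supplies graph distances between nodes).
#' @param sigma similarity half-width in nodes (default 1).
#' @param lambda_r reward weight in the strength factor (default 1).
#' @param lambda_i per-step inhibition decay (default 0.99); the
#'   disinhibition horizon 1/(1 - lambda_i) is kept comparable to the
#'   event length so one event cannot loop over a handful of tuples.
#' @param strength_norm `"max"` (default) or `"none"`.
#' @return environment of class `experience_store`.
#' @export
experience_store <- function(maze, sigma = 1, lambda_r = 1, lambda_i = 0.99,
                             strength_norm = c("max", "none")) {
  st <- new.env(parent = emptyenv())
  st$sigma <- sigma
  st$lambda_r <- lambda_r
  st$lambda_i <- lambda_i
  st$strength_norm <- match.arg(strength_norm)
  st$n_states <- maze$n_states
  st$dist_nodes <- maze$dist_nodes
  st$state_node <- rep(seq_len(maze$n_nodes), each = 4L)
  cap <- maze$n_states * 6L          # at most one tuple per (state, action)
  st$keymap <- integer(cap)          # (s-1)*6 + a  ->  row id (0 = absent)
  st$s <- integer(cap); st$a <- integer(cap); st$s2 <- integer(cap)
  st$n <- numeric(cap); st$r_sum <- numeric(cap); st$terminal <- logical(cap)
  st$I <- numeric(cap)
  st$m <- 0L
  class(st) <- "experience_store"
  st
}

#' Record experiences in the store
#'
#' Tuples are deduplicated by `(s, a, s')`; the visit count is
#' incremented and the reward tallied on revisits.
#'
#' @param store an [experience_store()].
#' @param s,a,s2,r,terminal parallel transition vectors (state indices).
#' @return the store, invisibly.
#' @export
store_record <- function(store, s, a, s2, r, terminal) {
  keys <- (as.integer(s) - 1L) * 6L + as.integer(a)
  for (i in seq_along(keys)) {
    row <- store$keymap[keys[i]]
    if (row == 0L) {
      store$m <- row <- store$m + 1L
      store$keymap[keys[i]] <- row
      store$s[row] <- s[i]; store$a[row] <- a[i]; store$s2[row] <- s2[i]
      store$terminal[row] <- terminal[i]
    }
    store$n[row] <- store$n[row] + 1
    store$r_sum[row] <- store$r_sum[row] + r[i]
  }
  invisible(store)
}

#' Stored experiences as a table
#'
#' @param store an [experience_store()].
#' @return data.frame with one row per unique stored tuple.
#' @export
store_experiences <- function(store) {
  m <- store$m
  data.frame(e = seq_len(m), s = store$s[seq_len(m)], a = store$a[seq_len(m)],
             s2 = store$s2[seq_len(m)], n = store$n[seq_len(m)],
             r_mean = ifelse(store$n[seq_len(m)] > 0,
                             store$r_sum[seq_len(m)] / store$n[seq_len(m)], 0),
             terminal = store$terminal[seq_len(m)])
}

#' Strength factor C(e)
#'
#' `C(e) = c(e) * (1 + lambda_r * rbar(e))`; 0 for never-stored
#' experiences. See [experience_store()] for the count normalization.
#'
#' @param store an [experience_store()].
#' @param e experience row id(s); `NULL` for all stored experiences.
#' @return numeric vector of strengths.
#' @export
strength <- function(store, e = NULL) {
  m <- store$m
  if (m == 0L) return(numeric(0))
  n <- store$n[seq_len(m)]
  cnt <- if (store$strength_norm == "max") n / max(n) else n
  rbar <- store$r_sum[seq_len(m)] / n
  C <- cnt * (1 + store$lambda_r * rbar)
  if (is.null(e)) C else ifelse(e >= 1L & e <= m, C[pmin(pmax(e, 1L), m)], 0)
}

.anchor_nodes <- function(store, mode) {
  m <- seq_len(store$m)
  if (mode == "reverse") store$state_node[store$s2[m]]
  else store$state_node[store$s[m]]
}

#' Similarity factor D(e | e')
#'
#' `exp(-d_G / sigma)` over the graph distance between the candidate's
#' anchor node and the previous reactivation's anchor node; 1 at the
#' start of an event (no previous reactivation), 0 for unreachable
#' anchors.
#'
#' @param store an [experience_store()].
#' @param e candidate experience row id(s).
#' @param e_prev previously reactivated experience row id, or `NULL` at
#'   the event start.
#' @param mode `"reverse"` (chains extend backward along behavior) or
#'   `"forward"`.
#' @return numeric similarity in `[0, 1]`.
#' @export
similarity <- function(store, e, e_prev = NULL, mode = c("reverse", "forward")) {
  mode <- match.arg(mode)
  if (is.null(e_prev)) return(rep(1, length(e)))
  anchors <- .anchor_nodes(store, mode)
  prev_anchor <- if (mode == "reverse") store$state_node[store$s[e_prev]]
                 else store$state_node[store$s2[e_prev]]
  d <- store$dist_nodes[anchors[e], prev_anchor]
  exp(-d / store$sigma)
}

#' Reactivation scores R(e | e')
#'
#' `R(e|e') = C(e) * D(e|e') * (1 - I(e))` for every stored experience.
#'
#' @param store an [experience_store()].
#' @param e_prev previously reactivated experience row id or `NULL`.
#' @param mode `"reverse"` or `"forward"`.
#' @return numeric vector of length `m` (empty store: length 0).
#' @export
reactivation_scores <- function(store, e_prev = NULL,
                                mode = c("reverse", "forward")) {
  mode <- match.arg(mode)
  m <- store$m
  if (m == 0L) return(numeric(0))
  C <- strength(store)
  if (is.null(e_prev)) D <- rep(1, m)
  else {
    anchors <- .anchor_nodes(store, mode)
    prev_anchor <- if (mode == "reverse") store$state_node[store$s[e_prev]]
                   else store$state_node[store$s2[e_prev]]
    D <- exp(-store$dist_nodes[anchors, prev_anchor] / store$sigma)
  }
  C * D * (1 - store$I[seq_len(m)])
}

#' Inverse-temperature replay sampling
#'
#' Samples the next reactivated experience from
#' `p(e|e') = (exp(beta R(e|e')) - 1) / sum_tau (exp(beta R(e_tau|e')) - 1)`,
#' so a zero score has probability exactly zero. At `beta = 0` the rule
#' switches (a deliberate discontinuity of the model) to uniform sampling
#' over the eligible experiences -- those visited (`C > 0`) and not fully
#' inhibited (`I < 1`).
#'
#' @param scores reactivation scores over the stored experiences.
#' @param beta inverse temperature, `>= 0`.
#' @param eligible logical eligibility mask used when `beta = 0`
#'   (defaults to `scores > 0`).
#' @return sampled experience row id, or `NA_integer_` when no
#'   probability mass exists (the caller ends the event early).
#' @export
sample_next <- function(scores, beta, eligible = scores > 0) {
  m <- length(scores)
  if (m == 0L) return(NA_integer_)
  if (beta == 0) {
    cand <- which(eligible)
    if (length(cand) == 0L) return(NA_integer_)
    return(cand[sample.int(length(cand), 1L)])
  }
  bs <- beta * scores
  mx <- max(bs)
  if (mx <= 0) return(NA_integer_)
  w <- if (mx > 700) {            # overflow-safe: exp(bs - mx), zeros stay zero
    out <- exp(bs - mx); out[scores <= 0] <- 0; out
  } else expm1(bs)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) return(NA_integer_)
  sample.int(m, 1L, prob = w)
}

#' Analytic replay probabilities
#'
#' The normalized distribution underlying [sample_next()] for `beta > 0`;
#' used for goodness-of-fit diagnostics.
#'
#' @inheritParams sample_next
#' @return numeric probability vector summing to 1.
#' @export
replay_probabilities <- function(scores, beta) {
  stopifnot(beta > 0)
  w <- expm1(beta * scores)
  w / sum(w)
}

#' Generate a sequential replay event
#'
#' A trial-end reactivation episode: inhibitions are reset, then
#' experiences are drawn one at a time via [sample_next()]; each
#' reactivation fully inhibits its experience and all inhibitions decay
#' by `lambda_i` per step, allowing long events to revisit experiences.
#' The reactivation stream is chunked into `n_batches` batches of
#' `batch_size`, each of which drives one network update downstream.
#'
#' @param store an [experience_store()] (nonempty).
#' @param n_batches number of batches in the event.
#' @param batch_size experiences per batch (default 32).
#' @param beta inverse temperature.
#' @param mode `"reverse"` (default experimental setting) or
#'   `"forward"`.
#' @param anchor optional state index at which the event initiates
#'   (typically the agent's position at trial end, i.e. the goal on
#'   successful trials); the first reactivation is then drawn with the
#'   similarity factor anchored there, so reverse events begin near the
#'   reward and sweep backward. `NULL` seeds the event from the strength
#'   factor alone.
#' @return object of class `replay_event`: list with `batches` (list of
#'   integer experience-id vectors), `sequence`, `mode`, `beta` and a
#'   `truncated` flag set when the event terminated early.
#' @export
generate_replay_event <- function(store, n_batches, batch_size = 32L,
                                  beta, mode = c("reverse", "forward"),
                                  anchor = NULL) {
  mode <- match.arg(mode)
  if (store$m == 0L) stop("cannot replay from an empty store")
  m <- store$m
  total <- n_batches * batch_size
  seqs <- integer(total)
  e_prev <- NULL
  # hot loop: work on local copies, write inhibition back at the end
  C <- strength(store)
  anchors <- .anchor_nodes(store, mode)
  state_node <- store$state_node
  src_nodes <- state_node[store$s[seq_len(m)]]
  dst_nodes <- state_node[store$s2[seq_len(m)]]
  move_nodes <- if (mode == "reverse") src_nodes else dst_nodes
  by_move_node <- split(seq_len(m), move_nodes)
  simmat <- exp(-store$dist_nodes / store$sigma)   # node-level similarity
  anchor_node <- if (!is.null(anchor)) state_node[as.integer(anchor)]
  I <- numeric(m)
  lam <- store$lambda_i
  eligible0 <- C > 0
  k <- 0L
  for (i in seq_len(total)) {
    if ((i - 1L) %% batch_size == 0L) e_prev <- NULL
    if (is.null(e_prev)) {
      # replay initiates at the agent's current position when one is given
      # (at trial end this is the goal on successful trials), so reverse
      # events begin near the reward and sweep backward; without an anchor
      # every experience is an equally similar event seed
      D <- if (is.null(anchor_node)) 1 else simmat[anchors, anchor_node]
    } else {
      prev_anchor <- if (mode == "reverse") state_node[store$s[e_prev]]
                     else state_node[store$s2[e_prev]]
      D <- simmat[anchors, prev_anchor]
    }
    scores <- C * D * (1 - I)
    e <- sample_next(scores, beta, eligible = eligible0 & I < 1)
    if (is.na(e)) break
    k <- i
    seqs[i] <- e
    I <- I * lam
    # refractoriness acts at the level of the co-localized assembly: all
    # experiences that would pull the wave back into the node it just
    # covered are inhibited together with the reactivated tuple, which is
    # what makes reverse waves sweep outward instead of diffusing among
    # the ~24 tuples each node hosts
    covered <- if (mode == "reverse") state_node[store$s2[e]]
               else state_node[store$s[e]]
    I[by_move_node[[as.character(covered)]]] <- 1
    I[e] <- 1
    e_prev <- e
  }
  store$I[seq_len(m)] <- I
  seqs <- seqs[seq_len(k)]
  batches <- split(seqs, ceiling(seq_along(seqs) / batch_size))
  structure(list(batches = unname(batches), sequence = seqs, mode = mode,
                 beta = beta, batch_size = as.integer(batch_size),
                 truncated = k < total),
            class = "replay_event")
}

#' Generate a random replay event
#'
#' The trial-end random comparator: experiences are drawn independently
#' with probability proportional to their visit frequency `n(e)`, with
#' the same event geometry (`n_batches` x `batch_size`) as sequential
#' events.
#'
#' @inheritParams generate_replay_event
#' @return a `replay_event` with `mode = "random"`.
#' @export
random_replay_event <- function(store, n_batches, batch_size = 32L) {
  if (store$m == 0L) stop("cannot replay from an empty store")
  total <- n_batches * batch_size
  n <- store$n[seq_len(store$m)]
  seqs <- sample.int(store$m, total, replace = TRUE, prob = n)
  batches <- split(seqs, ceiling(seq_along(seqs) / batch_size))
  structure(list(batches = unname(batches), sequence = seqs, mode = "random",
                 beta = NA_real_, batch_size = as.integer(batch_size),
                 truncated = FALSE),
            class = "replay_event")
}

#' Within-event replay sequence lengths
#'
#' Lengths of maximal runs of spatially contiguous reactivations. In
#' reverse mode a reactivation extends the current run when its *next*
#' state's node lies within one node of the previous reactivation's
#' *current* node -- the wave moved contiguously backward along behavior
#' (replay statistics are scored at this spatial resolution); forward
#' mode mirrors this.
#'
#' @param store the [experience_store()] the event was drawn from.
#' @param event a `replay_event`.
#' @return integer vector of run lengths (sums to the event length).
#' @export
replay_sequence_lengths <- function(store, event) {
  seqs <- event$sequence
  if (length(seqs) <= 1L) return(length(seqs))
  nd <- store$state_node
  if (identical(event$mode, "forward"))
    adj <- store$dist_nodes[cbind(nd[store$s[seqs[-1]]],
                                  nd[store$s2[seqs[-length(seqs)]]])] <= 1
  else
    adj <- store$dist_nodes[cbind(nd[store$s2[seqs[-1]]],
                                  nd[store$s[seqs[-length(seqs)]]])] <= 1
  lens <- integer(0)
  cur <- 1L
  for (ok in adj) {
    if (ok) cur <- cur + 1L
    else { lens <- c(lens, cur); cur <- 1L }
  }
  c(lens, cur)
}

#' @export
print.experience_store <- function(x, ...) {
  cat(sprintf("experience store: %d unique tuples (sigma = %g, lambda_r = %g, lambda_i = %g, %s-normalized strength)\n",
              x$m, x$sigma, x$lambda_r, x$lambda_i, x$strength_norm))
  invisible(x)
}

#' @export
print.replay_event <- function(x, ...) {
  cat(sprintf("replay event (%s%s): %d batches x %d, %d reactivations%s\n",
              x$mode, if (is.na(x$beta)) "" else sprintf(", beta = %g", x$beta),
              length(x$batches), x$batch_size, length(x$sequence),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
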