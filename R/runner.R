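#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform random action; otherwise the
#' argmax of the action values, ties broken uniformly at random.
#'
#' @param q numeric vector of action values.
#' @param epsilon exploration rate in `[0, 1]`.
#' @return selected action index.
#' @export
epsilon_greedy <- function(q, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  n <- length(q)
  if (epsilon > 0 && runif(1) < epsilon) return(sample.int(n, 1L))
  cand <- which(q == max(q))
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

#' Experiment configuration
#'
#' Bundles every knob of a training study. Defaults follow the study
#' conditions: epsilon = 0.1, gamma = 0.9, 500 trials, 50 runs, 600-step
#' timeout, k = 5 neighbors, batch size 32, soft-update alpha = 0.01.
#'
#' @param algorithm `"ec"` (one-shot / episodic control), `"dqn"`
#'   (replay learning) or `"online_dqn"` (online learning, no memory).
#' @param maze_level tunnel-maze level 1..4 (ignored when `maze` given).
#' @param maze optional explicit `tunnel_maze`.
#' @param replay_mode `"per_step_random"` (classic replay learning),
#'   `"trial_end_random"` or `"trial_end_sequential"` (SFMA). Only
#'   meaningful for `algorithm = "dqn"`.
#' @param trials,runs learning trials per run and independent runs.
#' @param epsilon,gamma exploration rate and discount factor.
#' @param beta inverse temperature of sequential replay.
#' @param n_batches replay batches per trial-end event.
#' @param batch_size experiences per batch / mini-batch size.
#' @param schedule_variant per-step update schedule (see
#'   [update_schedule()]).
#' @param approximator `"tabular"`, `"linear"` or `"mlp"`.
#' @param hidden MLP hidden widths.
#' @param obs_dim,proj_dim,adjacent_cor observation-codec parameters.
#' @param k,capacity episodic-control neighbor count and memory capacity.
#' @param lr,optimizer,alpha approximator learning rate, optimizer and
#'   soft-update factor.
#' @param sigma,lambda_r,lambda_i,strength_norm sequential-replay
#'   parameters (see [experience_store()]).
#' @param replay_sample_mode `"reverse"` or `"forward"` sequence
#'   direction for sequential replay.
#' @param master_seed master seed; every per-run stream derives from it.
#' @param record_replay collect per-event replay diagnostics (similarity,
#'   sequence lengths)?
#' @param timeout trial step budget (default: the maze's).
#' @return object of class `run_config`.
#' @export
run_config <- function(algorithm = c("ec", "dqn", "online_dqn"),
                       maze_level = 4L, maze = NULL,
                       replay_mode = c("per_step_random", "trial_end_random",
                                       "trial_end_sequential"),
                       trials = 500L, runs = 50L,
                       epsilon = 0.1, gamma = 0.9,
                       beta = 5, n_batches = 10L, batch_size = 32L,
                       schedule_variant = "default",
                       approximator = c("linear", "tabular", "mlp"),
                       hidden = c(64L, 64L),
                       obs_dim = 64L, proj_dim = 256L, adjacent_cor = 0.8,
                       k = 5L, capacity = 50000L,
                       lr = NULL, optimizer = NULL, alpha = 0.01,
                       sigma = 1, lambda_r = 1, lambda_i = 0.99,
                       strength_norm = "max",
                       replay_sample_mode = "reverse",
                       master_seed = 1L, record_replay = FALSE,
                       timeout = NULL) {
  algorithm <- match.arg(algorithm)
  replay_mode <- match.arg(replay_mode)
  approximator <- match.arg(approximator)
  schedule_variant <- match.arg(schedule_variant,
                                c("default", "batch_size_one", "sparse_sampling"))
  if (algorithm == "online_dqn" && replay_mode != "per_step_random")
    stop("configuration error: online learning has no replay mode")
  if (algorithm != "dqn" && schedule_variant != "default")
    stop("configuration error: update-schedule variants apply to replay learning only")
  structure(list(
    algorithm = algorithm, maze_level = as.integer(maze_level), maze = maze,
    replay_mode = replay_mode, trials = as.integer(trials),
    runs = as.integer(runs), epsilon = epsilon, gamma = gamma, beta = beta,
    n_batches = as.integer(n_batches), batch_size = as.integer(batch_size),
    schedule_variant = schedule_variant, approximator = approximator,
    hidden = as.integer(hidden), obs_dim = as.integer(obs_dim),
    proj_dim = as.integer(proj_dim), adjacent_cor = adjacent_cor,
    k = as.integer(k), capacity = as.integer(capacity), lr = lr,
    optimizer = optimizer, alpha = alpha, sigma = sigma,
    lambda_r = lambda_r, lambda_i = lambda_i, strength_norm = strength_norm,
    replay_sample_mode = replay_sample_mode,
    master_seed = as.integer(master_seed),
    record_replay = isTRUE(record_replay), timeout = timeout
  ), class = "run_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(run_config, doc)
}

#' Train agents
#'
#' Executes `runs` independent training runs of the configured algorithm:
#' trials start from the fixed start state (facing north), actions are
#' epsilon-greedy on the agent's current action values, trials end on
#' reaching the goal or after the step timeout, and learning follows the
#' algorithm -- episodic control updates its table at every trial end;
#' replay learning draws mini-batches from its memory per step (or
#' replays a trial-end event); online learning takes one gradient step
#' per transition and stores nothing. Everything is reproducible from
#' `master_seed`.
#'
#' @param config a [run_config()].
#' @return object of class `run_result_set`: the maze, config, and one
#'   result per run with per-trial escape latencies, the set of visited
#'   states, the trained agent's greedy action-value table and optional
#'   replay diagnostics.
#' @export
run_training <- function(config) {
  maze <- if (!is.null(config$maze)) config$maze else build_tunnel_maze(config$maze_level)
  if (!is.null(config$timeout)) maze$timeout <- as.integer(config$timeout)
  tables <- transition_tables(maze)
  codec <- state_codec(maze, dim = config$obs_dim, seed = config$master_seed)
  proj <- projection_matrix(config$proj_dim, config$obs_dim,
                            seed = config$master_seed + 1L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$runs)
  results <- vector("list", config$runs)
  for (i in seq_len(config$runs)) {
    set.seed(seeds[i])
    results[[i]] <- if (config$algorithm == "ec")
      .run_one_ec(config, maze, tables, codec, proj, seeds[i])
    else
      .run_one_dqn(config, maze, tables, codec, seeds[i])
    results[[i]]$seed <- seeds[i]
  }
  structure(list(maze = maze, config = config, results = results),
            class = "run_result_set")
}

.start_state <- function(maze) state_index(maze$start, 1L)  # facing north

.run_one_ec <- function(config, maze, tables, codec, proj, seed) {
  mem <- ec_memory(codec, proj, k = config$k, gamma = config$gamma,
                   capacity = config$capacity)
  S <- maze$n_states
  timeout <- maze$timeout
  visited <- logical(S)
  latencies <- integer(config$trials)
  s0 <- .start_state(maze)
  nxt <- tables$next_state; rew <- tables$reward; term <- tables$terminal
  eps <- config$epsilon
  tr_s <- integer(timeout); tr_a <- integer(timeout)
  tr_s2 <- integer(timeout); tr_r <- numeric(timeout)
  for (trial in seq_len(config$trials)) {
    s <- s0
    visited[s] <- TRUE
    n <- 0L
    repeat {
      q <- ec_q_lookup(mem, s)
      a <- epsilon_greedy(q, eps)
      n <- n + 1L
      tr_s[n] <- s; tr_a[n] <- a
      s2 <- nxt[s, a]
      tr_s2[n] <- s2; tr_r[n] <- rew[s, a]
      visited[s2] <- TRUE
      s <- s2
      if (term[tr_s[n], a] || n >= timeout) break
    }
    idx <- seq_len(n)
    ec_update(mem, data.frame(s = tr_s[idx], a = tr_a[idx], s2 = tr_s2[idx],
                              r = tr_r[idx],
                              terminal = c(rep(FALSE, n - 1L), term[tr_s[n], tr_a[n]])))
    latencies[trial] <- n
  }
  q_final <- t(vapply(seq_len(S), function(s) ec_q_lookup(mem, s), numeric(6)))
  list(latencies = latencies, visited = which(visited), q = q_final,
       algorithm = "ec", replay = NULL)
}

.run_one_dqn <- function(config, maze, tables, codec, seed) {
  tabular <- config$approximator == "tabular"
  obs <- if (tabular) NULL else observation_matrix(codec)
  net <- q_approximator(config$approximator,
                        input_dim = if (tabular) maze$n_states else config$obs_dim,
                        hidden = config$hidden, optimizer = config$optimizer,
                        lr = config$lr, seed = seed, obs = obs)
  online <- config$algorithm == "online_dqn"
  per_step <- config$replay_mode == "per_step_random"
  buf <- if (!online && per_step) replay_buffer(config$capacity)
  store <- if (!online && !per_step)
    experience_store(maze, sigma = config$sigma, lambda_r = config$lambda_r,
                     lambda_i = config$lambda_i,
                     strength_norm = config$strength_norm)
  sched <- update_schedule(config$schedule_variant, config$batch_size)
  S <- maze$n_states
  timeout <- maze$timeout
  visited <- logical(S)
  latencies <- integer(config$trials)
  replay_diag <- if (config$record_replay) vector("list", config$trials)
  s0 <- .start_state(maze)
  nxt <- tables$next_state; rew <- tables$reward; term <- tables$terminal
  eps <- config$epsilon; gamma <- config$gamma; alpha <- config$alpha
  steps_total <- 0L
  tr_s <- integer(timeout); tr_a <- integer(timeout)
  tr_s2 <- integer(timeout); tr_r <- numeric(timeout); tr_t <- logical(timeout)
  for (trial in seq_len(config$trials)) {
    s <- s0
    visited[s] <- TRUE
    n <- 0L
    repeat {
      q <- .q_row(net, s)
      a <- epsilon_greedy(q, eps)
      n <- n + 1L
      s2 <- nxt[s, a]; r <- rew[s, a]; tl <- term[s, a]
      tr_s[n] <- s; tr_a[n] <- a; tr_s2[n] <- s2; tr_r[n] <- r; tr_t[n] <- tl
      visited[s2] <- TRUE
      if (online) {
        online_update(net, list(s = s, a = a, s2 = s2, r = r, terminal = tl),
                      gamma = gamma)
        soft_update(net, alpha)
      } else if (per_step) {
        buffer_push(buf, s, a, s2, r, tl)
        steps_total <- steps_total + 1L
        if (steps_total %% sched$every == 0L && buf$size >= sched$batch_size) {
          replay_update(net, buf, sched$batch_size, gamma = gamma)
          soft_update(net, alpha)
        }
      }
      s <- s2
      if (tl || n >= timeout) break
    }
    latencies[trial] <- n
    if (!online && !per_step) {
      idx <- seq_len(n)
      store_record(store, tr_s[idx], tr_a[idx], tr_s2[idx], tr_r[idx], tr_t[idx])
      event <- if (config$replay_mode == "trial_end_sequential")
        generate_replay_event(store, config$n_batches, config$batch_size,
                              beta = config$beta, mode = config$replay_sample_mode,
                              anchor = s)
      else
        random_replay_event(store, config$n_batches, config$batch_size)
      for (batch in event$batches) {
        # offline trial-end replay bootstraps from the online values so
        # that sequenced updates can chain within one event (both the
        # sequential and the random comparator use this regime)
        tgt <- td_targets(net, store$r_sum[batch] / store$n[batch],
                          store$s2[batch], store$terminal[batch], gamma = gamma,
                          use_target = FALSE)
        bk <- .q_backward(net, .net_input(net, store$s[batch]), store$a[batch], tgt)
        .q_apply_grads(net, bk$grads)
        soft_update(net, alpha)
      }
      if (config$record_replay)
        replay_diag[[trial]] <- list(
          similarity = event_similarity(event),
          seq_lengths = replay_sequence_lengths(store, event),
          truncated = event$truncated)
    }
  }
  q_final <- q_values(net, seq_len(S))
  list(latencies = latencies, visited = which(visited), q = q_final,
       algorithm = config$algorithm, replay = replay_diag,
       n_updates = net$n_updates)
}

#' Greedy test trial
#'
#' Places a trained agent in `start` (default: the maze's start state,
#' facing north) and rolls out its greedy policy (epsilon = 0, ties
#' broken uniformly at random from a dedicated seeded stream) for at most
#' the trial timeout.
#'
#' @param maze a `tunnel_maze`.
#' @param agent a per-run result from [run_training()] (or any
#'   `n_states x 6` action-value matrix).
#' @param start starting state index (default: maze start, facing north).
#' @param seed seed of the tie-breaking stream.
#' @return list with `states` (ordered visited state indices, including
#'   the start), `latency` (steps taken) and `timeout` flag.
#' @export
test_trial <- function(maze, agent, start = NULL, seed = 1L) {
  q <- if (is.matrix(agent)) agent else agent$q
  if (is.null(start)) start <- .start_state(maze)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  tables <- attr(maze, "cached_tables")
  if (is.null(tables)) tables <- transition_tables(maze)
  .greedy_rollout(maze, tables, q, start)
}

.greedy_rollout <- function(maze, tables, q, start) {
  timeout <- maze$timeout
  states <- integer(timeout + 1L)
  states[1L] <- s <- start
  n <- 0L
  goal_hit <- (start - 1L) %/% 4L + 1L == maze$goal
  while (!goal_hit && n < timeout) {
    row <- q[s, ]
    cand <- which(row == max(row))
    a <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    s <- tables$next_state[s, a]
    n <- n + 1L
    states[n + 1L] <- s
    if (tables$terminal[states[n], a]) goal_hit <- TRUE
  }
  list(states = states[seq_len(n + 1L)], latency = n, timeout = !goal_hit)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config: %s, maze level %d, %d runs x %d trials (eps = %g, gamma = %g, seed = %d)\n",
              x$algorithm, x$maze_level, x$runs, x$trials, x$epsilon,
              x$gamma, x$master_seed))
  if (x$algorithm == "dqn")
    cat(sprintf("  replay: %s (%s schedule), approximator %s\n",
                x$replay_mode, x$schedule_variant, x$approximator))
  invisible(x)
}

#' @export
print.run_result_set <- function(x, ...) {
  lat <- latency_matrix(x)
  cat(sprintf("%s: %d runs x %d trials on maze level %s\n",
              x$config$algorithm, ncol(lat), nrow(lat), x$maze$level))
  cat(sprintf("  mean latency: first trial %.1f, last trial %.1f\n",
              mean(lat[1, ]), mean(lat[nrow(lat), ])))
  invisible(x)
}
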