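#' Per-trial escape-latency matrix
#'
#' @param results a `run_result_set`.
#' @return numeric matrix, trials x runs.
#' @export
latency_matrix <- function(results) {
  vapply(results$results, function(r) as.numeric(r$latencies),
         numeric(results$config$trials))
}

#' Learning curve
#'
#' Trialwise mean and standard deviation of the escape latency across
#' runs.
#'
#' @param results a `run_result_set` (or a trials x runs latency matrix).
#' @return data.frame with columns `trial`, `mean`, `sd`.
#' @export
learning_curve <- function(results) {
  lat <- if (is.matrix(results)) results else latency_matrix(results)
  sds <- if (ncol(lat) > 1L) apply(lat, 1L, sd) else rep(0, nrow(lat))
  data.frame(trial = seq_len(nrow(lat)),
             mean = rowMeans(lat),
             sd = sds)
}

#' Learning-speed summary (area under the learning curve)
#'
#' Per-run sum of escape latencies over the first `window` trials; the
#' scalar learning-speed statistic (smaller = faster learning) used for
#' rank tests across runs.
#'
#' @param results a `run_result_set` or latency matrix.
#' @param window number of leading trials (default 100).
#' @return numeric vector, one AUC per run.
#' @export
learning_auc <- function(results, window = 100L) {
  lat <- if (is.matrix(results)) results else latency_matrix(results)
  window <- min(window, nrow(lat))
  colSums(lat[seq_len(window), , drop = FALSE])
}

#' Classify a test trajectory's route
#'
#' `"timeout"` if the trial timed out; `"tunnel"` if any visited node is
#' a tunnel corridor node; otherwise `"open"`.
#'
#' @param trajectory a [test_trial()] result.
#' @param maze the `tunnel_maze`.
#' @return one of `"tunnel"`, `"open"`, `"timeout"`.
#' @export
route_classification <- function(trajectory, maze) {
  if (isTRUE(trajectory$timeout)) return("timeout")
  nodes <- (trajectory$states - 1L) %/% 4L + 1L
  if (any(nodes %in% maze$tunnel)) "tunnel" else "open"
}

#' Tunnel-route fraction of a trained cohort
#'
#' Runs one greedy test trial per trained agent from the fixed start and
#' reports the proportion (in percent) classified as the tunnel route.
#'
#' @param results a `run_result_set`.
#' @param seed tie-breaking seed base for the test trials.
#' @return list with `percent`, per-agent `routes`, and `n`.
#' @export
tunnel_route_fraction <- function(results, seed = 1L) {
  maze <- results$maze
  tables <- transition_tables(maze)
  attr(maze, "cached_tables") <- tables
  routes <- vapply(seq_along(results$results), function(i) {
    tt <- test_trial(maze, results$results[[i]], seed = seed + i)
    route_classification(tt, maze)
  }, character(1))
  list(percent = 100 * mean(routes == "tunnel"), routes = routes,
       n = length(routes))
}

#' Solution-state analysis
#'
#' For every state visited during training, runs a greedy test trial from
#' that state and labels it a *solution state* iff the agent reaches the
#' goal within the timeout: the per-state record of how far the reward
#' information propagated.
#'
#' @param maze the `tunnel_maze`.
#' @param agent a per-run result of [run_training()] (or a Q matrix).
#' @param visited integer vector of visited state indices.
#' @param seed tie-breaking seed for the greedy rollouts.
#' @return list with counts `never_visited`, `visited_non_solution`,
#'   `solution` (summing to the state count), fractions of the total
#'   state count, `solution_to_visited` ratio and the per-state `label`
#'   factor.
#' @export
solution_state_analysis <- function(maze, agent, visited, seed = 1L) {
  q <- if (is.matrix(agent)) agent else agent$q
  S <- maze$n_states
  tables <- transition_tables(maze)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  label <- rep("never_visited", S)
  for (s in visited) {
    tt <- .greedy_rollout(maze, tables, q, s)
    label[s] <- if (tt$timeout) "visited_non_solution" else "solution"
  }
  label <- factor(label, levels = c("never_visited", "visited_non_solution",
                                    "solution"))
  counts <- table(label)
  n_vis <- length(visited)
  list(never_visited = unname(counts[1]),
       visited_non_solution = unname(counts[2]),
       solution = unname(counts[3]),
       fractions = as.numeric(counts) / S,
       visited_fraction = n_vis / S,
       solution_to_visited = if (n_vis > 0) unname(counts[3]) / n_vis else NA_real_,
       label = label)
}

#' Cohort solution-state summary
#'
#' Applies [solution_state_analysis()] to every run of a result set.
#'
#' @param results a `run_result_set`.
#' @param seed tie-breaking seed base.
#' @return data.frame with one row per run: visited fraction, solution
#'   fraction (of all states) and solution-to-visited ratio.
#' @export
solution_state_summary <- function(results, seed = 1L) {
  maze <- results$maze
  out <- lapply(seq_along(results$results), function(i) {
    r <- results$results[[i]]
    an <- solution_state_analysis(maze, r, r$visited, seed = seed + i)
    data.frame(run = i, visited_fraction = an$visited_fraction,
               solution_fraction = an$fractions[3],
               solution_to_visited = an$solution_to_visited)
  })
  do.call(rbind, out)
}

#' Replay batch similarity
#'
#' Proportion of shared experience tuples between two equally sized
#' batches. By default batches are deduplicated before intersecting (a
#' tuple appearing twice in one batch counts once); `multiset = TRUE`
#' intersects with multiplicities instead.
#'
#' @param a,b integer vectors of experience ids (equal length).
#' @param multiset count shared tuples with multiplicities?
#' @return similarity in `[0, 1]`.
#' @export
batch_similarity <- function(a, b, multiset = FALSE) {
  if (length(a) != length(b)) stop("mismatched batch sizes")
  if (!multiset) return(length(intersect(unique(a), unique(b))) / length(a))
  ta <- table(a); tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  sum(pmin(ta[shared], tb[shared])) / length(a)
}

#' Event-level replay similarity
#'
#' Mean [batch_similarity()] over all unordered batch pairs of a replay
#' event.
#'
#' @param event a `replay_event`.
#' @param multiset see [batch_similarity()].
#' @return similarity in `[0, 1]` (`NA` for events with fewer than two
#'   batches).
#' @export
event_similarity <- function(event, multiset = FALSE) {
  b <- event$batches
  nb <- length(b)
  if (nb < 2L) return(NA_real_)
  sims <- numeric(0)
  for (i in seq_len(nb - 1L))
    for (j in (i + 1L):nb)
      sims <- c(sims, batch_similarity(b[[i]], b[[j]], multiset))
  mean(sims)
}

#' Study-level replay similarity
#'
#' Mean event-level similarity over all replay events of the first
#' `window` trials across all runs (requires `record_replay = TRUE` in
#' the configuration).
#'
#' @param results a `run_result_set` from a trial-end replay study.
#' @param window leading-trials window (default 200).
#' @return mean similarity.
#' @export
study_replay_similarity <- function(results, window = 200L) {
  sims <- unlist(lapply(results$results, function(r) {
    if (is.null(r$replay)) return(NULL)
    keep <- seq_len(min(window, length(r$replay)))
    vapply(r$replay[keep], function(ev)
      if (is.null(ev)) NA_real_ else ev$similarity, numeric(1))
  }))
  mean(sims, na.rm = TRUE)
}

#' Mean replay sequence length of a study
#'
#' @param results a `run_result_set` with recorded replay diagnostics.
#' @param window leading-trials window.
#' @return mean within-event sequence length.
#' @export
study_sequence_length <- function(results, window = 200L) {
  lens <- unlist(lapply(results$results, function(r) {
    if (is.null(r$replay)) return(NULL)
    keep <- seq_len(min(window, length(r$replay)))
    unlist(lapply(r$replay[keep], function(ev) ev$seq_lengths))
  }))
  mean(lens)
}

#' Relative performance of sequential over random replay
#'
#' Inverse ratio of average escape latencies: mean latency under random
#' replay divided by mean latency under sequential replay; values above 1
#' favor sequential replay.
#'
#' @param seq_results,rand_results `run_result_set`s (or latency
#'   matrices) of the sequential and random replay conditions.
#' @return the latency ratio.
#' @export
relative_performance <- function(seq_results, rand_results) {
  ms <- mean(if (is.matrix(seq_results)) seq_results else latency_matrix(seq_results))
  mr <- mean(if (is.matrix(rand_results)) rand_results else latency_matrix(rand_results))
  mr / ms
}

#' Write study results to disk
#'
#' Per-run CSVs of (trial, latency), a JSON summary, and solution-state
#' maps keyed by (node, heading).
#'
#' @param results a `run_result_set`.
#' @param dir output directory (created if needed).
#' @export
write_run_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lat <- latency_matrix(results)
  for (i in seq_len(ncol(lat)))
    write.csv(data.frame(trial = seq_len(nrow(lat)), latency = lat[, i]),
              file.path(dir, sprintf("run_%03d_latency.csv", i)),
              row.names = FALSE)
  lc <- learning_curve(results)
  summary <- list(algorithm = results$config$algorithm,
                  maze_level = results$maze$level,
                  runs = ncol(lat), trials = nrow(lat),
                  mean_final_latency = mean(lat[nrow(lat), ]),
                  auc = mean(learning_auc(results)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(lc, file.path(dir, "learning_curve.csv"), row.names = FALSE)
  invisible(dir)
}
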