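# shared fixtures, built in code

fixture_maze1 <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_tunnel_maze(1)
    m
  }
})

fixture_codec1 <- local({
  cd <- NULL
  function() {
    if (is.null(cd)) cd <<- state_codec(fixture_maze1(), dim = 64L, seed = 101L)
    cd
  }
})

# 1 x n east-west corridor maze (no tunnel; validation off)
corridor_maze <- function(n = 3L, timeout = 600L) {
  nodes <- cbind(x = 0:(n - 1L), y = 0L)
  edges <- cbind(1:(n - 1L), 2:n)
  tunnel_maze(nodes, edges, start = 1L, goal = n, tunnel = integer(0),
              timeout = timeout, validate = FALSE)
}

# random-policy episode traces on a maze, for oracle tests
random_traces <- function(maze, n_episodes, max_steps = 60L, seed = 1L) {
  tab <- transition_tables(maze)
  set.seed(seed)
  s0 <- (maze$start - 1L) * 4L + 1L
  traces <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    s <- s0
    ss <- integer(0); aa <- integer(0); s2s <- integer(0); rr <- numeric(0)
    tt <- logical(0)
    for (i in seq_len(max_steps)) {
      a <- sample.int(6L, 1L)
      ss <- c(ss, s); aa <- c(aa, a)
      s2s <- c(s2s, tab$next_state[s, a]); rr <- c(rr, tab$reward[s, a])
      tt <- c(tt, tab$terminal[s, a])
      s <- tab$next_state[s, a]
      if (tab$terminal[ss[i], a]) break
    }
    traces[[ep]] <- as_episode_trace(ss, aa, s2s, rr, tt)
  }
  traces
}
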