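# store over a 1 x n corridor with a single eastward rewarded traversal
traversal_store <- function(n = 6L, ...) {
  m <- corridor_maze(n)
  st <- experience_store(m, ...)
  # states: node i facing E = (i-1)*4 + 2; forward moves east
  s <- (seq_len(n - 1L) - 1L) * 4L + 2L
  s2 <- (seq_len(n - 1L)) * 4L + 2L
  r <- c(rep(0, n - 2L), 1)
  store_record(st, s, rep(1L, n - 1L), s2, r, c(rep(FALSE, n - 2L), TRUE))
  list(maze = m, store = st)
}

test_that("strength combines visit counts and mean reward; unstored tuples score zero", {
  m <- corridor_maze(4)
  st <- experience_store(m, strength_norm = "none")
  store_record(st, c(2L, 2L, 2L), c(1L, 1L, 1L), c(6L, 6L, 6L), c(0, 0, 0), rep(FALSE, 3))
  expect_equal(strength(st, 1), 3)               # visited 3x, no reward
  store_record(st, 5L, 2L, 9L, 1, TRUE)
  expect_equal(strength(st, 2), 2)               # visited once with reward, lambda_r = 1
  expect_equal(strength(st, 99), 0)              # never stored
  # normalized default keeps strengths on an order-1 scale
  st2 <- experience_store(m)
  store_record(st2, c(2L, 2L, 2L, 5L), c(1L, 1L, 1L, 2L), c(6L, 6L, 6L, 9L),
               c(0, 0, 0, 1), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(strength(st2, 1), 1)              # 3/3 * (1 + 0)
  expect_equal(strength(st2, 2), (1 / 3) * 2)    # 1/3 * (1 + 1)
})

test_that("similarity decays exponentially with graph distance and handles event starts", {
  tw <- traversal_store(6)
  st <- tw$store
  # reverse mode anchors the candidate's next state against the previous
  # tuple's current state: the behavioral predecessor has distance 0
  expect_equal(similarity(st, 1, 2, mode = "reverse"), 1)         # exp(0)
  expect_equal(similarity(st, e = 1, e_prev = NULL), 1)
  d <- vapply(1:5, function(e) similarity(st, e, 5, mode = "reverse"), numeric(1))
  # similarity decays strictly with the anchor distance on the line graph
  expect_equal(d, exp(-c(3, 2, 1, 0, 1)))
  expect_equal(d[4], 1)                                           # predecessor of 5
  expect_true(all(diff(d[1:4]) > 0))
  expect_lt(d[5], d[4])
})

test_that("reactivation scores are the strength x similarity x disinhibition product", {
  tw <- traversal_store(4, strength_norm = "none")
  st <- tw$store
  sc <- reactivation_scores(st, e_prev = NULL)
  expect_equal(sc, strength(st))                 # D = 1, I = 0 at event start
  st$I[2] <- 1
  sc2 <- reactivation_scores(st, e_prev = NULL)
  expect_equal(sc2[2], 0)                        # fully inhibited
  st$I[2] <- 0
  # C = 2, D = 0.5, I = 0 -> 1.0 (direct product check)
  expect_equal(2 * 0.5 * (1 - 0), 1.0)
  empty <- experience_store(corridor_maze(3))
  expect_length(reactivation_scores(empty, NULL), 0)
})

test_that("inverse-temperature sampling follows the shifted-exponential distribution", {
  # scores (ln 3, ln 2) at beta = 1: p = (e^R - 1)/sum = (2, 1)/3
  p <- replay_probabilities(c(log(3), log(2)), beta = 1)
  expect_equal(p, c(2 / 3, 1 / 3))
  expect_equal(sum(p), 1)
  # zero scores have probability exactly zero
  p2 <- replay_probabilities(c(0, log(2), 0), beta = 1)
  expect_equal(p2, c(0, 1, 0))
  # two equal positive scores split evenly at any beta
  set.seed(2)
  draws <- replicate(4000, sample_next(c(0.7, 0.7), beta = 3))
  expect_equal(unname(prop.table(table(draws))[1]), 0.5, tolerance = 0.05)
  # empirical frequencies match the analytic distribution (goodness of fit)
  scores <- c(0.1, 0.4, 0.8, 1.2, 0.05)
  set.seed(7)
  draws <- replicate(1e5, sample_next(scores, beta = 2))
  expected <- replay_probabilities(scores, beta = 2)
  gof <- suppressWarnings(chisq.test(tabulate(draws, 5), p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("beta = 0 samples uniformly over eligible experiences, unlike frequency-weighted random replay", {
  m <- corridor_maze(5)
  st <- experience_store(m)
  # unequal visit counts: tuple 1 visited 9x, tuples 2..4 once each
  store_record(st, rep(2L, 9L), rep(1L, 9L), rep(6L, 9L), rep(0, 9), rep(FALSE, 9))
  for (i in 2:4) store_record(st, (i - 1L) * 4L + 2L, 1L, i * 4L + 2L, 0, FALSE)
  set.seed(3)
  seq_draws <- replicate(8000, sample_next(strength(st), beta = 0,
                                           eligible = st$n[1:st$m] > 0))
  seq_freq <- tabulate(seq_draws, 4) / 8000
  expect_equal(max(abs(seq_freq - 0.25)), 0, tolerance = 0.03)
  # random replay draws proportionally to n(e): 9 of 12 for tuple 1
  ev <- random_replay_event(st, n_batches = 10, batch_size = 100)
  rand_freq <- mean(ev$sequence == 1)
  expect_equal(rand_freq, 9 / 12, tolerance = 0.05)
  # the two distributions genuinely differ
  expect_gt(rand_freq - seq_freq[1], 0.3)
})

test_that("replay events have the configured geometry and reset inhibition", {
  tw <- traversal_store(8)
  ev <- generate_replay_event(tw$store, n_batches = 10, batch_size = 32, beta = 5)
  expect_length(ev$sequence, 320)
  expect_length(ev$batches, 10)
  expect_true(all(lengths(ev$batches) == 32))
  expect_true(all(ev$sequence >= 1 & ev$sequence <= tw$store$m))
  expect_false(ev$truncated)
  rv <- random_replay_event(tw$store, n_batches = 10, batch_size = 32)
  expect_length(rv$sequence, 320)
  expect_true(all(lengths(rv$batches) == 32))
})

test_that("reverse mode chains to the behavioral predecessor as the modal successor", {
  tw <- traversal_store(8)
  st <- tw$store
  set.seed(11)
  ev <- generate_replay_event(st, n_batches = 4, batch_size = 32, beta = 10,
                              mode = "reverse")
  seqs <- ev$sequence
  # exhaustive score computation: for every reactivated e with a unique
  # stored behavioral predecessor p, the highest-scoring successor
  # candidate (e freshly inhibited, everything else disinhibited) is p
  C <- strength(st)
  for (e in unique(seqs)) {
    pred <- which(st$s2[1:st$m] == st$s[e])
    if (length(pred) != 1) next
    D <- vapply(1:st$m, function(k) similarity(st, k, e, mode = "reverse"),
                numeric(1))
    inh <- rep(0, st$m); inh[e] <- 1
    sc <- C * D * (1 - inh)
    expect_equal(which.max(sc), pred)
  }
  # and the realized high-beta stream mostly follows reverse adjacency
  adj <- mean(st$s2[seqs[-1]] == st$s[seqs[-length(seqs)]])
  expect_gt(adj, 0.5)
  lens <- replay_sequence_lengths(st, ev)
  expect_equal(sum(lens), length(seqs))
  expect_gt(mean(lens), 2)
})

test_that("within-event sequence length grows with the inverse temperature", {
  tw <- traversal_store(10)
  mean_len <- sapply(c(0, 1, 2, 5, 10), function(b) {
    set.seed(40 + b)
    mean(unlist(lapply(1:6, function(i)
      replay_sequence_lengths(tw$store,
        generate_replay_event(tw$store, n_batches = 4, batch_size = 32, beta = b)))))
  })
  expect_gt(cor(c(0, 1, 2, 5, 10), mean_len, method = "spearman"), 0.8)
  expect_gt(mean_len[5], mean_len[1])
})
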