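test_that("parametric family emits the documented layout, counted by enumeration", {
  m1 <- fixture_maze1()
  # brute-force: count distinct grid coordinates of the emitted layout
  expect_equal(nrow(unique(m1$nodes)), m1$n_nodes)
  # chamber 5x3 plus a 1-wide corridor rising 2, running east, descending 2
  expect_equal(m1$n_nodes, 5 * 3 + (2 * 2 + 5 - 2))
  expect_equal(m1$n_states, 4 * m1$n_nodes)
  # level-2 chamber grows 1 east, 1 west, 2 south relative to level-1's 5x3
  m2 <- build_tunnel_maze(2)
  chamber_dims <- function(m) {
    ch <- m$nodes[-m$tunnel, , drop = FALSE]
    c(width = max(ch[, 1]) + 1, height = max(ch[, 2]) + 1)
  }
  expect_equal(unname(chamber_dims(m1)), c(5, 3))
  expect_equal(unname(chamber_dims(m2)), c(7, 5))
  # tunnel elongates by 1 unit north-south per level (rise above the chamber)
  rise_of <- function(m) max(m$nodes[, 2]) - (chamber_dims(m)["height"] - 1)
  expect_equal(unname(rise_of(m2)), unname(rise_of(m1)) + 1)
  for (lv in 1:4) {
    m <- build_tunnel_maze(lv)
    expect_true(m$start %in% seq_len(m$n_nodes))
    expect_true(m$goal %in% seq_len(m$n_nodes))
    expect_true(all(m$tunnel %in% seq_len(m$n_nodes)))
  }
})

test_that("maze invariants hold at every level", {
  for (lv in 1:4) {
    m <- build_tunnel_maze(lv)
    expect_true(igraph::is_connected(m$graph))
    expect_true(m$start != m$goal)
    expect_true(all(igraph::degree(m$graph)[m$tunnel] <= 2))
    d_open <- shortest_path_length(m, m$start, m$goal)
    d_via <- min(sapply(m$tunnel, function(t)
      shortest_path_length(m, m$start, t) + shortest_path_length(m, t, m$goal)))
    expect_gt(d_via, d_open)
  }
})

test_that("invalid configurations raise configuration errors", {
  expect_error(build_tunnel_maze(5), "level")
  expect_error(build_tunnel_maze(1, chamber_width = 1), "configuration error")
  # degenerate explicit layout: disconnected graph
  expect_error(
    tunnel_maze(cbind(c(0, 1, 5), c(0, 0, 5)), rbind(c(1, 2)), 1, 2, integer(0)),
    "not connected")
})

test_that("rotations change heading only and are mutually inverse", {
  m <- fixture_maze1()
  st <- maze_states(m)
  for (s in c(1, 17, 40)) {
    os <- oriented_state(m, st$node[s], st$heading[s])
    cw <- step_maze(m, os, "rotate_cw")
    expect_equal(cw$next_state$node, os$node)
    expect_equal(cw$reward, 0)
    back <- step_maze(m, cw$next_state, "rotate_ccw")
    expect_identical(back$next_state$state, os$state)
  }
  os <- oriented_state(m, m$start, "N")
  expect_equal(step_maze(m, os, "rotate_cw")$next_state$heading, "E")
})

test_that("blocked translations are no-ops and goal entry is rewarded terminal", {
  m <- fixture_maze1()
  # start is the chamber NW corner: no west neighbor, heading W forward blocked
  os <- oriented_state(m, m$start, "W")
  tr <- step_maze(m, os, "forward")
  expect_identical(tr$next_state$state, os$state)
  expect_equal(tr$reward, 0)
  expect_false(tr$terminal)
  # step onto the goal from its southern neighbor
  gx <- m$nodes[m$goal, 1]; gy <- m$nodes[m$goal, 2]
  below <- which(m$nodes[, 1] == gx & m$nodes[, 2] == gy - 1L)
  tr2 <- step_maze(m, oriented_state(m, below, "N"), "forward")
  expect_equal(tr2$next_state$node, m$goal)
  expect_equal(tr2$reward, 1.0)
  expect_true(tr2$terminal)
})

test_that("step is pure and closed over the 6-action state space", {
  m <- fixture_maze1()
  st <- maze_states(m)
  set.seed(4)
  for (s in sample(nrow(st), 25)) {
    os <- oriented_state(m, st$node[s], st$heading[s])
    for (a in 1:6) {
      t1 <- step_maze(m, os, a)
      t2 <- step_maze(m, os, a)
      expect_identical(t1, t2)
      expect_true(t1$next_state$node >= 1 && t1$next_state$node <= m$n_nodes)
      expect_true(t1$next_state$heading %in% c("N", "E", "S", "W"))
    }
  }
  expect_error(step_maze(m, oriented_state(m, 1, "N"), "fly"), "unknown action")
  expect_error(oriented_state(m, m$n_nodes + 1, "N"), "invalid node")
})

test_that("shortest path lengths match brute-force expectations", {
  m <- fixture_maze1()
  expect_equal(shortest_path_length(m, m$start, m$start), 0)
  line <- corridor_maze(3)
  expect_equal(shortest_path_length(line, 1, 3), 2)
  # restriction to a subset that cannot connect gives no path, not an error
  expect_equal(shortest_path_length(m, m$start, m$goal,
                                    restrict_to = c(m$start, m$goal)), Inf)
  # restriction to the full node set changes nothing
  expect_equal(shortest_path_length(m, m$start, m$goal,
                                    restrict_to = seq_len(m$n_nodes)),
               shortest_path_length(m, m$start, m$goal))
})

test_that("a random walker reaches the goal within the timeout at every level", {
  for (lv in 1:4) {
    m <- build_tunnel_maze(lv)
    tab <- transition_tables(m)
    set.seed(100 + lv)
    hits <- 0
    for (w in 1:25) {
      s <- (m$start - 1L) * 4L + 1L
      for (i in seq_len(m$timeout)) {
        a <- sample.int(6L, 1L)
        done <- tab$terminal[s, a]
        s <- tab$next_state[s, a]
        if (done) { hits <- hits + 1; break }
      }
    }
    expect_gt(hits, 0)
  }
})

test_that("maze serialization round-trips through JSON and exports GraphML", {
  m <- fixture_maze1()
  jf <- tempfile(fileext = ".json")
  maze_to_json(m, jf)
  m2 <- maze_from_json(jf)
  expect_equal(m2$nodes, m$nodes)
  expect_equal(m2$start, m$start)
  expect_equal(m2$goal, m$goal)
  expect_equal(sort(m2$tunnel), sort(m$tunnel))
  expect_equal(m2$dist_nodes, m$dist_nodes)
  gf <- tempfile(fileext = ".graphml")
  maze_to_graphml(m, gf)
  g <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::vcount(g), m$n_nodes)
  unlink(c(jf, gf))
})

test_that("transition tables agree with step_maze by construction", {
  m <- corridor_maze(4)
  tab <- transition_tables(m)
  st <- maze_states(m)
  for (s in seq_len(m$n_states)) for (a in 1:6) {
    tr <- step_maze(m, oriented_state(m, st$node[s], st$heading[s]), a)
    expect_identical(tab$next_state[s, a], tr$next_state$state)
    expect_identical(tab$reward[s, a], tr$reward)
  }
})
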