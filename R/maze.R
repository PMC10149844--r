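#' @importFrom stats rnorm runif sd cor setNames
#' @importFrom utils write.csv head tail
NULL

HEADINGS <- c("N", "E", "S", "W")
# unit direction vectors, x east / y north
HEADING_DX <- c(N = 0L, E = 1L, S = 0L, W = -1L)
HEADING_DY <- c(N = 1L, E = 0L, S = -1L, W = 0L)

ACTIONS <- c("forward", "backward", "left", "right", "rotate_cw", "rotate_ccw")

#' Construct a tunnel maze from an explicit layout
#'
#' Builds the topology-graph environment used throughout the package: a set
#' of integer grid nodes, undirected edges (the allowed translations), a
#' fixed start and goal node, and the set of nodes forming the 1-wide
#' tunnel corridor. Agents occupy *oriented states*: (node, heading) pairs
#' with four headings per node, so the state count is `4 * nrow(nodes)`.
#'
#' Most users should call [build_tunnel_maze()], which generates the
#' parametric maze family; this constructor accepts any explicit layout so
#' alternative reconstructions are drop-in replacements.
#'
#' @param nodes integer matrix (n x 2) of (x, y) node coordinates; x grows
#'   east, y grows north.
#' @param edges integer matrix (m x 2) of node-index pairs (allowed
#'   transitions).
#' @param start,goal node indices of the fixed start and goal.
#' @param tunnel integer vector of node indices forming the corridor.
#' @param level integer label (1-4 for the built-in family).
#' @param timeout trial step budget imposed by the runner (default 600).
#' @param validate check maze invariants (connectivity, corridor property,
#'   two-route property)?
#' @return An object of class `tunnel_maze`.
#' @export
tunnel_maze <- function(nodes, edges, start, goal, tunnel, level = NA_integer_,
                        timeout = 600L, validate = TRUE) {
  nodes <- matrix(as.integer(as.matrix(nodes)), ncol = 2L,
                  dimnames = list(NULL, c("x", "y")))
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  n <- nrow(nodes)
  if (any(edges < 1L | edges > n)) stop("edge refers to a node outside the maze")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  maze <- structure(list(
    nodes = nodes, edges = edges, start = as.integer(start),
    goal = as.integer(goal), tunnel = as.integer(tunnel),
    level = as.integer(level), timeout = as.integer(timeout),
    graph = g, n_nodes = n, n_states = 4L * n
  ), class = "tunnel_maze")
  maze$node_at <- .coord_index(nodes)
  maze$dist_nodes <- igraph::distances(g)
  if (validate) .validate_maze(maze)
  maze
}

.coord_index <- function(nodes) {
  idx <- matrix(NA_integer_, nrow = max(nodes[, 1]) + 1L,
                ncol = max(nodes[, 2]) + 1L)
  idx[cbind(nodes[, 1] + 1L, nodes[, 2] + 1L)] <- seq_len(nrow(nodes))
  idx
}

.validate_maze <- function(maze) {
  if (maze$start == maze$goal)
    stop("maze configuration error: start and goal coincide")
  if (!igraph::is_connected(maze$graph))
    stop("maze configuration error: topology graph is not connected")
  deg <- igraph::degree(maze$graph)
  if (any(deg[maze$tunnel] > 2L))
    stop("maze configuration error: tunnel interior node with degree > 2 ",
         "(corridor property violated)")
  d_open <- maze$dist_nodes[maze$start, maze$goal]
  d_via <- min(maze$dist_nodes[maze$start, maze$tunnel] +
                 maze$dist_nodes[maze$tunnel, maze$goal])
  if (!(d_via > d_open))
    stop("maze configuration error: shortest start->goal path through the ",
         "tunnel is not strictly longer than the unconstrained shortest path ",
         "(two-route-class property violated)")
  invisible(maze)
}

#' Generate a maze of the parametric tunnel-maze family
#'
#' The family scales systematically with `level`: an open rectangular
#' chamber of width `5 + 2*(level-1)` and height `3 + 2*(level-1)` sits at
#' the south, and a 1-wide corridor arcs over its north side, rising
#' `2 + (level-1)` units from the chamber's north-west node, running east
#' along its top row and descending into the chamber's north-east node.
#' The start is the chamber's north-west node (the corridor mouth) and the
#' goal the chamber's north-east node, the corridor's other end. This
#' yields two route classes: a wall-constrained longer tunnel route that
#' funneled random exploration finds easily (entering the corridor mouth
#' next to the start leads the agent to the goal), and a strictly shorter
#' route through the open chamber, which is harder to discover because it
#' requires undirected exploration of the open area.
#' Each successive level elongates the tunnel north-south by 1 unit and
#' enlarges the chamber by 1 unit east and west and 2 units south.
#'
#' @param level integer in 1..4.
#' @param chamber_width,chamber_height,tunnel_rise optional overrides of
#'   the per-level layout parameters.
#' @param timeout trial step budget (default 600).
#' @return A `tunnel_maze`. Construction is deterministic.
#' @examples
#' m <- build_tunnel_maze(1)
#' m$n_nodes
#' @export
build_tunnel_maze <- function(level, chamber_width = NULL, chamber_height = NULL,
                              tunnel_rise = NULL, timeout = 600L) {
  if (!(length(level) == 1L && level %in% 1:4))
    stop("maze configuration error: level must be one of 1, 2, 3, 4")
  W <- if (is.null(chamber_width)) 5L + 2L * (level - 1L) else as.integer(chamber_width)
  H <- if (is.null(chamber_height)) 3L + 2L * (level - 1L) else as.integer(chamber_height)
  R <- if (is.null(tunnel_rise)) 2L + (level - 1L) else as.integer(tunnel_rise)
  if (W < 2L || H < 2L || R < 1L)
    stop("maze configuration error: chamber must be at least 2x2 with tunnel rise >= 1")
  chamber <- cbind(x = rep(0:(W - 1L), times = H), y = rep(0:(H - 1L), each = W))
  y_top <- H - 1L + R
  rise_w <- cbind(x = 0L, y = H:(y_top))                       # west rise incl. corner
  run_e <- cbind(x = 1:(W - 1L), y = y_top)                    # top run east of corner
  desc_e <- if (R > 1L) cbind(x = W - 1L, y = (y_top - 1L):H) else NULL # east descent
  tunnel_xy <- rbind(rise_w, run_e, desc_e)
  nodes <- rbind(chamber, tunnel_xy)
  tunnel <- (nrow(chamber) + 1L):nrow(nodes)
  edges <- .unit_adjacent_edges(nodes)
  start <- which(nodes[, 1] == 0L & nodes[, 2] == H - 1L)      # chamber NW
  goal <- which(nodes[, 1] == W - 1L & nodes[, 2] == H - 1L)   # chamber NE
  tunnel_maze(nodes, edges, start, goal, tunnel, level = level, timeout = timeout)
}

.unit_adjacent_edges <- function(nodes) {
  idx <- .coord_index(nodes)
  nr <- nrow(idx); nc <- ncol(idx)
  out <- list()
  for (i in seq_len(nrow(nodes))) {
    x <- nodes[i, 1] + 1L; y <- nodes[i, 2] + 1L
    if (x < nr && !is.na(idx[x + 1L, y])) out[[length(out) + 1L]] <- c(i, idx[x + 1L, y])
    if (y < nc && !is.na(idx[x, y + 1L])) out[[length(out) + 1L]] <- c(i, idx[x, y + 1L])
  }
  do.call(rbind, out)
}

#' Oriented states of a maze
#'
#' An oriented state is a (node, heading) pair; headings are N, E, S, W.
#' States are indexed `(node - 1) * 4 + heading_index`, giving
#' `4 * n_nodes` states in total.
#'
#' @param maze a `tunnel_maze`.
#' @return data.frame with columns `state`, `node`, `x`, `y`, `heading`.
#' @export
maze_states <- function(maze) {
  n <- maze$n_nodes
  node <- rep(seq_len(n), each = 4L)
  heading <- rep(HEADINGS, times = n)
  data.frame(state = seq_len(4L * n), node = node,
             x = maze$nodes[node, 1], y = maze$nodes[node, 2],
             heading = heading, stringsAsFactors = FALSE)
}

#' @rdname maze_states
#' @param node,heading node index and heading label (or index 1..4).
#' @export
oriented_state <- function(maze, node, heading) {
  h <- if (is.character(heading)) match(heading, HEADINGS) else as.integer(heading)
  if (is.na(h) || h < 1L || h > 4L) stop("invalid heading")
  node <- as.integer(node)
  if (node < 1L || node > maze$n_nodes) stop("state not in maze: invalid node")
  list(node = node, x = maze$nodes[node, 1], y = maze$nodes[node, 2],
       heading = HEADINGS[h], state = (node - 1L) * 4L + h)
}

state_index <- function(node, heading_idx) (node - 1L) * 4L + heading_idx

#' Environment step dynamics
#'
#' Pure transition function of the maze: rotations change heading in place;
#' `forward`/`backward` translate one grid unit along/against the heading,
#' `left`/`right` translate laterally at fixed heading (strafing). A
#' translation happens iff the corresponding edge exists, otherwise the
#' agent stays in place. The reward is +1.0 iff the next node is the goal,
#' which also terminates the trial; the 600-step timeout is bookkeeping of
#' the training runner, not of `step_maze`.
#'
#' @param maze a `tunnel_maze`.
#' @param state an oriented state as returned by [oriented_state()].
#' @param action one of `"forward"`, `"backward"`, `"left"`, `"right"`,
#'   `"rotate_cw"`, `"rotate_ccw"` (or its index 1..6).
#' @return list with `next_state` (oriented state), `reward` (0 or 1) and
#'   `terminal` (goal reached).
#' @export
step_maze <- function(maze, state, action) {
  a <- if (is.character(action)) match(action, ACTIONS) else as.integer(action)
  if (is.na(a) || a < 1L || a > 6L) stop("unknown action: ", action)
  node <- as.integer(state$node)
  if (node < 1L || node > maze$n_nodes) stop("state not in maze")
  h <- match(state$heading, HEADINGS)
  if (is.na(h)) stop("state not in maze: invalid heading")
  if (a >= 5L) {
    h2 <- if (a == 5L) (h %% 4L) + 1L else ((h + 2L) %% 4L) + 1L
    ns <- oriented_state(maze, node, h2)
    return(list(next_state = ns, reward = 0, terminal = FALSE))
  }
  # translation direction relative to heading: forward 0, backward 2, left -1, right +1
  turn <- c(0L, 2L, -1L, 1L)[a]
  dir <- ((h - 1L + turn) %% 4L) + 1L
  x2 <- state$x + HEADING_DX[dir]; y2 <- state$y + HEADING_DY[dir]
  node2 <- node
  if (x2 >= 0L && y2 >= 0L && x2 < nrow(maze$node_at) && y2 < ncol(maze$node_at)) {
    cand <- maze$node_at[x2 + 1L, y2 + 1L]
    if (!is.na(cand) && maze$dist_nodes[node, cand] == 1) node2 <- cand
  }
  ns <- oriented_state(maze, node2, h)
  hit <- node2 == maze$goal
  list(next_state = ns, reward = if (hit) 1.0 else 0.0, terminal = hit)
}

#' Shortest node-path length
#'
#' Breadth-first shortest path length between two nodes over the maze
#' edges, counting node transitions only (rotations are free). With
#' `restrict_to`, the path must stay inside the given node subset
#' (endpoints included); an unreachable pair returns `Inf` rather than
#' signalling an error.
#'
#' @param maze a `tunnel_maze`.
#' @param from,to node indices.
#' @param restrict_to optional integer vector of admissible nodes.
#' @return integer path length in edges, or `Inf` if no path exists.
#' @export
shortest_path_length <- function(maze, from, to, restrict_to = NULL) {
  from <- as.integer(from); to <- as.integer(to)
  if (from < 1L || from > maze$n_nodes || to < 1L || to > maze$n_nodes)
    stop("node not in maze")
  if (is.null(restrict_to)) return(unname(maze$dist_nodes[from, to]))
  keep <- sort(unique(as.integer(restrict_to)))
  if (!(from %in% keep) || !(to %in% keep)) return(Inf)
  g <- igraph::induced_subgraph(maze$graph, keep)
  d <- igraph::distances(g, v = match(from, keep), to = match(to, keep))
  unname(d[1, 1])
}

#' Precomputed transition tables
#'
#' For every oriented state and action, the successor state index, reward
#' and goal-terminal flag. Training loops use these tables so that
#' environment stepping is a table lookup; contents agree exactly with
#' [step_maze()] by construction.
#'
#' @param maze a `tunnel_maze`.
#' @return list with integer matrix `next_state` (n_states x 6), numeric
#'   matrix `reward` and logical matrix `terminal`.
#' @export
transition_tables <- function(maze) {
  S <- maze$n_states
  nxt <- matrix(0L, S, 6L); rew <- matrix(0, S, 6L); term <- matrix(FALSE, S, 6L)
  st <- maze_states(maze)
  for (s in seq_len(S)) {
    os <- oriented_state(maze, st$node[s], st$heading[s])
    for (a in 1:6) {
      tr <- step_maze(maze, os, a)
      nxt[s, a] <- tr$next_state$state
      rew[s, a] <- tr$reward
      term[s, a] <- tr$terminal
    }
  }
  list(next_state = nxt, reward = rew, terminal = term)
}

#' Serialize a maze
#'
#' `maze_to_json()` writes the layout as a JSON document
#' `{level, nodes, edges, start, goal, tunnel, timeout}` (0-based indices
#' for interoperability); `maze_from_json()` reads it back;
#' `maze_to_graphml()` exports the topology graph for inspection in
#' standard graph tools.
#'
#' @param maze a `tunnel_maze`.
#' @param path file path (for `maze_from_json`, a path or JSON string).
#' @return `maze_to_json` and `maze_to_graphml` return `path` invisibly;
#'   `maze_from_json` returns a `tunnel_maze`.
#' @export
maze_to_json <- function(maze, path) {
  doc <- list(level = maze$level,
              nodes = unname(apply(maze$nodes, 1, as.list)),
              edges = unname(apply(maze$edges - 1L, 1, as.list)),
              start = maze$start - 1L, goal = maze$goal - 1L,
              tunnel = as.list(maze$tunnel - 1L), timeout = maze$timeout)
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname maze_to_json
#' @export
maze_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tunnel_maze(nodes = doc$nodes, edges = doc$edges + 1L,
              start = doc$start + 1L, goal = doc$goal + 1L,
              tunnel = unlist(doc$tunnel) + 1L,
              level = if (is.null(doc$level)) NA_integer_ else doc$level,
              timeout = doc$timeout)
}

#' @rdname maze_to_json
#' @export
maze_to_graphml <- function(maze, path) {
  g <- maze$graph
  igraph::V(g)$x <- maze$nodes[, 1]
  igraph::V(g)$y <- maze$nodes[, 2]
  igraph::V(g)$role <- ifelse(seq_len(maze$n_nodes) == maze$start, "start",
                       ifelse(seq_len(maze$n_nodes) == maze$goal, "goal",
                       ifelse(seq_len(maze$n_nodes) %in% maze$tunnel, "tunnel", "chamber")))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.tunnel_maze <- function(x, ...) {
  cat(sprintf("tunnel maze (level %s): %d nodes, %d states, %d tunnel nodes\n",
              x$level, x$n_nodes, x$n_states, length(x$tunnel)))
  cat(sprintf("  start node %d, goal node %d, timeout %d steps\n",
              x$start, x$goal, x$timeout))
  cat(sprintf("  shortest open path %d, shortest via-tunnel path %d\n",
              x$dist_nodes[x$start, x$goal],
              min(x$dist_nodes[x$start, x$tunnel] + x$dist_nodes[x$tunnel, x$goal])))
  invisible(x)
}
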