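#' Deterministic state observation codec
#'
#' Emulates the visual input of an embodied agent with a deterministic,
#' spatially smooth embedding of each oriented state. The pose
#' `u(s) = (x/x_max, y/y_max, cos(theta), sin(theta))` is mapped through a
#' random Fourier feature expansion with codec-seeded frequencies, so
#' observations of spatially and orientationally nearby states are nearby
#' in observation space -- the property that makes nearest-neighbor
#' generalization in episodic control meaningful, mirroring the visual
#' similarity of nearby camera views.
#'
#' The feature bandwidth is chosen so that observations of adjacent nodes
#' (same heading) correlate approximately `adjacent_cor` (default 0.8).
#' All observations for a maze are precomputed and cached, so lookups are
#' O(1) after construction.
#'
#' @param maze a `tunnel_maze`.
#' @param dim ambient observation dimension D (default 64).
#' @param seed integer seed fixing the random frequencies.
#' @param adjacent_cor target correlation between observations of adjacent
#'   nodes at equal heading, in (0, 1).
#' @return An object of class `state_codec` with a cached
#'   `n_states x dim` observation matrix.
#' @export
state_codec <- function(maze, dim = 64L, seed = 1L, adjacent_cor = 0.8) {
  stopifnot(dim >= 2L, adjacent_cor > 0, adjacent_cor < 1)
  st <- maze_states(maze)
  xmax <- max(st$x, 1L); ymax <- max(st$y, 1L)  # guard degenerate extents
  theta <- c(N = pi / 2, E = 0, S = -pi / 2, W = pi)[st$heading]
  u <- cbind(st$x / xmax, st$y / ymax, cos(theta), sin(theta))
  # Gaussian-kernel bandwidth from the adjacent-node spacing: for the RBF
  # kernel k(d) = exp(-d^2 / (2 l^2)), k(delta) = adjacent_cor fixes l.
  delta <- mean(c(1 / xmax, 1 / ymax))
  ell <- delta / sqrt(-2 * log(adjacent_cor))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  omega <- matrix(rnorm(dim * 4L, sd = 1 / ell), nrow = 4L)
  phase <- runif(dim, 0, 2 * pi)
  obs <- sqrt(2 / dim) * cos(sweep(u %*% omega, 2L, phase, "+"))
  structure(list(dim = as.integer(dim), seed = as.integer(seed),
                 adjacent_cor = adjacent_cor, bandwidth = ell,
                 n_states = maze$n_states, observations = obs),
            class = "state_codec")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Encode an oriented state as an observation vector
#'
#' Deterministic per-state observation lookup; identical states under the
#' same codec always encode identically.
#'
#' @param codec a `state_codec`.
#' @param state an oriented state (see [oriented_state()]) or a state index.
#' @return numeric vector of length `codec$dim`.
#' @export
encode_state <- function(codec, state) {
  s <- if (is.list(state)) state$state else as.integer(state)
  if (s < 1L || s > codec$n_states) stop("invalid state for this codec")
  codec$observations[s, ]
}

#' Full state-observation table
#'
#' @param codec a `state_codec`.
#' @return numeric matrix, one row per oriented state.
#' @export
observation_matrix <- function(codec) codec$observations

#' Dump the observation table to CSV
#'
#' Writes the full state -> observation table keyed by (node, heading) as
#' plain CSV for external inspection.
#'
#' @param codec a `state_codec`.
#' @param maze the owning `tunnel_maze`.
#' @param path output file path.
#' @export
write_observation_table <- function(codec, maze, path) {
  st <- maze_states(maze)
  out <- cbind(st[, c("node", "heading")], as.data.frame(codec$observations))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Random projection matrix
#'
#' A seeded `f x d` matrix with independent standard-normal entries, the
#' dimension-reduction map phi: x -> Mx of episodic control. By the
#' Johnson-Lindenstrauss lemma the map approximately preserves relative
#' distances: `||Mx - My|| ~ sqrt(f) * ||x - y||`. The projection stage is
#' kept even when `f >= d` to preserve the structure of the algorithm.
#'
#' @param f projected dimension (default 256).
#' @param d ambient observation dimension.
#' @param seed integer seed.
#' @return numeric matrix of class `projection_matrix`.
#' @export
projection_matrix <- function(f = 256L, d, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  structure(matrix(rnorm(f * d), nrow = f, ncol = d),
            class = c("projection_matrix", "matrix", "array"))
}

#' Apply a random projection
#'
#' Exact linear map `M x`. `x` may be a single observation vector or a
#' matrix with one observation per row (projected row-wise).
#'
#' @param M a [projection_matrix()].
#' @param x numeric vector of length `ncol(M)`, or matrix with that many
#'   columns.
#' @return projected vector of length `nrow(M)`, or matrix with one
#'   projected row per input row.
#' @export
project <- function(M, x) {
  if (is.matrix(x)) {
    if (ncol(x) != ncol(M)) stop("dimension mismatch: expected ", ncol(M),
                                 " columns, got ", ncol(x))
    return(x %*% t(M))
  }
  if (length(x) != ncol(M)) stop("dimension mismatch: expected length ",
                                 ncol(M), ", got ", length(x))
  drop(M %*% x)
}
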