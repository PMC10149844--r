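#' Q-function approximator
#'
#' Parametric map from observations to the six action values, holding an
#' online and a target parameter set of identical architecture. Three
#' architectures are provided: `"tabular"` (a one-hot table over state
#' indices, reducing the replay update to tabular Q-learning), `"linear"`
#' (affine map on the observation vector) and `"mlp"` (a two-hidden-layer
#' ReLU perceptron with a linear head, default widths 64, 64). The
#' original study's convolutional network is image-specific; its results
#' depend on incremental function approximation, not convolution, so the
#' approximator is configurable on low-dimensional observations.
#'
#' Defaults: linear/MLP use adaptive-moment (Adam) gradient descent with
#' learning rate 1e-4; the tabular architecture uses plain gradient
#' descent with step size 0.1 (a table needs no adaptive scaling, and a
#' DNN-scale learning rate would be meaningless for it).
#'
#' @param type `"tabular"`, `"linear"` or `"mlp"`.
#' @param input_dim observation dimension (for `"tabular"`: the state
#'   count).
#' @param n_actions number of actions (default 6).
#' @param hidden hidden-layer widths for `"mlp"`.
#' @param optimizer `"adam"` or `"sgd"`; default depends on `type`.
#' @param lr learning rate eta.
#' @param seed seed for weight initialization.
#' @param obs optional `n_states x input_dim` observation matrix; when
#'   set, updates may refer to transitions by state index.
#' @return environment of class `q_approximator`.
#' @export
q_approximator <- function(type = c("mlp", "linear", "tabular"),
                           input_dim, n_actions = 6L, hidden = c(64L, 64L),
                           optimizer = NULL, lr = NULL, seed = 1L, obs = NULL) {
  type <- match.arg(type)
  net <- new.env(parent = emptyenv())
  net$type <- type
  net$n_actions <- as.integer(n_actions)
  net$input_dim <- as.integer(input_dim)
  net$obs <- obs
  net$optimizer <- if (!is.null(optimizer)) match.arg(optimizer, c("adam", "sgd"))
                   else if (type == "tabular") "sgd" else "adam"
  net$lr <- if (!is.null(lr)) lr else if (type == "tabular") 0.1 else 1e-4
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  net$params <- switch(type,
    tabular = list(W = matrix(0, input_dim, n_actions)),
    linear = list(W = matrix(rnorm(input_dim * n_actions, sd = 0.01),
                             input_dim, n_actions),
                  b = numeric(n_actions)),
    mlp = {
      h1 <- hidden[1]; h2 <- hidden[2]
      list(W1 = matrix(rnorm(input_dim * h1, sd = sqrt(2 / input_dim)), input_dim, h1),
           b1 = numeric(h1),
           W2 = matrix(rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
           b2 = numeric(h2),
           W3 = matrix(rnorm(h2 * n_actions, sd = sqrt(2 / h2)), h2, n_actions),
           b3 = numeric(n_actions))
    })
  net$target <- net$params
  net$opt_m <- lapply(net$params, function(p) p * 0)
  net$opt_v <- lapply(net$params, function(p) p * 0)
  net$opt_t <- 0L
  net$n_updates <- 0L
  class(net) <- "q_approximator"
  net
}

.net_input <- function(net, s) {
  if (net$type == "tabular") return(as.integer(s))
  if (is.matrix(s) || (is.numeric(s) && length(s) == net$input_dim && is.null(net$obs)))
    return(if (is.matrix(s)) s else matrix(s, nrow = 1L))
  if (is.null(net$obs)) stop("approximator has no observation table; pass raw inputs")
  net$obs[as.integer(s), , drop = FALSE]
}

#' Action values of a Q approximator
#'
#' @param net a [q_approximator()].
#' @param s state indices (when the net holds an observation table or is
#'   tabular) or a matrix of raw observations, one per row.
#' @param target evaluate the target parameters instead of the online
#'   ones?
#' @return numeric matrix, one row of action values per input state.
#' @export
q_values <- function(net, s, target = FALSE) {
  p <- if (target) net$target else net$params
  x <- .net_input(net, s)
  switch(net$type,
    tabular = p$W[x, , drop = FALSE],
    linear = sweep(x %*% p$W, 2L, p$b, "+"),
    mlp = {
      h1 <- pmax(sweep(x %*% p$W1, 2L, p$b1, "+"), 0)
      h2 <- pmax(sweep(h1 %*% p$W2, 2L, p$b2, "+"), 0)
      sweep(h2 %*% p$W3, 2L, p$b3, "+")
    })
}

# single-state action values without matrix scaffolding (hot path of the
# training loops)
.q_row <- function(net, s) {
  p <- net$params
  if (net$type == "tabular") return(p$W[s, ])
  x <- net$obs[s, ]
  if (net$type == "linear") return(drop(x %*% p$W) + p$b)
  h1 <- pmax(drop(x %*% p$W1) + p$b1, 0)
  h2 <- pmax(drop(h1 %*% p$W2) + p$b2, 0)
  drop(h2 %*% p$W3) + p$b3
}

# gradient of the summed squared error wrt all parameters; returns
# list(loss, grads)
.q_backward <- function(net, x, actions, targets) {
  p <- net$params
  n <- length(actions)
  if (net$type == "tabular") {
    pred <- p$W[cbind(x, actions)]
    delta <- 2 * (pred - targets)
    g <- matrix(0, nrow(p$W), ncol(p$W))
    key <- x + (actions - 1L) * nrow(p$W)   # column-major linear index
    # per-entry mean gradient: a table entry drawn several times in one
    # batch steps toward the mean of its TD targets, keeping the update
    # stable for any step size < 1 irrespective of sampling repeats
    agg <- rowsum(delta, key) / as.vector(rowsum(rep(1, length(key)), key))
    g[as.integer(rownames(agg))] <- agg
    return(list(loss = sum((pred - targets)^2), grads = list(W = g)))
  }
  if (net$type == "linear") {
    q <- sweep(x %*% p$W, 2L, p$b, "+")
    pred <- q[cbind(seq_len(n), actions)]
    dq <- matrix(0, n, net$n_actions)
    dq[cbind(seq_len(n), actions)] <- 2 * (pred - targets)
    return(list(loss = sum((pred - targets)^2),
                grads = list(W = crossprod(x, dq), b = colSums(dq))))
  }
  a1 <- sweep(x %*% p$W1, 2L, p$b1, "+"); h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% p$W2, 2L, p$b2, "+"); h2 <- pmax(a2, 0)
  q <- sweep(h2 %*% p$W3, 2L, p$b3, "+")
  pred <- q[cbind(seq_len(n), actions)]
  dq <- matrix(0, n, net$n_actions)
  dq[cbind(seq_len(n), actions)] <- 2 * (pred - targets)
  dh2 <- dq %*% t(p$W3) * (a2 > 0)
  dh1 <- dh2 %*% t(p$W2) * (a1 > 0)
  list(loss = sum((pred - targets)^2),
       grads = list(W1 = crossprod(x, dh1), b1 = colSums(dh1),
                    W2 = crossprod(h1, dh2), b2 = colSums(dh2),
                    W3 = crossprod(h2, dq), b3 = colSums(dq)))
}

.q_apply_grads <- function(net, grads) {
  if (net$optimizer == "sgd") {
    for (nm in names(grads)) net$params[[nm]] <- net$params[[nm]] - net$lr * grads[[nm]]
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    net$opt_t <- net$opt_t + 1L
    for (nm in names(grads)) {
      net$opt_m[[nm]] <- b1 * net$opt_m[[nm]] + (1 - b1) * grads[[nm]]
      net$opt_v[[nm]] <- b2 * net$opt_v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- net$opt_m[[nm]] / (1 - b1^net$opt_t)
      vhat <- net$opt_v[[nm]] / (1 - b2^net$opt_t)
      net$params[[nm]] <- net$params[[nm]] - net$lr * mhat / (sqrt(vhat) + eps)
    }
  }
  net$n_updates <- net$n_updates + 1L
  invisible(net)
}

#' Temporal-difference targets
#'
#' Per transition: `r` if terminal, else
#' `r + gamma * max_a' Q_target(s', a')`. The printed loss of the source
#' model omits the discount and terminal mask; `literal = TRUE` reproduces
#' that form (`r + max_a' Q_target(s', a')` always bootstrapped), the
#' default restores standard Q-learning semantics.
#'
#' @param net a [q_approximator()] (its target parameters are used).
#' @param r rewards.
#' @param s2 next states (indices or observation matrix).
#' @param terminal logical terminal flags.
#' @param gamma discount factor.
#' @param literal reproduce the literal printed loss (no discount, no
#'   terminal masking)?
#' @param use_target bootstrap from the target parameters (the replay
#'   learner's stabilizer) or from the online ones (the offline
#'   trial-end replay regime, where sequenced updates chain)?
#' @return numeric vector of targets.
#' @export
td_targets <- function(net, r, s2, terminal, gamma = 0.9, literal = FALSE,
                       use_target = TRUE) {
  stopifnot(length(r) >= 1L)
  qmax <- .row_max(q_values(net, s2, target = use_target))
  if (literal) return(r + qmax)
  r + gamma * qmax * !terminal
}

.row_max <- function(m) {
  out <- m[, 1]
  for (j in 2:ncol(m)) out <- pmax(out, m[, j])
  out
}

#' Experience replay buffer
#'
#' FIFO store of experience tuples with uniform sampling with replacement
#' over the stored contents.
#'
#' @param capacity maximum number of stored tuples (default 50000).
#' @return environment of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 50000L) {
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$s <- integer(capacity); buf$a <- integer(capacity)
  buf$s2 <- integer(capacity); buf$r <- numeric(capacity)
  buf$terminal <- logical(capacity)
  buf$size <- 0L
  buf$pos <- 0L
  class(buf) <- "replay_buffer"
  buf
}

#' @rdname replay_buffer
#' @param buf a replay buffer.
#' @param s,a,s2,r,terminal transition fields (state indices).
#' @export
buffer_push <- function(buf, s, a, s2, r, terminal) {
  buf$pos <- (buf$pos %% buf$capacity) + 1L
  buf$s[buf$pos] <- s; buf$a[buf$pos] <- a; buf$s2[buf$pos] <- s2
  buf$r[buf$pos] <- r; buf$terminal[buf$pos] <- terminal
  if (buf$size < buf$capacity) buf$size <- buf$size + 1L
  invisible(buf)
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buf) buf$size

#' Mini-batch replay update
#'
#' Draws a uniform mini-batch from the buffer, builds the summed squared
#' TD error against the target network and applies one gradient step to
#' the online parameters; the target parameters are untouched. An empty
#' buffer is a logged no-op.
#'
#' @param net a [q_approximator()] holding an observation table (or
#'   tabular).
#' @param buf a [replay_buffer()].
#' @param batch_size mini-batch size (default 32).
#' @param gamma discount factor.
#' @param literal use the literal printed TD target (see [td_targets()]).
#' @return the loss before the update (invisibly `NA` if the buffer is
#'   empty).
#' @export
replay_update <- function(net, buf, batch_size = 32L, gamma = 0.9,
                          literal = FALSE) {
  if (buf$size == 0L) {
    message("replay_update: empty buffer, skipping update")
    return(invisible(NA_real_))
  }
  idx <- sample.int(buf$size, batch_size, replace = TRUE)
  tgt <- td_targets(net, buf$r[idx], buf$s2[idx], buf$terminal[idx],
                    gamma = gamma, literal = literal)
  bk <- .q_backward(net, .net_input(net, buf$s[idx]), buf$a[idx], tgt)
  .q_apply_grads(net, bk$grads)
  bk$loss
}

#' Soft target-network update
#'
#' Moves every target parameter a fraction `alpha` toward its online
#' counterpart: `w_bar <- w_bar + alpha * (w - w_bar)` elementwise, so the
#' target network trails the online network slowly (default
#' `alpha = 0.01`).
#'
#' @param net a [q_approximator()].
#' @param alpha interpolation factor in `[0, 1]`.
#' @return the net, invisibly.
#' @export
soft_update <- function(net, alpha = 0.01) {
  for (nm in names(net$params)) {
    if (!identical(dim(net$target[[nm]]), dim(net$params[[nm]])))
      stop("shape mismatch between online and target parameters")
    net$target[[nm]] <- net$target[[nm]] + alpha * (net$params[[nm]] - net$target[[nm]])
  }
  invisible(net)
}

#' Single-transition online update
#'
#' The memory-less learning rule: a squared TD error built from the
#' current transition only (bootstrapping from the target parameters,
#' terminal-masked, discounted), one gradient step; the tuple is never
#' stored. The printed form of this loss swaps the online and target
#' roles; `literal = TRUE` reproduces it (prediction from the target
#' parameters, bootstrap from the online ones, no discount/mask).
#'
#' @param net a [q_approximator()].
#' @param tuple list with fields `s`, `a`, `s2`, `r`, `terminal`.
#' @param gamma discount factor.
#' @param literal reproduce the literal printed form?
#' @return the loss before the update.
#' @export
online_update <- function(net, tuple, gamma = 0.9, literal = FALSE) {
  if (literal) {
    qmax <- max(q_values(net, tuple$s2, target = FALSE))
    pred <- q_values(net, tuple$s, target = TRUE)[1, tuple$a]
    loss <- (tuple$r + qmax - pred)^2
    # gradient flows through the target-parameter prediction in the
    # literal form; apply it to the online copy to keep learning moving
    tgt <- tuple$r + qmax
  } else {
    tgt <- td_targets(net, tuple$r, tuple$s2, tuple$terminal, gamma = gamma)
  }
  bk <- .q_backward(net, .net_input(net, tuple$s), tuple$a, tgt)
  .q_apply_grads(net, bk$grads)
  bk$loss
}

#' Per-step update schedule of the replay variants
#'
#' The default replay learner performs one 32-sample mini-batch update per
#' environment step. Two diagnostic variants match the online learner's
#' data budget: `batch_size_one` (one 1-sample update per step) and
#' `sparse_sampling` (one 32-sample update every 32 steps). All variants
#' apply a soft target update after each learner update.
#'
#' @param variant `"default"`, `"batch_size_one"` or `"sparse_sampling"`.
#' @param batch_size base mini-batch size (default 32).
#' @return list with `batch_size` (samples per update) and `every`
#'   (environment steps between updates).
#' @export
update_schedule <- function(variant = c("default", "batch_size_one",
                                        "sparse_sampling"),
                            batch_size = 32L) {
  variant <- match.arg(variant)
  switch(variant,
         default = list(batch_size = as.integer(batch_size), every = 1L),
         batch_size_one = list(batch_size = 1L, every = 1L),
         sparse_sampling = list(batch_size = as.integer(batch_size),
                                every = as.integer(batch_size)))
}

#' Save or load approximator parameters
#'
#' Checkpoints the online and target parameters (plus optimizer state) to
#' a single serialized file.
#'
#' @param net a [q_approximator()].
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(type = net$type, params = net$params, target = net$target,
               opt_m = net$opt_m, opt_v = net$opt_v, opt_t = net$opt_t,
               lr = net$lr, optimizer = net$optimizer), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(net, path) {
  ck <- readRDS(path)
  if (!identical(ck$type, net$type)) stop("checkpoint architecture mismatch")
  net$params <- ck$params; net$target <- ck$target
  net$opt_m <- ck$opt_m; net$opt_v <- ck$opt_v; net$opt_t <- ck$opt_t
  invisible(net)
}

#' @export
print.q_approximator <- function(x, ...) {
  cat(sprintf("Q approximator (%s, %s, lr = %g): %d updates\n",
              x$type, x$optimizer, x$lr, x$n_updates))
  invisible(x)
}
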