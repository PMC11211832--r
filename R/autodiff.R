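# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records operation nodes in execution order; backward() walks the
# nodes in reverse, calling each node's backward closure to push gradients to
# its parents. Passing tape = NULL runs every op value-only (inference mode).
# All gradients are finite-difference-checked in the test suite.

.new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.tp_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!is.null(tape) && !is.null(backward)) {
    nd$parents <- parents
    nd$backward <- backward
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

.val <- function(x) if (is.environment(x)) x$value else x

tp_const <- function(tape, x) .tp_node(tape, x)

.acc <- function(node, g) {
  if (is.environment(node)) {
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  }
  invisible(NULL)
}

backward <- function(tape, loss) {
  loss$grad <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) .acc(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# Elementwise / linear algebra ------------------------------------------------

tp_matmul <- function(tape, a, b) {
  av <- .val(a); bv <- .val(b)
  .tp_node(tape, av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

tp_add <- function(tape, a, b) {
  .tp_node(tape, .val(a) + .val(b), list(a, b), function(g) list(g, g))
}

# Add a 1 x d bias row to every row of a.
tp_addbias <- function(tape, a, bias) {
  av <- .val(a); bv <- .val(bias)
  .tp_node(tape, sweep(av, 2L, as.vector(bv), "+"), list(a, bias),
           function(g) list(g, matrix(colSums(g), 1L)))
}

tp_scale <- function(tape, a, s) {
  .tp_node(tape, .val(a) * s, list(a), function(g) list(g * s))
}

tp_relu <- function(tape, a) {
  av <- .val(a)
  m <- av > 0
  .tp_node(tape, av * m, list(a), function(g) list(g * m))
}

tp_lrelu <- function(tape, a, slope = 0.01) {
  av <- .val(a)
  m <- ifelse(av > 0, 1, slope)
  .tp_node(tape, av * m, list(a), function(g) list(g * m))
}

tp_dropout <- function(tape, a, p, training = TRUE) {
  if (!training || p <= 0) return(a)
  av <- .val(a)
  keep <- matrix(stats::runif(length(av)) >= p, nrow(av), ncol(av)) / (1 - p)
  .tp_node(tape, av * keep, list(a), function(g) list(g * keep))
}

# Row indexing ----------------------------------------------------------------

tp_gather <- function(tape, a, idx) {
  av <- .val(a)
  n <- nrow(av)
  .tp_node(tape, av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, n, ncol(av))
    if (length(idx) > 0L) {
      rs <- rowsum(g, group = idx, reorder = TRUE)
      out[as.integer(rownames(rs)), ] <- rs
    }
    list(out)
  })
}

# Sum rows of a into `n` output rows by destination index.
tp_scatter_sum <- function(tape, a, idx, n) {
  av <- .val(a)
  fwd <- function(x) {
    out <- matrix(0, n, ncol(x))
    if (length(idx) > 0L) {
      rs <- rowsum(x, group = idx, reorder = TRUE)
      out[as.integer(rownames(rs)), ] <- rs
    }
    out
  }
  .tp_node(tape, fwd(av), list(a),
           function(g) list(g[idx, , drop = FALSE]))
}

# Mean of rows within each group (groups must cover 1..ngroups).
tp_segment_mean <- function(tape, a, groups, ngroups) {
  av <- .val(a)
  cnt <- tabulate(groups, nbins = ngroups)
  rs <- rowsum(av, group = groups, reorder = TRUE)
  out <- matrix(0, ngroups, ncol(av))
  out[as.integer(rownames(rs)), ] <- rs
  out <- out / pmax(cnt, 1L)
  .tp_node(tape, out, list(a), function(g) {
    list(g[groups, , drop = FALSE] / pmax(cnt, 1L)[groups])
  })
}

# Concatenate a variable matrix with a constant matrix column-wise.
tp_concat_const <- function(tape, a, constmat) {
  av <- .val(a)
  d <- ncol(av)
  .tp_node(tape, cbind(av, constmat), list(a),
           function(g) list(g[, seq_len(d), drop = FALSE]))
}

# Batch normalization ---------------------------------------------------------

# `state` is an environment with $mean and $var (running statistics, updated
# in place during training); gamma/beta are 1 x d parameter rows.
tp_batchnorm <- function(tape, x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- .val(x); gv <- as.vector(.val(gamma)); bv <- as.vector(.val(beta))
  m <- nrow(xv)
  if (training && m > 1L) {
    mu <- colMeans(xv)
    va <- colMeans(sweep(xv, 2L, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xv, 2L, mu), 2L, inv_std, "*")
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  use_batch <- training && m > 1L
  .tp_node(tape, out, list(x, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- sweep(g, 2L, gv, "*")
    if (use_batch) {
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
      dx <- sweep(t1 - t2, 2L, inv_std, "*")
    } else {
      dx <- sweep(dxhat, 2L, inv_std, "*")
    }
    list(dx, dgamma, dbeta)
  })
}

# InfoNCE ---------------------------------------------------------------------

.row_normalize <- function(x, eps = 1e-8) {
  nr <- sqrt(rowSums(x^2))
  list(xn = x / pmax(nr, eps), norm = pmax(nr, eps))
}

.log_softmax_stats <- function(s) {
  # returns row softmax P and column softmax Q plus the diagonal log-probs
  mr <- apply(s, 1L, max)
  er <- exp(s - mr)
  P <- er / rowSums(er)
  mc <- apply(s, 2L, max)
  ec <- exp(sweep(s, 2L, mc))
  Q <- sweep(ec, 2L, colSums(ec), "/")
  list(P = P, Q = Q,
       row_logp = diag(s) - (mr + log(rowSums(er))),
       col_logp = diag(s) - (mc + log(colSums(ec))))
}

# Dual (symmetric) InfoNCE over matched rows of X and Y with cosine
# similarity at temperature tau. Returns a scalar node.
tp_info_nce <- function(tape, X, Y, tau) {
  xv <- .val(X); yv <- .val(Y)
  if (nrow(xv) != nrow(yv) || ncol(xv) != ncol(yv))
    stop("dimension error: X and Y must have matching shapes")
  B <- nrow(xv)
  nx <- .row_normalize(xv); ny <- .row_normalize(yv)
  S <- (nx$xn %*% t(ny$xn)) / tau
  st <- .log_softmax_stats(S)
  loss <- -mean(st$row_logp + st$col_logp) / 2
  .tp_node(tape, loss, list(X, Y), function(g) {
    G <- g * (st$P + st$Q - 2 * diag(B)) / (2 * B)
    dXn <- (G %*% ny$xn) / tau
    dYn <- (t(G) %*% nx$xn) / tau
    dX <- (dXn - nx$xn * rowSums(dXn * nx$xn)) / nx$norm
    dY <- (dYn - ny$xn * rowSums(dYn * ny$xn)) / ny$norm
    list(dX, dY)
  })
}

#' Dual InfoNCE contrastive loss
#'
#' Symmetric noise-contrastive cross-entropy over in-batch negatives: matched
#' rows of `X` and `Y` are positive pairs, every other row of the opposite
#' matrix is a negative, similarity is cosine scaled by the temperature
#' `tau`, and the two softmax directions (X against all Y, Y against all X)
#' are averaged. With a single pair the loss is 0; with all rows identical it
#' is `log(B)`. Smaller `tau` sharpens the softmax and increases the penalty
#' for near-duplicate negatives.
#'
#' @param X,Y Numeric matrices, one row per projection, matched by row.
#' @param tau Positive temperature scalar.
#' @return The scalar loss.
#' @examples
#' X <- diag(2); info_nce(X, X, tau = 1)  # log(1 + exp(-1))
#' @export
info_nce <- function(X, Y, tau) {
  stopifnot(is.numeric(tau), tau > 0)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("dimension error: row counts differ")
  .val(tp_info_nce(NULL, X, Y, tau))
}

# Losses for fine-tuning ------------------------------------------------------

# Mean squared error over non-missing targets.
tp_mse_masked <- function(tape, pred, target) {
  pv <- .val(pred)
  mask <- !is.na(target)
  n <- max(sum(mask), 1L)
  diff <- ifelse(mask, pv - ifelse(mask, target, 0), 0)
  .tp_node(tape, sum(diff^2) / n, list(pred),
           function(g) list(g * 2 * diff / n))
}

# Sigmoid cross-entropy with missing labels masked out.
tp_bce_masked <- function(tape, logits, target) {
  lv <- .val(logits)
  mask <- !is.na(target)
  n <- max(sum(mask), 1L)
  t0 <- ifelse(mask, target, 0)
  p <- 1 / (1 + exp(-lv))
  ll <- ifelse(mask, t0 * log(pmax(p, 1e-12)) +
                 (1 - t0) * log(pmax(1 - p, 1e-12)), 0)
  .tp_node(tape, -sum(ll) / n, list(logits),
           function(g) list(g * ifelse(mask, p - t0, 0) / n))
}

# Adam ------------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
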