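# Finite-difference validation of the reverse-mode tape that powers the
# encoder and the contrastive objectives.

fd_grad <- function(f, X, h = 1e-6) {
  g <- X
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    g[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  g
}

tape_grad <- function(op, X, ...) {
  tape <- molrgr:::.new_tape()
  xn <- molrgr:::.tp_node(tape, X)
  # route through a recorded identity so xn participates in the tape
  xs <- molrgr:::tp_scale(tape, xn, 1)
  out <- op(tape, xs, ...)
  # reduce to scalar with fixed weights for a well-defined gradient
  w <- matrix(seq_along(molrgr:::.val(out)) / length(molrgr:::.val(out)),
              nrow(molrgr:::.val(out)))
  loss <- molrgr:::.tp_node(tape, sum(molrgr:::.val(out) * w), list(out),
                            function(g) list(g * w))
  molrgr:::backward(tape, loss)
  xn$grad
}

value_of <- function(op, X, ...) {
  function(Xi) {
    out <- op(NULL, molrgr:::.tp_node(NULL, Xi), ...)
    v <- molrgr:::.val(out)
    w <- matrix(seq_along(v) / length(v), nrow(v))
    sum(v * w)
  }
}

test_that("tape gradients of core ops match finite differences", {
  set.seed(11)
  X <- matrix(rnorm(5 * 4), 5)
  cases <- list(
    relu = function(t, x) molrgr:::tp_relu(t, x),
    lrelu = function(t, x) molrgr:::tp_lrelu(t, x, 0.01),
    matmul = local({
      W <- matrix(rnorm(4 * 3), 4)
      function(t, x) molrgr:::tp_matmul(t, x, molrgr:::.tp_node(t, W))
    }),
    addbias = local({
      b <- matrix(rnorm(4), 1)
      function(t, x) molrgr:::tp_addbias(t, x, molrgr:::.tp_node(t, b))
    }),
    gather = function(t, x) molrgr:::tp_gather(t, x, c(2L, 2L, 5L, 1L)),
    scatter = function(t, x) molrgr:::tp_scatter_sum(t, x, c(1L, 3L, 3L, 2L, 1L), 3L),
    segmean = function(t, x) molrgr:::tp_segment_mean(t, x, c(1L, 1L, 2L, 2L, 2L), 2L),
    concat = function(t, x) molrgr:::tp_concat_const(t, x, matrix(1, 5, 2))
  )
  for (nm in names(cases)) {
    g <- tape_grad(cases[[nm]], X)
    num <- fd_grad(value_of(cases[[nm]], X), X)
    expect_lt(max(abs(g - num)), 1e-5, label = nm)
  }
})

test_that("batch normalization gradients match finite differences", {
  set.seed(12)
  X <- matrix(rnorm(6 * 3), 6)
  gamma <- matrix(runif(3, 0.5, 1.5), 1)
  beta <- matrix(rnorm(3), 1)
  mk_state <- function() {
    st <- new.env(); st$mean <- rep(0, 3); st$var <- rep(1, 3); st
  }
  op <- function(t, x) molrgr:::tp_batchnorm(t, x, molrgr:::.tp_node(t, gamma),
                                             molrgr:::.tp_node(t, beta),
                                             mk_state(), training = TRUE)
  g <- tape_grad(op, X)
  num <- fd_grad(value_of(op, X), X)
  expect_lt(max(abs(g - num)), 1e-4)
})

test_that("info_nce matches its analytic values and a two-loop reference", {
  expect_equal(info_nce(matrix(rnorm(8), 1), matrix(rnorm(8), 1), 0.5), 0)
  expect_equal(info_nce(diag(2), diag(2), 1), log(1 + exp(-1)),
               tolerance = 1e-6)
  Z <- matrix(1, 8, 4)
  expect_equal(info_nce(Z, Z, 0.1), log(8), tolerance = 1e-9)

  ref_infonce <- function(X, Y, tau) {
    B <- nrow(X)
    cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    S <- matrix(0, B, B)
    for (i in 1:B) for (j in 1:B) S[i, j] <- cs(X[i, ], Y[j, ]) / tau
    tot <- 0
    for (i in 1:B) {
      tot <- tot + log(exp(S[i, i]) / sum(exp(S[i, ]))) +
        log(exp(S[i, i]) / sum(exp(S[, i])))
    }
    -tot / (2 * B)
  }
  set.seed(21)
  for (k in 1:20) {
    X <- matrix(rnorm(8 * 16), 8)
    Y <- matrix(rnorm(8 * 16), 8)
    tau <- runif(1, 0.05, 1)
    expect_equal(info_nce(X, Y, tau), ref_infonce(X, Y, tau),
                 tolerance = 1e-6)
  }
  expect_error(info_nce(matrix(0, 2, 3), matrix(0, 3, 3), 1), "dimension")
})

test_that("info_nce gradients match finite differences", {
  set.seed(22)
  X <- matrix(rnorm(5 * 6), 5)
  Y <- matrix(rnorm(5 * 6), 5)
  tape <- molrgr:::.new_tape()
  xn <- molrgr:::.tp_node(tape, X)
  xs <- molrgr:::tp_scale(tape, xn, 1)
  L <- molrgr:::tp_info_nce(tape, xs, molrgr:::.tp_node(tape, Y), 0.3)
  molrgr:::backward(tape, L)
  num <- fd_grad(function(Xi) info_nce(Xi, Y, 0.3), X)
  expect_lt(max(abs(xn$grad - num)), 1e-5)
})

test_that("masked regression and classification losses ignore missing labels", {
  set.seed(23)
  P <- matrix(rnorm(6), 3)
  Yr <- matrix(c(1, NA, 0, 2, -1, NA), 3)
  l <- molrgr:::.val(molrgr:::tp_mse_masked(NULL, molrgr:::.tp_node(NULL, P), Yr))
  expect_equal(l, mean((P[!is.na(Yr)] - Yr[!is.na(Yr)])^2))
  Yc <- matrix(c(1, NA, 0, 1, 0, NA), 3)
  lb <- molrgr:::.val(molrgr:::tp_bce_masked(NULL, molrgr:::.tp_node(NULL, P), Yc))
  p <- 1 / (1 + exp(-P))
  ok <- !is.na(Yc)
  expect_equal(lb, -mean(Yc[ok] * log(p[ok]) + (1 - Yc[ok]) * log(1 - p[ok])))
})

test_that("Adam reduces a quadratic and matches its bias-corrected update", {
  params <- list(w = matrix(c(5, -3), 1))
  st <- molrgr:::adam_init(params)
  for (i in 1:500) {
    g <- list(w = 2 * params$w)
    up <- molrgr:::adam_step(params, g, st, lr = 0.05)
    params <- up$params
    st <- up$state
  }
  expect_lt(max(abs(params$w)), 1e-3)
})
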