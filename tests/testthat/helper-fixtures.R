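# shared miniature fixtures, generated once per test run
fx <- make_fixtures(seed = 1)

# Moore-Penrose least squares used as an independent oracle for the
# Gram-form readout solutions
pinv_solve <- function(X, Y) {
  s <- svd(X)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], Y)) / s$d[pos])
}

# plain projected gradient descent, the independent oracle for the
# nonnegative readout QP
pg_nonneg_oracle <- function(H, y, iters = 3e5) {
  M <- nrow(H)
  w <- rep(0, M)
  b <- 0
  L <- 2 * max(eigen(crossprod(H) + 1, symmetric = TRUE,
                     only.values = TRUE)$values)
  for (i in seq_len(iters)) {
    r <- drop(crossprod(H, w)) + b - y
    w <- pmax(w - 2 * drop(H %*% r) / L, 0)
    b <- b - 2 * sum(r) / L
  }
  list(w = w, b = b, obj = sum((drop(crossprod(H, w)) + b - y)^2))
}

expansion_errors_over_grid <- function(ds, net, f_grid) {
  Ztr <- effective_weights(net) %*% t(ds$train_inputs)
  Zte <- effective_weights(net) %*% t(ds$test_inputs)
  vapply(f_grid, function(f) {
    th <- quantile(Ztr, 1 - f, names = FALSE)
    m <- fit_least_squares(pmax(Ztr - th, 0), ds$train_targets)
    evaluate_readout(m, pmax(Zte - th, 0), ds$test_targets, ds$task_kind)
  }, numeric(1))
}
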