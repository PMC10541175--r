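test_that("least squares interpolates realizable targets and is minimum-norm", {
  set.seed(1)
  H <- matrix(rnorm(200 * 50), 200, 50)
  w_star <- H %*% rnorm(50) # a weight vector in the row space of H'
  y <- drop(crossprod(H, w_star))
  m <- fit_least_squares(H, y)
  expect_lt(mean((drop(crossprod(H, m$w)) - y)^2), 1e-8)

  expect_equal(fit_least_squares(H, rep(0, 50))$w, matrix(0, 200, 1))

  # Gram-form solution agrees with the direct pseudo-inverse oracle
  Y <- matrix(rnorm(50 * 2), 50, 2)
  m2 <- fit_least_squares(H, Y)
  w_oracle <- pinv_solve(t(H), Y)
  expect_lt(max(abs(m2$w - w_oracle)), 1e-6)

  # wide-data branch (M < P) also matches the pseudo-inverse
  Hw <- matrix(rnorm(10 * 40), 10, 40)
  yw <- rnorm(40)
  expect_lt(max(abs(fit_least_squares(Hw, yw)$w - pinv_solve(t(Hw), yw))),
            1e-6)
})

test_that("ridge regression matches its closed form and limits", {
  set.seed(2)
  H <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(6)
  M <- nrow(H)
  for (a in c(1e-3, 0.1, 2)) {
    w_cf <- solve(tcrossprod(H) + diag(M * a, M), H %*% y)
    expect_lt(max(abs(fit_ridge(H, y, a)$w - w_cf)), 1e-8)
  }
  # alpha = 0 equals least squares on a full-rank problem
  Hf <- matrix(rnorm(5 * 20), 5, 20)
  yf <- rnorm(20)
  expect_equal(fit_ridge(Hf, yf, 0)$w, fit_least_squares(Hf, yf)$w)
  # alpha -> infinity shrinks to zero
  expect_lt(max(abs(fit_ridge(H, y, 1e8)$w)), 1e-6)
})

test_that("ridge training error is nondecreasing in the regularization", {
  set.seed(3)
  H <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(20)
  errs <- vapply(c(0, 1e-4, 1e-3, 1e-2, 0.1, 1, 10), function(a) {
    m <- fit_ridge(H, y, a)
    mean((drop(crossprod(H, m$w)) - y)^2)
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-10))
})

test_that("nonnegative readout solves the constrained program", {
  m0 <- fit_nonnegative(matrix(abs(rnorm(50)), 10, 5), rep(0, 5))
  expect_equal(max(abs(m0$w)), 0)
  expect_equal(m0$bias, 0)

  set.seed(4)
  H <- matrix(abs(rnorm(30 * 12)), 30, 12)
  w_star <- ifelse(runif(30) < 0.3, abs(rnorm(30)), 0)
  y <- drop(crossprod(H, w_star)) + 0.5
  m <- fit_nonnegative(H, y)
  expect_true(all(m$w >= -1e-9))
  obj_star <- sum((drop(crossprod(H, w_star)) + 0.5 - y)^2) # = 0, realizable
  expect_lte(m$objective, obj_star + 1e-8)

  # objective matches an independent projected-gradient oracle
  for (s in 1:3) {
    set.seed(10 + s)
    Hs <- matrix(abs(rnorm(20 * 10)), 20, 10)
    ys <- abs(rnorm(10))
    ms <- fit_nonnegative(Hs, ys)
    oracle <- pg_nonneg_oracle(Hs, ys)
    expect_lt(ms$objective, oracle$obj + 1e-6)
  }

  expect_error(fit_nonnegative(H, c(-1, rep(1, 11))), "nonnegative")
})

test_that("nonnegative training objective is bounded below by unconstrained", {
  set.seed(5)
  H <- matrix(abs(rnorm(40 * 15)), 40, 15)
  y <- abs(rnorm(15))
  m <- fit_nonnegative(H, y)
  Hb <- rbind(H, 1)
  mf <- fit_least_squares(Hb, y)
  obj_free <- sum((drop(crossprod(Hb, mf$w)) - y)^2)
  expect_gte(m$objective + 1e-10, obj_free)
})

test_that("silent fraction counts weights at zero", {
  expect_equal(silent_fraction(rep(0, 10)), 1)
  expect_equal(silent_fraction(rep(1, 10)), 0)
  expect_equal(silent_fraction(c(0, 0, 1, 2)), 0.5)
})

test_that("silent synapse fractions are substantial and task-ordered", {
  sf <- t(vapply(1:4, function(s) {
    netg <- expansion_network(M = 2000, D = 3, seed = 100 + s)
    gp <- sample_gp_task(80, 10, 3, 1, seed = 200 + s)
    netg <- calibrate_threshold(netg, gp$train_inputs, 0.3)
    mg <- fit_nonnegative(expand(netg, gp$train_inputs)$H,
                          abs(gp$train_targets[, 1]))
    netc <- expansion_network(M = 2000, D = 50, seed = 400 + s)
    ct <- sample_random_categorization(80, 50, 0.1, seed = 500 + s)
    Xc <- ct$train_inputs / sqrt(rowSums(ct$train_inputs^2))
    netc <- calibrate_threshold(netc, Xc, 0.3)
    mc <- fit_nonnegative(expand(netc, Xc)$H, (ct$train_targets[, 1] + 1) / 2)
    c(gp = silent_fraction(mg), cat = silent_fraction(mc))
  }, numeric(2)))
  expect_true(all(sf[, "gp"] > 0.2 & sf[, "gp"] < 0.9))
  expect_gt(mean(sf[, "cat"]), mean(sf[, "gp"]))
})

test_that("online climbing-fiber rule behaves like LMS", {
  H <- matrix(abs(rnorm(100 * 8)), 100, 8)
  m0 <- fit_online_cf(H, rep(0, 8), n_epochs = 50, seed = 1)
  expect_equal(max(abs(m0$w)), 0)

  # consistent realizable system: training error vanishes
  set.seed(6)
  H <- matrix(rnorm(200 * 10), 200, 10)
  y <- drop(crossprod(H, rnorm(200) / 10))
  m <- fit_online_cf(H, y, eta = 0.3 / 200, n_epochs = 3000, seed = 2)
  expect_lt(m$train_error, 1e-3)

  # test error close to the least-squares readout on the same data
  ds <- sample_gp_task(30, 200, 3, 1, seed = 5)
  net <- calibrate_threshold(expansion_network(M = 2000, D = 3, seed = 6),
                             ds$train_inputs, 0.3)
  Htr <- expand(net, ds$train_inputs)$H
  Hte <- expand(net, ds$test_inputs)$H
  mo <- fit_online_cf(Htr, ds$train_targets[, 1], n_epochs = 5000, seed = 7)
  ml <- fit_least_squares(Htr, ds$train_targets)
  eo <- evaluate_readout(mo, Hte, ds$test_targets, "continuous")
  el <- evaluate_readout(ml, Hte, ds$test_targets, "continuous")
  expect_lt(abs(eo - el) / el, 0.2)

  # divergence with an absurd learning rate is caught
  expect_error(fit_online_cf(Htr, ds$train_targets[, 1], eta = 10,
                             n_epochs = 500, seed = 8), "diverged")
})

test_that("evaluation metrics match their definitions", {
  H <- diag(4)
  y <- c(1, -2, 3, -4)
  m <- readout_model(diag(4) %*% y)
  expect_equal(evaluate_readout(m, H, y, "continuous"), 0)

  # all-zero predictor scores exactly 1 in relative MSE
  mz <- readout_model(rep(0, 4))
  expect_equal(evaluate_readout(mz, H, y, "continuous"), 1)

  # anti-correlated predictor misclassifies everything
  yc <- c(1, -1, 1, -1)
  mneg <- readout_model(diag(4) %*% (-yc))
  expect_equal(evaluate_readout(mneg, H, yc, "categorical"), 1)

  # sign(0) counts as +1
  expect_equal(evaluate_readout(mz, H, yc, "categorical"), mean(yc == -1))

  expect_error(evaluate_readout(mz, H, rep(0, 4), "continuous"), "zero")
})
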