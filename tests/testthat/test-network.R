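test_that("embeddings satisfy their structural invariants", {
  A <- make_embedding(3, 3, "distributed_orthonormal", seed = 1)
  expect_lt(max(abs(crossprod(A) - diag(3))), 1e-10)
  A2 <- make_embedding(1000, 3, "distributed_orthonormal", seed = 2)
  expect_lt(max(abs(crossprod(A2) - diag(3))), 1e-10)

  Ac <- make_embedding(6, 3, "clustered_blocks")
  expect_true(all(Ac %in% c(0, 1)))
  expect_equal(colSums(Ac), rep(2, 3))
  expect_equal(rowSums(Ac), rep(1, 6)) # blocks are disjoint

  expect_error(make_embedding(2, 3, "distributed_orthonormal"), "N >= D")
  expect_error(make_embedding(7, 3, "clustered_blocks"), "divide")
})

test_that("expansion weights follow the three connectivity models", {
  J <- make_expansion_weights(50, 10, K = 4, kind = "sparse_homogeneous",
                              seed = 3)
  expect_true(all(rowSums(J != 0) == 4))
  expect_true(all(rowSums(J) == 4))

  Ji <- make_expansion_weights(50, 10, K = 4, kind = "sparse_homogeneous",
                               global_inhibition = TRUE, seed = 3)
  expect_lt(abs(sum(Ji)), 1e-10)

  Jt <- make_expansion_weights(50, 10, K = 4, kind = "sparse_truncnorm",
                               seed = 4)
  expect_true(all(rowSums(Jt != 0) == 4))
  expect_true(all(Jt >= 0))

  Jd <- make_expansion_weights(1e4, 100, kind = "dense_gaussian", seed = 5)
  n <- length(Jd)
  expect_lt(abs(mean(Jd)), 3 / sqrt(n))
  expect_lt(abs(var(c(Jd)) - 1), 3 * sqrt(2 / n))

  expect_error(make_expansion_weights(10, 5, K = 9, kind = "sparse_homogeneous"),
               "K")
})

test_that("threshold calibration hits the requested coding level", {
  net <- expansion_network(M = 2000, D = 3, seed = 6)
  Xcal <- runif_sphere(500, 3, seed = 7)
  Xfresh <- runif_sphere(500, 3, seed = 8)

  n5 <- calibrate_threshold(net, Xcal, f = 0.5)
  expect_lt(abs(n5$theta), 0.02) # median of a standard normal

  n1 <- calibrate_threshold(net, Xcal, f = 0.1)
  expect_lt(abs(n1$theta - qnorm(0.9)), 0.02) # analytic dense-Gaussian oracle

  n3 <- calibrate_threshold(net, Xcal, f = 0.3)
  act <- expand(n3, Xfresh)
  expect_gt(act$measured_f, 0.29)
  expect_lt(act$measured_f, 0.31)

  expect_error(calibrate_threshold(net, matrix(0, 10, 3), 0.3), "degenerate")
  expect_error(calibrate_threshold(net, Xcal, 0), "f")
})

test_that("expansion activity follows the threshold-power nonlinearity", {
  net <- fx$networks$dense
  X <- runif_sphere(50, 3, seed = 9)
  silent <- expand(net, X, theta = 1e6)
  expect_true(all(silent$H == 0))
  expect_equal(silent$measured_f, 0)

  net1 <- calibrate_threshold(net, X, 0.4)
  net2 <- net1
  net2$power <- 2
  expect_equal(expand(net2, X)$H, expand(net1, X)$H^2)

  expect_error(expand(net1, matrix(0, 5, 7)), "dimension")
})

test_that("winner-take-all keeps exactly the top ceiling(f*M) units", {
  z <- matrix(c(5, 4, 3, 2, 1), 5, 1)
  act <- winner_take_all(z, 0.4)
  expect_equal(which(act$H > 0), c(1L, 2L))
  expect_equal(drop(act$H[1:2, 1]), c(2, 1)) # shifted by the cutoff (3)

  set.seed(10)
  Z <- matrix(rnorm(200 * 30), 200, 30)
  a <- winner_take_all(Z, 0.15)
  expect_true(all(colSums(a$H > 0) == ceiling(0.15 * 200)))

  # f = 1 reduces to rectification about the per-pattern minimum
  a1 <- winner_take_all(Z, 1)
  expect_equal(a1$H, sweep(Z, 2, apply(Z, 2, min), "-"))

  # ties among the winners resolve toward the lowest neuron index
  zt <- matrix(c(1, 2, 2, 0.5, 0), 5, 1)
  at <- winner_take_all(zt, 0.4)
  expect_equal(which(at$H > 0), c(2L, 3L))
  # a tie exactly at the cutoff keeps membership deterministic (the kept
  # units sit at the cutoff and carry zero activity)
  zb <- matrix(c(1, 2, 2, 2, 0), 5, 1)
  expect_identical(winner_take_all(zb, 0.4)$H, winner_take_all(zb, 0.4)$H)
  expect_true(all(winner_take_all(zb, 0.4)$H == 0))
})

test_that("coding level counts strictly positive activity", {
  expect_equal(coding_level(matrix(0, 4, 3)), 0)
  expect_equal(coding_level(matrix(1, 4, 3)), 1)
  H <- rbind(matrix(1, 2, 3), matrix(0, 2, 3))
  expect_equal(coding_level(H), 0.5)
  expect_error(coding_level(matrix(numeric(0), 0, 0)), "empty")
  expect_error(coding_level(matrix(-1, 2, 2)), "nonnegative")
})

test_that("participation dimension matches closed-form cases", {
  # all neurons identical and nonconstant: a single nonzero eigenvalue
  v <- c(1, 3, 2, 5, 4)
  expect_equal(participation_dimension(rbind(v, v, v)), 1)

  # two orthogonal equal-variance response patterns: d = 2 exactly
  H2 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(participation_dimension(H2), 2)

  expect_warning(d0 <- participation_dimension(matrix(1, 3, 4)), "zero")
  expect_equal(d0, 0)

  # M independent unit-variance neurons: d approaches M once P >> M
  # (the estimator is biased by a factor ~ 1/(1 + M/P) at finite P)
  H <- matrix(rnorm(500 * 10000), 500, 10000)
  d <- participation_dimension(H)
  expect_gt(d, 0.9 * 500)
  expect_lt(d, 1.1 * 500)
})

test_that("effective-weight correlations diagnose task-subspace sampling", {
  # dense Gaussian, D = 3: cosine similarities are uniform on [-1, 1]
  net <- expansion_network(M = 2000, D = 3, seed = 11)
  r <- effective_weight_correlations(net, n_pairs = 1e4, seed = 12)
  ks <- suppressWarnings(ks.test(r, "punif", -1, 1))
  expect_lt(unname(ks$statistic), 0.02)

  # identical rows are perfectly correlated
  netc <- net
  netc$Jeff <- matrix(rep(c(1, 2, 3), each = 50), 50, 3)
  expect_equal(effective_weight_correlations(netc, 100, seed = 1),
               rep(1, 100))

  # clustered embedding at small N: excess mass of near-duplicate tuning
  ncl <- expansion_network(M = 2000, D = 3, N = 999, K = 4,
                           weight_kind = "sparse_homogeneous",
                           embedding = "clustered_blocks", seed = 13)
  rc <- effective_weight_correlations(ncl, 1e4, seed = 14)
  expect_gt(mean(rc > 0.9), 0.05)
})

test_that("realistic sparse connectivity samples task variables like dense", {
  # N = 7000, K = 4 heterogeneous excitatory rows with global inhibition
  net_s <- expansion_network(M = 1500, D = 3, N = 7000, K = 4,
                             weight_kind = "sparse_truncnorm",
                             global_inhibition = TRUE, seed = 15)
  net_d <- expansion_network(M = 1500, D = 3, seed = 16)
  rs <- effective_weight_correlations(net_s, 1e4, seed = 17)
  rd <- effective_weight_correlations(net_d, 1e4, seed = 18)
  ks <- suppressWarnings(ks.test(rs, rd))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the empirical kernel converges to the analytic infinite-width kernel", {
  f <- 0.3
  rho_grid <- seq(-0.9, 0.9, by = 0.3)
  # input pairs with exact overlaps rho: x and rho x + sqrt(1-rho^2) y
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  X <- rbind(e1, t(vapply(rho_grid, function(r) r * e1 + sqrt(1 - r^2) * e2,
                          numeric(3))))
  M <- 2e5
  net <- expansion_network(M = M, D = 3, seed = 19)
  theta <- qnorm(1 - f)
  H <- expand(net, X, theta = theta)$H
  K_emp <- crossprod(H[, 1], H[, -1]) / M
  K_th <- analytic_kernel(rho_grid, theta)
  K1 <- analytic_kernel(1, theta)
  expect_lt(max(abs(K_emp - K_th)) / K1, 0.02)
})

test_that("dimension decreases with coding level for a fixed dense network", {
  net <- expansion_network(M = 5000, D = 3, seed = 20)
  X <- runif_sphere(800, 3, seed = 21)
  Z <- effective_weights(net) %*% t(X)
  dims <- vapply(seq(0.05, 0.5, by = 0.05), function(f) {
    participation_dimension(pmax(Z - quantile(Z, 1 - f, names = FALSE), 0))
  }, numeric(1))
  expect_true(all(diff(dims) < 0))
  expect_true(all(dims >= 1 & dims <= 800))
})
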