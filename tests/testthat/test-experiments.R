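small_gp_cfg <- function(...) {
  modifyList(list(
    task = list(family = "gp", D = 3, P = 20, P_test = 60, gamma = 1),
    network = list(M = 400),
    sweep = list(f_grid = c(0.05, 0.2, 0.4)),
    replication = list(n_seeds = 2, base_seed = 11)
  ), list(...))
}

test_that("sweeps are deterministic given the base seed", {
  r1 <- run_coding_level_sweep(small_gp_cfg())
  r2 <- run_coding_level_sweep(small_gp_cfg())
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "config_hash"), attr(r2, "config_hash"))

  d <- withr::local_tempdir()
  write_sweep_result(r1, file.path(d, "a.csv"))
  write_sweep_result(r2, file.path(d, "b.csv"))
  expect_identical(readBin(file.path(d, "a.csv"), "raw", 1e5),
                   readBin(file.path(d, "b.csv"), "raw", 1e5))

  # rows carry sem = sd/sqrt(n) of the per-seed errors
  errs <- attr(r1, "errors")
  expect_equal(r1$sem, apply(errs, 2, sd) / sqrt(2))
})

test_that("optimal coding level is located with ties, flats and boundaries", {
  fake <- function(err) {
    res <- data.frame(f = c(0.05, 0.15, 0.3), mean_error = err,
                      sem = rep(1e-3, 3), n_seeds = 5,
                      mean_coding_level = c(0.05, 0.15, 0.3))
    attr(res, "sweep_var") <- "f"
    class(res) <- c("sweep_result", "data.frame")
    res
  }
  o <- find_optimal_coding_level(fake(c(0.5, 0.2, 0.4)))
  expect_equal(o$optimum, 0.15)
  expect_false(o$boundary)

  flat <- find_optimal_coding_level(fake(c(0.3, 0.3, 0.3)))
  expect_true(flat$flat)
  expect_equal(flat$interval, c(0.05, 0.3))

  mono <- find_optimal_coding_level(fake(c(0.5, 0.4, 0.3)))
  expect_true(mono$boundary)
  expect_equal(mono$optimum, 0.3)

  # exact ties break toward the smaller coding level
  tie <- find_optimal_coding_level(fake(c(0.4, 0.2, 0.2)))
  expect_equal(tie$optimum, 0.15)
})

test_that("architecture sweeps respect their structural constraints", {
  cfg <- list(
    task = list(family = "gp", D = 3, P = 30, P_test = 60, gamma = 1),
    network = list(N = 20, weight_kind = "sparse_homogeneous",
                   global_inhibition = TRUE),
    sweep = list(type = "in_degree", S = 800, k_grid = c(2, 4, 8), f = 0.3),
    replication = list(n_seeds = 2, base_seed = 3))
  res <- run_architecture_sweep(cfg)
  expect_equal(res$K * res$M, rep(800, 3)) # S = M K held exactly
  expect_equal(res$K, c(2, 4, 8))
  expect_error(run_architecture_sweep(modifyList(cfg, list(
    sweep = list(type = "in_degree", S = 801, k_grid = c(2, 4), f = 0.3)))),
    "divide")

  cfg2 <- modifyList(cfg, list(
    network = list(N = 50, K = 4, weight_kind = "sparse_homogeneous",
                   global_inhibition = TRUE),
    sweep = list(type = "expansion_ratio", ratio_grid = c(2, 8), f = 0.3)))
  res2 <- run_architecture_sweep(cfg2)
  expect_equal(res2$expansion_ratio, c(2, 8))
})

test_that("in-degree optimum is small and expansion keeps helping", {
  ka <- run_architecture_sweep(
    modifyList(experiment_preset("indegree_sweep"),
               list(replication = list(n_seeds = 6, base_seed = 2))))
  expect_lte(find_optimal_coding_level(ka)$optimum, 8)

  mn <- run_architecture_sweep(
    modifyList(experiment_preset("expansion_ratio_sweep"),
               list(replication = list(n_seeds = 6, base_seed = 2))))
  # error non-increasing in M/N within pooled error bars
  slack <- 2 * sqrt(mn$sem[-1]^2 + mn$sem[-nrow(mn)]^2)
  expect_true(all(diff(mn$mean_error) <= slack))
})

test_that("input-layer baseline separates linear from nonlinear tasks", {
  # linearly realizable target: the baseline is essentially perfect
  set.seed(12)
  X <- runif_sphere(60, 4)
  Xt <- runif_sphere(60, 4)
  v <- rnorm(4)
  ds_lin <- task_dataset(X, X %*% v, Xt, Xt %*% v, task_kind = "continuous")
  expect_lt(input_layer_baseline(ds_lin), 1e-10)

  # quickly varying GP target: expansion beats the input layer by a margin
  ds <- sample_gp_task(60, 200, 3, gamma = 0.5, seed = 13)
  base_err <- input_layer_baseline(ds)
  net <- calibrate_threshold(expansion_network(M = 3000, D = 3, seed = 14),
                             ds$train_inputs, 0.2)
  m <- fit_least_squares(expand(net, ds$train_inputs)$H, ds$train_targets)
  exp_err <- evaluate_readout(m, expand(net, ds$test_inputs)$H,
                              ds$test_targets, "continuous")
  expect_gt(base_err, 5 * exp_err)

  expect_error(input_layer_baseline(fx$datasets$categorization), "continuous")
})

test_that("arm model optimum is denser than the mushroom-body optimum", {
  arm_cfg <- modifyList(experiment_preset("arm_forward_model"),
                        list(network = list(M = 5000),
                             replication = list(n_seeds = 4, base_seed = 21)))
  arm_opt <- find_optimal_coding_level(run_coding_level_sweep(arm_cfg))

  mb_cfg <- modifyList(experiment_preset("mushroom_body"),
                       list(network = list(M = 5000, N = 50, K = 7,
                                           weight_kind = "sparse_homogeneous",
                                           global_inhibition = TRUE),
                            replication = list(n_seeds = 4, base_seed = 21)))
  mb_opt <- find_optimal_coding_level(run_coding_level_sweep(mb_cfg))

  expect_gt(arm_opt$optimum, mb_opt$optimum)
  expect_lte(mb_opt$optimum, 0.1)

  # the expansion at its optimum beats a readout of the input layer
  ds <- sample_arm_task(100, 300, seed = 22)
  expect_gt(input_layer_baseline(ds), arm_opt$error)
})

test_that("VOR performance is high across a wide range of coding levels", {
  cfg <- modifyList(experiment_preset("vor"),
                    list(replication = list(n_seeds = 6, base_seed = 31)))
  res <- run_coding_level_sweep(cfg)
  sub <- res[res$f >= 0.05 & res$f <= 0.45, ]
  expect_lt(max(sub$mean_error) / min(sub$mean_error), 2)
  expect_lt(max(sub$mean_error), 1e-3) # tiny relative error throughout
})

test_that("theory-comparison driver pairs deterministic predictions with sims", {
  cfg <- list(task = list(family = "gp", D = 3, gamma = 0.5, P_test = 100),
              network = list(M = 5000),
              sweep = list(f_values = 0.3, P_grid = c(10, 30), k_max = 40),
              replication = list(n_seeds = 3, base_seed = 7))
  tc1 <- run_theory_comparison(cfg)
  tc2 <- run_theory_comparison(cfg)
  expect_identical(tc1$predicted, tc2$predicted)
  expect_identical(tc1$simulated, tc2$simulated)
  expect_equal(nrow(tc1), 2)
  expect_true(all(tc1$predicted > 0))
  expect_true(all(diff(tc1$simulated) < 0)) # more data, less error
})

test_that("fixture bundles are reproducible and valid", {
  fx2 <- make_fixtures(seed = 1)
  expect_identical(fx2$datasets, fx$datasets)
  expect_identical(fx2$networks$sparse_hom$Jeff, fx$networks$sparse_hom$Jeff)
  for (ds in fx$datasets) expect_silent(validate_task_dataset(ds))
  expect_true(all(fx$activity$H >= 0))
  # covers every connectivity kind
  kinds <- vapply(fx$networks, function(n) n$weight_kind, character(1))
  expect_setequal(unique(kinds),
                  c("dense_gaussian", "sparse_homogeneous", "sparse_truncnorm"))
})
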