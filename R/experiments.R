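#' Default coding-level grid
#'
#' Fourteen grid points on (0, 0.5\], denser near zero where the optima of
#' categorization-style tasks live.
#'
#' @return a numeric vector of coding levels.
#' @export
default_f_grid <- function() {
  c(0.005, 0.01, 0.02, 0.03, 0.05, 0.075, 0.1, 0.15,
    0.2, 0.25, 0.3, 0.35, 0.4, 0.5)
}

.default_config <- function() {
  list(
    task = list(family = "gp", D = 3, P = 30, P_test = 300, gamma = 1,
                epsilon = 0.1, n_points = 100),
    network = list(M = 10000, N = NULL, K = NULL,
                   weight_kind = "dense_gaussian",
                   embedding = "distributed_orthonormal",
                   global_inhibition = FALSE, power = 1, wta = FALSE),
    sweep = list(type = "coding_level", f_grid = default_f_grid(),
                 f = 0.3, S = NULL, k_grid = NULL, ratio_grid = NULL),
    replication = list(n_seeds = 10, base_seed = 1),
    readout = list(method = "lstsq", alpha_ridge = 0)
  )
}

.merge_config <- function(config) {
  base <- .default_config()
  for (blk in names(base)) {
    if (!is.null(config[[blk]])) base[[blk]] <- modifyList(base[[blk]], config[[blk]])
  }
  extra <- setdiff(names(config), names(base))
  if (length(extra)) stop("unknown config block(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  base
}

# order-independent fingerprint of a config, for provenance rows
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.build_task <- function(tc, seed) {
  switch(tc$family,
    categorization = sample_random_categorization(tc$P, tc$D, tc$epsilon, seed),
    gp = sample_gp_task(tc$P, tc$P_test, tc$D, tc$gamma, seed),
    arm = sample_arm_task(tc$P, tc$P_test, seed = seed),
    vor = sample_vor_task(NULL, tc$n_points, tc$P, seed),
    stop("unknown task family: ", tc$family, call. = FALSE))
}

.build_network <- function(nc, ds, seed, M = nc$M, K = nc$K, N = nc$N) {
  D_input <- ncol(ds$train_inputs)
  embedding <- nc$embedding
  if (ds$input_mode == "direct_input_layer") {
    embedding <- "identity"
    N <- D_input
  }
  expansion_network(M = M, D = D_input, N = N, K = K,
                    weight_kind = nc$weight_kind, embedding = embedding,
                    global_inhibition = nc$global_inhibition,
                    power = nc$power, seed = seed)
}

.fit_readout <- function(H, Y, readout) {
  switch(readout$method,
    lstsq = fit_least_squares(H, Y),
    ridge = fit_ridge(H, Y, readout$alpha_ridge),
    stop("sweep readout must be lstsq or ridge", call. = FALSE))
}

# evaluate one (task, network) pair across a coding-level grid, reusing the
# preactivations so the network is identical at every f
.sweep_over_f <- function(ds, net, f_grid, readout, wta = FALSE) {
  Ztr <- net$Jeff %*% t(ds$train_inputs)
  Zte <- net$Jeff %*% t(ds$test_inputs)
  out <- matrix(NA_real_, length(f_grid), 2,
                dimnames = list(NULL, c("error", "measured_f")))
  for (i in seq_along(f_grid)) {
    f <- f_grid[i]
    if (wta) {
      Htr <- winner_take_all(Ztr, f)$H
      Hte <- winner_take_all(Zte, f)$H
    } else {
      theta <- quantile(Ztr, probs = 1 - f, names = FALSE)
      Htr <- pmax(Ztr - theta, 0)
      Hte <- pmax(Zte - theta, 0)
      if (net$power != 1) {
        Htr <- Htr^net$power
        Hte <- Hte^net$power
      }
    }
    model <- .fit_readout(Htr, ds$train_targets, readout)
    out[i, "error"] <- evaluate_readout(model, Hte, ds$test_targets, ds$task_kind)
    out[i, "measured_f"] <- mean(Hte > 0)
  }
  out
}

.aggregate_sweep <- function(values, errors, mfs, config, sweep_var) {
  # errors, mfs: n_seeds x n_values matrices (NA for failed cells)
  n_ok <- colSums(is.finite(errors))
  if (sum(!is.finite(errors)) > 0.5 * length(errors))
    stop("more than 50% of sweep cells failed; aborting", call. = FALSE)
  res <- data.frame(
    value = values,
    mean_error = colMeans(errors, na.rm = TRUE),
    sem = apply(errors, 2, sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1)),
    n_seeds = n_ok,
    mean_coding_level = colMeans(mfs, na.rm = TRUE)
  )
  names(res)[1] <- sweep_var
  res <- res[order(res[[sweep_var]]), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "config") <- config
  attr(res, "config_hash") <- .config_hash(config)
  attr(res, "sweep_var") <- sweep_var
  attr(res, "errors") <- errors
  attr(res, "seeds") <- attr(errors, "seeds")
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> over %s (config %s)\n", attr(x, "sweep_var"),
              attr(x, "config_hash")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Run a coding-level sweep
#'
#' For every coding level on the grid and every replicate seed: generate
#' the task, build the network, set the threshold to the pooled-quantile
#' calibration for that f (or apply winner-take-all when the network config
#' requests it), fit the readout on training activity, and score the test
#' error. Within a replicate the same task and network are reused across
#' the whole f grid, so curves are paired. Each replicate draws its task
#' and network seeds from the base seed via [derive_seed()].
#'
#' @param config nested configuration list with blocks `task`, `network`,
#'   `sweep`, `replication`, `readout`; omitted entries take defaults (see
#'   [experiment_preset()] for ready-made configurations).
#' @return a `sweep_result` data.frame with columns `f`, `mean_error`,
#'   `sem`, `n_seeds`, `mean_coding_level`, plus provenance attributes
#'   (`config`, `config_hash`, per-seed error matrix `errors`).
#' @export
#' @examples
#' cfg <- list(task = list(family = "gp", P = 20, P_test = 50),
#'             network = list(M = 500),
#'             sweep = list(f_grid = c(0.05, 0.2, 0.4)),
#'             replication = list(n_seeds = 2, base_seed = 1))
#' run_coding_level_sweep(cfg)
run_coding_level_sweep <- function(config = list()) {
  cfg <- .merge_config(config)
  f_grid <- sort(cfg$sweep$f_grid)
  ns <- cfg$replication$n_seeds
  base <- cfg$replication$base_seed
  errors <- matrix(NA_real_, ns, length(f_grid))
  mfs <- matrix(NA_real_, ns, length(f_grid))
  seeds <- matrix(NA_integer_, ns, 2, dimnames = list(NULL, c("task", "network")))
  for (s in seq_len(ns)) {
    seeds[s, ] <- c(derive_seed(base, 1, s), derive_seed(base, 2, s))
    res <- tryCatch({
      ds <- .build_task(cfg$task, seeds[s, 1])
      net <- .build_network(cfg$network, ds, seeds[s, 2])
      .sweep_over_f(ds, net, f_grid, cfg$readout, wta = isTRUE(cfg$network$wta))
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", s, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      errors[s, ] <- res[, "error"]
      mfs[s, ] <- res[, "measured_f"]
    }
  }
  attr(errors, "seeds") <- seeds
  .aggregate_sweep(f_grid, errors, mfs, cfg, "f")
}

#' Locate the optimal coding level on a sweep curve
#'
#' Argmin of the mean error, with ties broken toward the smaller sweep
#' value. If the curve is flat relative to its pooled standard error the
#' whole flat interval is reported instead of a point; an optimum at either
#' end of the grid is flagged as a boundary solution.
#'
#' @param result a `sweep_result` from [run_coding_level_sweep()] or
#'   [run_architecture_sweep()].
#' @return a list with `optimum` (sweep value at the minimum), `error`,
#'   `resolution` (local grid spacing), `boundary`, `flat`, and `interval`
#'   (range of indistinguishable values when flat).
#' @export
find_optimal_coding_level <- function(result) {
  stopifnot(inherits(result, "sweep_result"), nrow(result) >= 3)
  v <- result[[attr(result, "sweep_var")]]
  err <- result$mean_error
  pooled_sem <- sqrt(mean(result$sem^2, na.rm = TRUE))
  i <- which.min(err) # first minimum: ties go to the smaller value
  flat <- (max(err) - min(err)) < pooled_sem
  spacing <- diff(v)
  res <- if (i == 1) spacing[1] else if (i == length(v)) spacing[length(spacing)]
         else max(spacing[i - 1], spacing[i])
  list(optimum = v[i], error = err[i], resolution = res,
       boundary = i %in% c(1L, length(v)), flat = flat,
       interval = if (flat) range(v) else c(v[i], v[i]))
}

#' Run an architecture sweep at fixed coding level
#'
#' Two sweep types mirror the anatomical questions: `"in_degree"` varies
#' the granule cell in-degree K while holding the total number of synaptic
#' connections S = M K fixed (so many small-degree neurons trade off
#' against fewer large-degree neurons), and `"expansion_ratio"` varies M/N
#' at fixed input-layer size N. The coding level is fixed at `sweep$f`.
#'
#' @param config nested configuration list; `sweep$type` selects the sweep,
#'   with `sweep$S` + `sweep$k_grid` or `sweep$ratio_grid` as the grid.
#' @return a `sweep_result` with first column `K` or `expansion_ratio`.
#' @export
run_architecture_sweep <- function(config = list()) {
  cfg <- .merge_config(config)
  type <- match.arg(cfg$sweep$type, c("in_degree", "expansion_ratio"))
  f <- cfg$sweep$f
  if (type == "in_degree") {
    S <- cfg$sweep$S
    grid <- sort(cfg$sweep$k_grid)
    if (is.null(S) || is.null(grid))
      stop("in_degree sweep needs sweep$S and sweep$k_grid", call. = FALSE)
    if (any(S %% grid != 0))
      stop("every K in k_grid must divide S = M*K", call. = FALSE)
    Ms <- S / grid
    Ks <- grid
    Ns <- rep(cfg$network$N, length(grid))
    var_name <- "K"
  } else {
    grid <- sort(cfg$sweep$ratio_grid)
    if (is.null(grid))
      stop("expansion_ratio sweep needs sweep$ratio_grid", call. = FALSE)
    Ms <- as.integer(round(grid * cfg$network$N))
    Ks <- rep(cfg$network$K %||% 4, length(grid))
    Ns <- rep(cfg$network$N, length(grid))
    var_name <- "expansion_ratio"
  }
  ns <- cfg$replication$n_seeds
  base <- cfg$replication$base_seed
  errors <- matrix(NA_real_, ns, length(grid))
  mfs <- matrix(NA_real_, ns, length(grid))
  seeds <- matrix(NA_integer_, ns, 2, dimnames = list(NULL, c("task", "network")))
  for (s in seq_len(ns)) {
    seeds[s, ] <- c(derive_seed(base, 1, s), derive_seed(base, 2, s))
    ds <- tryCatch(.build_task(cfg$task, seeds[s, 1]), error = function(e) {
      warning(sprintf("replicate %d task failed: %s", s, conditionMessage(e)))
      NULL
    })
    if (is.null(ds)) next
    for (g in seq_along(grid)) {
      res <- tryCatch({
        net <- .build_network(cfg$network, ds, derive_seed(base, 2, s, g),
                              M = Ms[g], K = Ks[g], N = Ns[g])
        .sweep_over_f(ds, net, f, cfg$readout, wta = isTRUE(cfg$network$wta))
      }, error = function(e) {
        warning(sprintf("replicate %d, %s=%g failed: %s", s, var_name,
                        grid[g], conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        errors[s, g] <- res[1, "error"]
        mfs[s, g] <- res[1, "measured_f"]
      }
    }
  }
  attr(errors, "seeds") <- seeds
  out <- .aggregate_sweep(grid, errors, mfs, cfg, var_name)
  if (type == "in_degree") out$M <- S / out$K
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate generalization error of a wide expansion by kernel-form regression
#'
#' Builds a dense-Gaussian expansion of size M for the dataset, calibrates
#' the threshold to coding level f, fits the minimum-norm least-squares
#' readout in Gram form and returns the test error. The expansion is
#' generated in neuron chunks and only the pattern-by-pattern Gram matrices
#' are accumulated, so M can be large (hundreds of thousands) in modest
#' memory.
#'
#' @param ds a [task_dataset()] with `task_subspace` inputs.
#' @param M expansion size.
#' @param f coding level.
#' @param power nonlinearity exponent.
#' @param chunk neurons per chunk.
#' @param seed optional RNG seed for the expansion weights.
#' @return a list with `error`, `measured_f` (on the test set) and `theta`.
#' @export
simulate_expansion_regression <- function(ds, M, f, power = 1, chunk = 2e4,
                                          seed = NULL) {
  stopifnot(inherits(ds, "task_dataset"))
  .assert_scalar(M, "M", lower = 1, integer = TRUE)
  .assert_scalar(f, "f", lower = 0, upper = 1, strict = TRUE)
  .set_seed_if(seed)
  Xt <- t(rbind(ds$train_inputs, ds$test_inputs))
  D <- nrow(Xt)
  n_tr <- nrow(ds$train_inputs)
  n_te <- nrow(ds$test_inputs)
  idx_tr <- seq_len(n_tr)
  idx_te <- n_tr + seq_len(n_te)
  G <- matrix(0, n_tr, n_tr)
  Cx <- matrix(0, n_te, n_tr)
  theta <- NULL
  active_te <- 0
  done <- 0L
  while (done < M) {
    mc <- min(chunk, M - done)
    Z <- matrix(rnorm(mc * D), mc, D) %*% Xt
    if (is.null(theta))
      theta <- quantile(Z[, idx_tr], probs = 1 - f, names = FALSE)
    H <- pmax(Z - theta, 0)
    if (power != 1) H <- H^power
    Htr <- H[, idx_tr, drop = FALSE]
    Hte <- H[, idx_te, drop = FALSE]
    G <- G + crossprod(Htr)
    Cx <- Cx + crossprod(Hte, Htr)
    active_te <- active_te + sum(Hte > 0)
    done <- done + mc
  }
  alpha <- .psd_solve(G, ds$train_targets)
  pred <- Cx %*% alpha
  Y <- ds$test_targets
  err <- if (ds$task_kind == "categorical") {
    mean(ifelse(pred >= 0, 1, -1) != Y)
  } else {
    mean(colMeans((Y - pred)^2) / colMeans(Y^2))
  }
  list(error = err, measured_f = active_te / (M * n_te), theta = theta)
}

#' Compare analytic error predictions with simulated networks
#'
#' For each Gaussian-process length scale, coding level and training-set
#' size, computes the analytic generalization-error prediction from the
#' kernel and target spectra and pairs it with simulated wide-network
#' least-squares errors averaged over seeds.
#'
#' @param config list with `task` (`gamma` may be a vector, `D`, `P_test`),
#'   `network` (`M`), `sweep` (`f_values`, `P_grid`, `k_max`), and
#'   `replication` blocks.
#' @return a data.frame with one row per (gamma, f, P): `predicted`,
#'   `simulated`, `sem`, `n_seeds`. Predictions are deterministic.
#' @export
run_theory_comparison <- function(config = list()) {
  cfg <- .merge_config(config)
  gammas <- cfg$task$gamma
  f_values <- cfg$sweep$f_values %||% c(0.1, 0.3)
  P_grid <- cfg$sweep$P_grid %||% c(10, 30, 100)
  k_max <- cfg$sweep$k_max %||% if (cfg$task$D <= 3) 60 else 25
  ns <- cfg$replication$n_seeds
  base <- cfg$replication$base_seed
  rows <- list()
  for (f in f_values) {
    kspec <- kernel_eigenvalues(kernel_model(f = f), cfg$task$D, k_max)
    for (gam in gammas) {
      tspec <- gp_target_spectrum(gam, cfg$task$D, k_max)
      for (P in P_grid) {
        pred <- predict_generalization_error(kspec, tspec, P)$error
        errs <- rep(NA_real_, ns)
        for (s in seq_len(ns)) {
          tc <- cfg$task
          tc$gamma <- gam
          tc$P <- P
          ds <- .build_task(tc, derive_seed(base, 1, s, P * 1000 + round(f * 100)))
          errs[s] <- simulate_expansion_regression(
            ds, cfg$network$M, f, power = cfg$network$power,
            seed = derive_seed(base, 2, s, P * 1000 + round(f * 100)))$error
        }
        rows[[length(rows) + 1]] <- data.frame(
          gamma = gam, f = f, P = P, predicted = pred,
          simulated = mean(errs, na.rm = TRUE),
          sem = sd(errs, na.rm = TRUE) / sqrt(sum(is.finite(errs))),
          n_seeds = sum(is.finite(errs)))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  attr(out, "config_hash") <- .config_hash(cfg)
  out
}

#' Least-squares readout of the input layer
#'
#' Baseline for how much of a continuous task is solvable without the
#' expansion: fit the readout directly on the input activity (the task
#' variables, or the mossy fiber-like activities for direct-input tasks)
#' and score the same relative error.
#'
#' @param ds a continuous [task_dataset()].
#' @return the scalar test error.
#' @export
input_layer_baseline <- function(ds) {
  stopifnot(inherits(ds, "task_dataset"))
  if (ds$task_kind != "continuous")
    stop("input-layer baseline is defined for continuous tasks", call. = FALSE)
  model <- fit_least_squares(t(ds$train_inputs), ds$train_targets)
  evaluate_readout(model, t(ds$test_inputs), ds$test_targets, "continuous")
}

#' Named experiment presets
#'
#' Ready-made configurations for the standard simulation conditions:
#' \describe{
#'   \item{categorization_dense}{random categorization, dense Gaussian
#'     weights, M = 10,000, D = 50, P = 1,000, epsilon = 0.1.}
#'   \item{gp_dense}{Gaussian-process target (gamma = 1 by default),
#'     dense Gaussian weights, M = 200,000, D = 3, P = 30.}
#'   \item{gp_sparse}{as gp_dense but sparse excitatory connectivity with
#'     global inhibition, N = 7,000, K = 4.}
#'   \item{gp_clustered}{as gp_sparse but a clustered (one task variable
#'     per input-neuron block) embedding, winner-take-all coding-level
#'     control, no global inhibition; N = 6,999 so D = 3 divides N.}
#'   \item{mushroom_body}{Kenyon cell-like model: M = 10,000, N = 50
#'     projection neurons, K = 7, global inhibition, random odor
#'     categorization with D = 50, P = 100, epsilon = 0.1.}
#'   \item{arm_forward_model}{two-joint-arm hand-position prediction,
#'     M = 20,000, D = 6, P = 100.}
#'   \item{vor}{vestibulo-ocular reflex adaptation: 24 mossy fiber tuning
#'     curves as direct input, M = 20,000, the 25-target slope battery,
#'     P = 30.}
#'   \item{indegree_sweep}{in-degree K sweep at fixed S = M K = 10,000,
#'     N = 100, f = 0.3, GP targets with D = 3, P = 200.}
#'   \item{expansion_ratio_sweep}{M/N sweep at N = 700, K = 4, f = 0.3,
#'     GP targets with D = 3, P = 200.}
#'   \item{nonneg_gp}{network/task pair for nonnegative-readout weight
#'     distributions: M = 5,000, f = 0.3, GP with D = 3, P = 100,
#'     gamma = 1.}
#' }
#'
#' @param name preset name.
#' @param scale divide the expansion size M and the number of seeds by this
#'   factor for quick runs (>= 1; defaults to 1 = full scale).
#' @return a config list for [run_coding_level_sweep()] /
#'   [run_architecture_sweep()].
#' @export
experiment_preset <- function(name = c("categorization_dense", "gp_dense",
                                       "gp_sparse", "gp_clustered",
                                       "mushroom_body", "arm_forward_model",
                                       "vor", "indegree_sweep",
                                       "expansion_ratio_sweep", "nonneg_gp"),
                              scale = 1) {
  name <- match.arg(name)
  .assert_scalar(scale, "scale", lower = 1)
  cfg <- switch(name,
    categorization_dense = list(
      task = list(family = "categorization", D = 50, P = 1000, epsilon = 0.1),
      network = list(M = 10000),
      replication = list(n_seeds = 20)),
    gp_dense = list(
      task = list(family = "gp", D = 3, P = 30, P_test = 500, gamma = 1),
      network = list(M = 200000),
      replication = list(n_seeds = 200)),
    gp_sparse = list(
      task = list(family = "gp", D = 3, P = 30, P_test = 500, gamma = 1),
      network = list(M = 200000, N = 7000, K = 4,
                     weight_kind = "sparse_homogeneous",
                     global_inhibition = TRUE),
      replication = list(n_seeds = 200)),
    gp_clustered = list(
      task = list(family = "gp", D = 3, P = 30, P_test = 500, gamma = 1),
      network = list(M = 200000, N = 6999, K = 4,
                     weight_kind = "sparse_homogeneous",
                     embedding = "clustered_blocks",
                     global_inhibition = FALSE, wta = TRUE),
      replication = list(n_seeds = 100)),
    mushroom_body = list(
      task = list(family = "categorization", D = 50, P = 100, epsilon = 0.1),
      network = list(M = 10000, N = 50, K = 7,
                     weight_kind = "sparse_homogeneous",
                     global_inhibition = TRUE),
      replication = list(n_seeds = 20)),
    arm_forward_model = list(
      task = list(family = "arm", P = 100, P_test = 200),
      network = list(M = 20000),
      replication = list(n_seeds = 10)),
    vor = list(
      task = list(family = "vor", P = 30, n_points = 100),
      network = list(M = 20000),
      replication = list(n_seeds = 10)),
    indegree_sweep = list(
      task = list(family = "gp", D = 3, P = 200, P_test = 500, gamma = 1),
      network = list(N = 100, weight_kind = "sparse_homogeneous",
                     global_inhibition = TRUE),
      sweep = list(type = "in_degree", S = 10000,
                   k_grid = c(1, 2, 4, 8, 20, 40), f = 0.3),
      replication = list(n_seeds = 10)),
    expansion_ratio_sweep = list(
      task = list(family = "gp", D = 3, P = 200, P_test = 500, gamma = 1),
      network = list(N = 700, K = 4, weight_kind = "sparse_homogeneous",
                     global_inhibition = TRUE),
      sweep = list(type = "expansion_ratio",
                   ratio_grid = c(1, 2, 4, 8, 16, 32), f = 0.3),
      replication = list(n_seeds = 10)),
    nonneg_gp = list(
      task = list(family = "gp", D = 3, P = 100, P_test = 300, gamma = 1),
      network = list(M = 5000),
      sweep = list(f_grid = 0.3),
      replication = list(n_seeds = 10))
  )
  if (scale > 1) {
    if (!is.null(cfg$network$M))
      cfg$network$M <- max(100L, as.integer(round(cfg$network$M / scale)))
    if (!is.null(cfg$sweep$S))
      cfg$sweep$S <- max(100L, as.integer(round(cfg$sweep$S / scale)))
    cfg$replication$n_seeds <-
      max(2L, as.integer(round(cfg$replication$n_seeds / scale)))
  }
  cfg
}

#' Write a sweep result (and its provenance) to CSV
#'
#' @param result a `sweep_result`.
#' @param path CSV file path; a sibling `<path>.json` stores the config,
#'   hash and per-replicate seeds.
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  data.table::fwrite(as.data.frame(result), path)
  meta <- list(config = attr(result, "config"),
               config_hash = attr(result, "config_hash"),
               seeds = attr(result, "seeds"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
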