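#' Construct a task dataset
#'
#' Container for a supervised learning task posed to an expansion-layer
#' network: train/test inputs living either in the D-dimensional task
#' subspace or directly in input-layer (mossy fiber-like) activity, together
#' with continuous or binary targets.
#'
#' @param train_inputs P x D numeric matrix of training inputs.
#' @param train_targets P x Q numeric matrix (vectors are accepted).
#' @param test_inputs P_test x D numeric matrix.
#' @param test_targets P_test x Q numeric matrix.
#' @param task_kind `"categorical"` (targets in -1/+1) or `"continuous"`.
#' @param input_mode `"task_subspace"` if inputs are task variables to be
#'   embedded by the network, `"direct_input_layer"` if they already are
#'   input-layer activities.
#' @param metadata named list of generator parameters (D, P, seed, ...).
#' @return an object of class `task_dataset`.
#' @export
task_dataset <- function(train_inputs, train_targets, test_inputs, test_targets,
                         task_kind = c("continuous", "categorical"),
                         input_mode = c("task_subspace", "direct_input_layer"),
                         metadata = list()) {
  task_kind <- match.arg(task_kind)
  input_mode <- match.arg(input_mode)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)
  ds <- structure(list(
    train_inputs = as_mat(train_inputs), train_targets = as_mat(train_targets),
    test_inputs = as_mat(test_inputs), test_targets = as_mat(test_targets),
    task_kind = task_kind, input_mode = input_mode, metadata = metadata
  ), class = "task_dataset")
  validate_task_dataset(ds)
  ds
}

#' Validate the internal consistency of a task dataset
#'
#' Checks mutually consistent shapes and, for categorical tasks, that all
#' targets are exactly -1 or +1.
#'
#' @param ds a [task_dataset()].
#' @return `ds`, invisibly; errors if an invariant is violated.
#' @export
validate_task_dataset <- function(ds) {
  stopifnot(inherits(ds, "task_dataset"))
  if (ncol(ds$train_inputs) != ncol(ds$test_inputs))
    stop("train and test inputs have inconsistent dimension", call. = FALSE)
  if (ncol(ds$train_targets) != ncol(ds$test_targets))
    stop("train and test targets have inconsistent dimension", call. = FALSE)
  if (nrow(ds$train_inputs) != nrow(ds$train_targets))
    stop("train inputs/targets have different numbers of patterns", call. = FALSE)
  if (nrow(ds$test_inputs) != nrow(ds$test_targets))
    stop("test inputs/targets have different numbers of patterns", call. = FALSE)
  if (!all(is.finite(ds$train_inputs)) || !all(is.finite(ds$test_inputs)) ||
      !all(is.finite(ds$train_targets)) || !all(is.finite(ds$test_targets)))
    stop("task dataset contains non-finite values", call. = FALSE)
  if (ds$task_kind == "categorical" &&
      !all(abs(ds$train_targets) == 1 & abs(ds$test_targets) == 1))
    stop("categorical targets must take values in {-1, +1}", call. = FALSE)
  invisible(ds)
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> %s, %s\n", x$task_kind, x$input_mode))
  cat(sprintf("  train: %d x %d inputs, %d target dim(s)\n",
              nrow(x$train_inputs), ncol(x$train_inputs), ncol(x$train_targets)))
  cat(sprintf("  test:  %d patterns\n", nrow(x$test_inputs)))
  if (length(x$metadata))
    cat("  params:", paste(names(x$metadata),
                           vapply(x$metadata, function(v)
                             paste(format(v, digits = 4), collapse = ","),
                             character(1)),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sample a random categorization task
#'
#' Training inputs are P random patterns in D dimensions with i.i.d.
#' normal(0, 1/D) entries, each assigned a random binary category +1/-1.
#' Test patterns probe generalization to noisy copies of the training
#' patterns: `x_test = sqrt(1 - epsilon^2) * x + epsilon * eta` with `eta`
#' again normal(0, 1/D), one test pattern per training pattern, carrying the
#' training pattern's label. `epsilon = 0` reproduces the training set;
#' `epsilon = 1` gives fresh unrelated patterns.
#'
#' @param P number of input-category associations.
#' @param D input dimension.
#' @param epsilon test noise magnitude in \[0, 1\].
#' @param seed optional RNG seed.
#' @return a categorical [task_dataset()].
#' @export
#' @examples
#' ds <- sample_random_categorization(P = 20, D = 10, epsilon = 0.1, seed = 1)
sample_random_categorization <- function(P, D, epsilon = 0.1, seed = NULL) {
  .assert_scalar(P, "P", lower = 1, integer = TRUE)
  .assert_scalar(D, "D", lower = 1, integer = TRUE)
  .assert_scalar(epsilon, "epsilon", lower = 0, upper = 1)
  .set_seed_if(seed)
  X <- matrix(rnorm(P * D, sd = sqrt(1 / D)), P, D)
  y <- sample(c(-1, 1), P, replace = TRUE)
  eta <- matrix(rnorm(P * D, sd = sqrt(1 / D)), P, D)
  Xt <- sqrt(1 - epsilon^2) * X + epsilon * eta
  task_dataset(X, y, Xt, y, task_kind = "categorical",
               metadata = list(family = "categorization", D = D, P = P,
                               epsilon = epsilon, seed = seed))
}

#' Sample a Gaussian-process regression task on the unit sphere
#'
#' Inputs are drawn uniformly on the unit sphere in D dimensions; the target
#' function is one joint draw from a zero-mean Gaussian process with
#' squared-exponential covariance
#' `C(x, x') = exp(-||x - x'||^2 / (2 gamma^2))` over the union of train and
#' test points. Small `gamma` produces quickly varying targets, large `gamma`
#' slowly varying (nearly constant) ones.
#'
#' @param P_train,P_test numbers of training and test patterns.
#' @param D input dimension (>= 2).
#' @param gamma GP length scale (> 0).
#' @param seed optional RNG seed.
#' @return a continuous [task_dataset()] with unit-norm inputs.
#' @export
#' @examples
#' ds <- sample_gp_task(P_train = 30, P_test = 50, D = 3, gamma = 1, seed = 1)
sample_gp_task <- function(P_train, P_test, D, gamma, seed = NULL) {
  .assert_scalar(P_train, "P_train", lower = 1, integer = TRUE)
  .assert_scalar(P_test, "P_test", lower = 1, integer = TRUE)
  .assert_scalar(D, "D", lower = 2, integer = TRUE)
  .assert_scalar(gamma, "gamma", lower = 0, strict = TRUE)
  .set_seed_if(seed)
  n <- P_train + P_test
  X <- .runif_sphere(n, D)
  sq <- as.matrix(stats::dist(X))^2
  C <- exp(-sq / (2 * gamma^2))
  f <- .gp_draw(C)
  task_dataset(X[seq_len(P_train), , drop = FALSE], f[seq_len(P_train)],
               X[P_train + seq_len(P_test), , drop = FALSE], f[P_train + seq_len(P_test)],
               task_kind = "continuous",
               metadata = list(family = "gp", D = D, P = P_train,
                               P_test = P_test, gamma = gamma, seed = seed))
}

# one joint GP draw given a covariance matrix; Cholesky with escalating jitter
.gp_draw <- function(C) {
  n <- nrow(C)
  jitter <- 1e-10
  for (attempt in 0:3) {
    L <- tryCatch(chol(C + diag(jitter, n)), error = function(e) NULL)
    if (!is.null(L)) return(drop(crossprod(L, rnorm(n))))
    jitter <- jitter * 10
  }
  stop(sprintf(paste0("GP covariance Cholesky failed even with jitter %.1e; ",
                      "points may be (near-)duplicated"), jitter), call. = FALSE)
}
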