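#' Build an input-layer embedding matrix
#'
#' Embeds D task variables into the activity of N input-layer (mossy
#' fiber-like) neurons. The `distributed_orthonormal` kind samples a random
#' N x D matrix with orthonormal columns, so every input neuron responds to
#' a random combination of task variables while the task-subspace geometry
#' is preserved. The `clustered_blocks` kind assigns each task variable a
#' disjoint block of N/D input neurons with 0/1 entries, so each input
#' neuron encodes a single task variable.
#'
#' @param N number of input-layer neurons (N >= D; for clustered embeddings
#'   D must divide N).
#' @param D number of task variables.
#' @param kind `"distributed_orthonormal"` or `"clustered_blocks"`.
#' @param seed optional RNG seed.
#' @return an N x D matrix with attribute `"kind"`.
#' @export
#' @examples
#' A <- make_embedding(12, 3, "distributed_orthonormal", seed = 1)
#' max(abs(crossprod(A) - diag(3))) < 1e-10
make_embedding <- function(N, D,
                           kind = c("distributed_orthonormal", "clustered_blocks"),
                           seed = NULL) {
  kind <- match.arg(kind)
  .assert_scalar(N, "N", lower = 1, integer = TRUE)
  .assert_scalar(D, "D", lower = 1, integer = TRUE)
  if (N < D) stop("embedding requires N >= D", call. = FALSE)
  .set_seed_if(seed)
  if (kind == "distributed_orthonormal") {
    A <- qr.Q(qr(matrix(rnorm(N * D), N, D)))
  } else {
    if (N %% D != 0)
      stop("clustered embedding requires D to divide N", call. = FALSE)
    A <- matrix(0, N, D)
    b <- N / D
    for (j in seq_len(D)) A[(j - 1) * b + seq_len(b), j] <- 1
  }
  attr(A, "kind") <- kind
  A
}

# sparse excitatory connectivity: exactly K nonzeros per row at uniformly
# random positions; values 1 (homogeneous) or |N(0,1)| (truncated normal,
# i.e. a standard normal conditioned on nonnegativity)
.sample_sparse_excitatory <- function(M, N, K, heterogeneous) {
  j <- unlist(lapply(seq_len(M), function(i) sample.int(N, K)))
  x <- if (heterogeneous) abs(rnorm(M * K)) else rep(1, M * K)
  Matrix::sparseMatrix(i = rep(seq_len(M), each = K), j = j, x = x,
                       dims = c(M, N))
}

#' Sample input-to-expansion-layer weights
#'
#' Three connectivity models for the M x N weight matrix J:
#' `dense_gaussian` has i.i.d. unit normal entries; `sparse_homogeneous`
#' places exactly K nonzero entries equal to 1 in each row at random
#' positions; `sparse_truncnorm` draws the K nonzero entries from a unit
#' truncated normal (a standard normal conditioned on being nonnegative).
#' With `global_inhibition`, the grand mean of the excitatory matrix is
#' subtracted from every entry, balancing excitation so the summed weight
#' is zero.
#'
#' @param M,N expansion- and input-layer sizes.
#' @param K in-degree for the sparse kinds (1 <= K <= N).
#' @param kind connectivity model.
#' @param global_inhibition subtract the grand-mean excitatory weight?
#' @param seed optional RNG seed.
#' @return a dense M x N matrix.
#' @export
make_expansion_weights <- function(M, N, K = NULL,
                                   kind = c("dense_gaussian", "sparse_homogeneous",
                                            "sparse_truncnorm"),
                                   global_inhibition = FALSE, seed = NULL) {
  kind <- match.arg(kind)
  .assert_scalar(M, "M", lower = 1, integer = TRUE)
  .assert_scalar(N, "N", lower = 1, integer = TRUE)
  .set_seed_if(seed)
  if (kind == "dense_gaussian") {
    J <- matrix(rnorm(M * N), M, N)
    if (global_inhibition) J <- J - mean(J)
    return(J)
  }
  if (is.null(K)) stop("sparse connectivity requires an in-degree K", call. = FALSE)
  .assert_scalar(K, "K", lower = 1, upper = N, integer = TRUE)
  JE <- .sample_sparse_excitatory(M, N, K, kind == "sparse_truncnorm")
  J <- as.matrix(JE)
  if (global_inhibition) J <- J - sum(JE) / (M * N)
  J
}

#' Construct an expansion-layer network
#'
#' Builds the full model granule cell layer: an embedding `A` of D task
#' variables into N input neurons (or the identity for tasks whose inputs
#' are already input-layer activities), input-to-expansion weights `J`, a
#' shared activation threshold `theta`, and a threshold-power nonlinearity
#' `phi(u) = max(u, 0)^power`. The effective weights `Jeff = J A` (M x D)
#' are materialized once; all activity computations use them.
#'
#' When `weight_kind = "dense_gaussian"` and `N` is `NULL`, the effective
#' weights are sampled directly as an M x D unit Gaussian matrix, which is
#' distribution-equivalent to dense Gaussian J combined with any orthonormal
#' embedding and independent of N.
#'
#' @param M expansion-layer size.
#' @param D number of task variables (input dimension seen by the network).
#' @param N input-layer size (optional for dense Gaussian weights).
#' @param K in-degree for sparse connectivity.
#' @param weight_kind one of `"dense_gaussian"`, `"sparse_homogeneous"`,
#'   `"sparse_truncnorm"`.
#' @param embedding `"distributed_orthonormal"`, `"clustered_blocks"`, or
#'   `"identity"` (requires `N == D`; used for direct input-layer tasks).
#' @param global_inhibition balance excitation with global feedforward
#'   inhibition (subtract the grand-mean excitatory weight)?
#' @param power nonlinearity exponent p >= 1 (rectified linear for p = 1).
#' @param theta initial shared threshold (typically set later by
#'   [calibrate_threshold()]).
#' @param seed optional RNG seed controlling both embedding and weights.
#' @return an object of class `expansion_network` with elements `Jeff`, `A`,
#'   `theta`, `power`, `target_f` and the constructor arguments.
#' @export
#' @examples
#' net <- expansion_network(M = 100, D = 3, seed = 1)
expansion_network <- function(M, D, N = NULL, K = NULL,
                              weight_kind = c("dense_gaussian", "sparse_homogeneous",
                                              "sparse_truncnorm"),
                              embedding = c("distributed_orthonormal",
                                            "clustered_blocks", "identity"),
                              global_inhibition = FALSE, power = 1,
                              theta = NA_real_, seed = NULL) {
  weight_kind <- match.arg(weight_kind)
  embedding <- match.arg(embedding)
  .assert_scalar(M, "M", lower = 1, integer = TRUE)
  .assert_scalar(D, "D", lower = 1, integer = TRUE)
  .assert_scalar(power, "power", lower = 1, integer = TRUE)
  .set_seed_if(seed)
  A <- NULL
  if (weight_kind == "dense_gaussian" && is.null(N)) {
    # direct Gaussian effective weights; geometry independent of N
    Jeff <- matrix(rnorm(M * D), M, D)
    N <- D
    embedding <- "identity"
  } else {
    if (is.null(N)) stop("sparse connectivity requires N", call. = FALSE)
    .assert_scalar(N, "N", lower = 1, integer = TRUE)
    if (embedding == "identity") {
      if (N != D) stop("identity embedding requires N == D", call. = FALSE)
    } else {
      A <- make_embedding(N, D, embedding)
    }
    if (weight_kind == "dense_gaussian") {
      J <- matrix(rnorm(M * N), M, N)
      Jeff <- if (is.null(A)) J else J %*% A
      if (global_inhibition) {
        jbar <- mean(J)
        Jeff <- Jeff - tcrossprod(rep(jbar, M),
                                  if (is.null(A)) rep(1, N) else colSums(A))
      }
    } else {
      if (is.null(K)) stop("sparse connectivity requires K", call. = FALSE)
      .assert_scalar(K, "K", lower = 1, upper = N, integer = TRUE)
      JE <- .sample_sparse_excitatory(M, N, K, weight_kind == "sparse_truncnorm")
      Jeff <- as.matrix(JE %*% (if (is.null(A)) diag(N) else A))
      if (global_inhibition) {
        jbar <- sum(JE) / (M * N) # grand mean of the excitatory matrix
        csA <- if (is.null(A)) rep(1, N) else colSums(A)
        Jeff <- Jeff - tcrossprod(rep(jbar, M), csA)
      }
    }
  }
  structure(list(Jeff = Jeff, A = A, M = M, N = N, D = D, K = K,
                 weight_kind = weight_kind, embedding = embedding,
                 global_inhibition = global_inhibition, power = power,
                 theta = theta, target_f = NA_real_, seed = seed),
            class = "expansion_network")
}

#' @export
print.expansion_network <- function(x, ...) {
  cat(sprintf("<expansion_network> M=%d, N=%d, D=%d, %s%s, embedding=%s\n",
              x$M, x$N, x$D, x$weight_kind,
              if (!is.null(x$K)) sprintf(" (K=%d)", x$K) else "",
              x$embedding))
  cat(sprintf("  power=%d, theta=%s, target coding level=%s%s\n", x$power,
              format(x$theta, digits = 4), format(x$target_f, digits = 4),
              if (x$global_inhibition) ", global inhibition" else ""))
  invisible(x)
}

#' Effective weights of an expansion network
#'
#' @param network an [expansion_network()].
#' @return the M x D effective weight matrix `Jeff = J A`.
#' @export
effective_weights <- function(network) {
  stopifnot(inherits(network, "expansion_network"))
  network$Jeff
}

#' Calibrate the shared activation threshold to a target coding level
#'
#' Sets `theta` to the empirical (1 - f) quantile of the pooled
#' preactivations `Jeff x` over all neurons and calibration patterns, so
#' that on data from the same distribution a fraction f of units sits above
#' threshold. This empirical rule works for every connectivity kind; for
#' dense Gaussian weights and unit-norm inputs it converges to the analytic
#' value `qnorm(1 - f)`.
#'
#' @param network an [expansion_network()].
#' @param calibration_inputs a patterns x D matrix drawn from the task's
#'   input distribution.
#' @param f target coding level in (0, 1).
#' @return the network with `theta` and `target_f` set.
#' @export
calibrate_threshold <- function(network, calibration_inputs, f) {
  stopifnot(inherits(network, "expansion_network"))
  .assert_scalar(f, "f", lower = 0, upper = 1, strict = TRUE)
  X <- if (is.matrix(calibration_inputs)) calibration_inputs
       else matrix(calibration_inputs, ncol = network$D)
  if (ncol(X) != network$D)
    stop("calibration inputs have wrong dimension", call. = FALSE)
  Z <- network$Jeff %*% t(X)
  if (max(Z) - min(Z) < 1e-12)
    stop("degenerate preactivations: threshold calibration impossible",
         call. = FALSE)
  network$theta <- unname(quantile(Z, probs = 1 - f, names = FALSE))
  network$target_f <- f
  network
}

#' Compute expansion-layer activity
#'
#' Applies the network nonlinearity to the preactivations:
#' `H[i, mu] = max(Jeff_i . x_mu - theta, 0)^power`.
#'
#' @param network an [expansion_network()] with a finite threshold.
#' @param inputs a patterns x D matrix of inputs (task variables, or direct
#'   input-layer activities for identity-embedding networks).
#' @param theta optional threshold override.
#' @return an object of class `expansion_activity`: a list with the M x P
#'   nonnegative activity matrix `H` and the `measured_f` coding level.
#' @export
#' @examples
#' net <- expansion_network(M = 200, D = 3, seed = 1)
#' net <- calibrate_threshold(net, runif_sphere(100, 3), f = 0.3)
#' act <- expand(net, runif_sphere(20, 3))
#' act$measured_f
expand <- function(network, inputs, theta = network$theta) {
  stopifnot(inherits(network, "expansion_network"))
  X <- if (is.matrix(inputs)) inputs else matrix(inputs, ncol = network$D)
  if (ncol(X) != network$D)
    stop(sprintf("input dimension %d does not match network D = %d",
                 ncol(X), network$D), call. = FALSE)
  if (!is.finite(theta))
    stop("network threshold is not set; call calibrate_threshold() first",
         call. = FALSE)
  H <- pmax(network$Jeff %*% t(X) - theta, 0)
  if (network$power != 1) H <- H^network$power
  structure(list(H = H, measured_f = coding_level(H)),
            class = "expansion_activity")
}

#' @export
print.expansion_activity <- function(x, ...) {
  cat(sprintf("<expansion_activity> %d neurons x %d patterns, coding level %.4f\n",
              nrow(x$H), ncol(x$H), x$measured_f))
  invisible(x)
}

#' Winner-take-all activity at a fixed per-pattern coding level
#'
#' For each input pattern, the `ceiling(f * M)` units with the largest
#' preactivations stay active with value (preactivation - cutoff), where the
#' cutoff is the largest excluded preactivation (the per-pattern minimum
#' when all units are kept); all other units are silenced. Ties at the
#' cutoff are broken deterministically toward the lowest neuron index.
#' This models strong recurrent inhibition that fixes the coding level for
#' every pattern, as used with clustered input representations.
#'
#' @param preactivations an M x P matrix of preactivations `Jeff x`.
#' @param f coding level in (0, 1\].
#' @return an `expansion_activity` object.
#' @export
winner_take_all <- function(preactivations, f) {
  Z <- as.matrix(preactivations)
  .assert_scalar(f, "f", lower = 0, upper = 1)
  if (f <= 0) stop("`f` must be positive", call. = FALSE)
  M <- nrow(Z)
  k <- min(M, ceiling(f * M))
  H <- matrix(0, M, ncol(Z))
  for (mu in seq_len(ncol(Z))) {
    z <- Z[, mu]
    ord <- order(z, decreasing = TRUE) # stable: ties go to lowest index
    keep <- ord[seq_len(k)]
    cutoff <- if (k < M) z[ord[k + 1]] else min(z)
    H[keep, mu] <- pmax(z[keep] - cutoff, 0)
  }
  structure(list(H = H, measured_f = coding_level(H)),
            class = "expansion_activity")
}

#' Coding level of an activity matrix
#'
#' The average over patterns of the fraction of strictly positive entries.
#'
#' @param H an M x P nonnegative activity matrix or an `expansion_activity`.
#' @return a fraction in \[0, 1\].
#' @export
coding_level <- function(H) {
  if (inherits(H, "expansion_activity")) H <- H$H
  H <- as.matrix(H)
  if (length(H) == 0) stop("empty activity matrix", call. = FALSE)
  if (any(H < 0)) stop("activity must be nonnegative", call. = FALSE)
  mean(colMeans(H > 0))
}

#' Participation-ratio dimension of expansion-layer activity
#'
#' `d = (sum_i lambda_i)^2 / (sum_i lambda_i^2)`, where `lambda_i` are the
#' eigenvalues of the neuron-by-neuron covariance of activity across
#' patterns. Computed via the pattern-by-pattern Gram matrix of centered
#' activity, which shares its nonzero eigenvalues with the covariance, so
#' the M x M covariance is never formed.
#'
#' @param H an M x P activity matrix (P >= 2) or an `expansion_activity`.
#' @return the dimension estimate, in \[0, min(M, P)\]; 0 with a warning if
#'   the activity has zero variance.
#' @export
participation_dimension <- function(H) {
  if (inherits(H, "expansion_activity")) H <- H$H
  H <- as.matrix(H)
  P <- ncol(H)
  if (P < 2) stop("dimension requires at least 2 patterns", call. = FALSE)
  Hc <- H - rowMeans(H)
  G <- if (nrow(Hc) <= P) tcrossprod(Hc) else crossprod(Hc)
  tr1 <- sum(diag(G)) # (P-1) * sum lambda_i
  if (tr1 <= 0) {
    warning("zero activity covariance; returning dimension 0")
    return(0)
  }
  tr2 <- sum(G^2) # (P-1)^2 * sum lambda_i^2
  tr1^2 / tr2
}

#' Pairwise correlations of effective weight vectors
#'
#' Samples random pairs of expansion-layer neurons and returns the cosine
#' similarity of their (uncentered) effective weight rows. For dense
#' Gaussian effective weights with D = 3 this distribution is exactly
#' uniform on \[-1, 1\]; deviations (e.g. excess mass near 1 for clustered
#' embeddings) diagnose non-uniform sampling of the task subspace.
#'
#' @param network an [expansion_network()].
#' @param n_pairs number of random neuron pairs to sample.
#' @param seed optional RNG seed.
#' @return a vector of `n_pairs` correlations; rows with zero norm are
#'   excluded with a warning.
#' @export
effective_weight_correlations <- function(network, n_pairs = 1e4, seed = NULL) {
  stopifnot(inherits(network, "expansion_network"))
  if (network$D < 2) stop("requires D >= 2", call. = FALSE)
  .set_seed_if(seed)
  W <- network$Jeff
  nrm <- sqrt(rowSums(W^2))
  ok <- which(nrm > 1e-12)
  if (length(ok) < nrow(W))
    warning(sprintf("excluded %d zero-norm effective weight rows",
                    nrow(W) - length(ok)))
  if (length(ok) < 2) stop("fewer than 2 usable rows", call. = FALSE)
  i <- ok[sample.int(length(ok), n_pairs, replace = TRUE)]
  j <- ok[sample.int(length(ok), n_pairs, replace = TRUE)]
  same <- which(i == j)
  while (length(same) > 0) {
    j[same] <- ok[sample.int(length(ok), length(same), replace = TRUE)]
    same <- same[i[same] == j[same]]
  }
  rowSums(W[i, , drop = FALSE] * W[j, , drop = FALSE]) / (nrm[i] * nrm[j])
}
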