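#' Number of independent spherical harmonics of a given degree
#'
#' The degeneracy N(D, k) of degree-k harmonics on the sphere in D ambient
#' dimensions: 1 for k = 0, `(2k + D - 2) / (D - 2) * choose(k + D - 3, k)`
#' for k >= 1 when D >= 3, and 2 for every k >= 1 when D = 2 (Fourier
#' modes).
#'
#' @param D ambient dimension (>= 2).
#' @param k degree (vectorized, >= 0).
#' @return degeneracies, same length as `k`.
#' @export
sphere_degeneracy <- function(D, k) {
  .assert_scalar(D, "D", lower = 2, integer = TRUE)
  stopifnot(all(k >= 0), all(k == round(k)))
  if (D == 2) return(ifelse(k == 0, 1, 2))
  ifelse(k == 0, 1, (2 * k + D - 2) / (D - 2) * choose(k + D - 3, k))
}

# ultraspherical (Gegenbauer) polynomials normalized to P_k(1) = 1 for the
# sphere in D dimensions; Legendre for D = 3, Chebyshev T for D = 2.
# Returns a length(t) x (k_max + 1) matrix.
.gegenbauer_normalized <- function(t, k_max, D) {
  n <- length(t)
  out <- matrix(0, n, k_max + 1)
  out[, 1] <- 1
  if (k_max == 0) return(out)
  if (D == 2) {
    th <- acos(pmin(pmax(t, -1), 1))
    for (k in 1:k_max) out[, k + 1] <- cos(k * th)
    return(out)
  }
  alpha <- (D - 2) / 2
  # unnormalized recurrence k C_k = 2(k + a - 1) t C_{k-1} - (k + 2a - 2) C_{k-2}
  cm2 <- rep(1, n); cm1 <- 2 * alpha * t
  vm2 <- 1; vm1 <- 2 * alpha # values at t = 1
  out[, 2] <- cm1 / vm1
  if (k_max >= 2) for (k in 2:k_max) {
    ck <- (2 * (k + alpha - 1) * t * cm1 - (k + 2 * alpha - 2) * cm2) / k
    vk <- (2 * (k + alpha - 1) * vm1 - (k + 2 * alpha - 2) * vm2) / k
    out[, k + 1] <- ck / vk
    cm2 <- cm1; cm1 <- ck
    vm2 <- vm1; vm1 <- vk
  }
  out
}

# quadrature nodes t_i and probability weights for averages against the
# overlap density (1 - t^2)^((D-3)/2) on [-1, 1]
.funk_hecke_nodes <- function(D, n) {
  if (D == 2) { # Chebyshev-Gauss handles the endpoint singularity
    i <- seq_len(n)
    list(t = cos((2 * i - 1) * pi / (2 * n)), w = rep(1 / n, n))
  } else {
    gl <- pracma::gaussLegendre(n, -1, 1)
    w <- gl$w * (1 - gl$x^2)^((D - 3) / 2)
    list(t = gl$x, w = w / sum(w))
  }
}

.lambda_from_nodes <- function(Kvals, nodes, k_max, D) {
  Pk <- .gegenbauer_normalized(nodes$t, k_max, D)
  drop(crossprod(Pk, nodes$w * Kvals))
}

#' Spherical-harmonic eigenvalues of a dot-product kernel
#'
#' Funk-Hecke reduction: for a dot-product kernel `K(x . x')` on the sphere
#' under the uniform input measure, the eigenfunctions are the spherical
#' harmonics and the eigenvalue for every degree-k harmonic is the weighted
#' average of `K(t)` against the degree-k ultraspherical polynomial
#' (normalized to 1 at t = 1) under the overlap density
#' `(1 - t^2)^((D-3)/2)`. Eigenvalues are stated per mode in the
#' orthonormal-harmonic convention, so the trace identity
#' `sum_k N(D, k) lambda_k = K(1)` holds. Quadrature nodes are doubled
#' until all eigenvalues are stable; tiny negative values from quadrature
#' noise are clipped to zero.
#'
#' @param kernel a [kernel_model()], or a vectorized function of the
#'   overlap t in \[-1, 1\].
#' @param D sphere ambient dimension (>= 2).
#' @param k_max maximum harmonic degree.
#' @param tol stability tolerance for node doubling.
#' @return an object of class `kernel_spectrum`: list with `D`, `degree`
#'   (0..k_max), per-mode eigenvalues `lambda`, `degeneracy`, and the
#'   kernel diagonal `kernel_trace = K(1)`.
#' @export
#' @examples
#' spec <- kernel_eigenvalues(kernel_model(f = 0.1), D = 3, k_max = 30)
#' sum(spec$degeneracy * spec$lambda) / spec$kernel_trace # ~ 1
kernel_eigenvalues <- function(kernel, D, k_max, tol = 1e-10) {
  .assert_scalar(D, "D", lower = 2, integer = TRUE)
  .assert_scalar(k_max, "k_max", lower = 0, integer = TRUE)
  kfun <- if (inherits(kernel, "kernel_model")) {
    function(t) kernel_value(kernel, t)
  } else {
    stopifnot(is.function(kernel))
    kernel
  }
  k1 <- kfun(1)
  scale <- max(abs(k1), 1e-300)
  n <- max(128L, 4L * (k_max + 1L))
  nodes <- .funk_hecke_nodes(D, n)
  lam <- .lambda_from_nodes(kfun(nodes$t), nodes, k_max, D)
  for (rep in 1:6) {
    n <- 2L * n
    nodes <- .funk_hecke_nodes(D, n)
    lam_new <- .lambda_from_nodes(kfun(nodes$t), nodes, k_max, D)
    if (max(abs(lam_new - lam)) < tol * max(1, scale)) {
      lam <- lam_new
      break
    }
    lam <- lam_new
    if (rep == 6)
      stop("Funk-Hecke quadrature did not stabilize under node doubling",
           call. = FALSE)
  }
  if (min(lam) < -1e-8 * scale)
    warning(sprintf("clipping substantially negative eigenvalue %.3e", min(lam)))
  lam <- pmax(lam, 0)
  structure(list(D = D, degree = 0:k_max, lambda = lam,
                 degeneracy = sphere_degeneracy(D, 0:k_max),
                 kernel_trace = k1),
            class = "kernel_spectrum")
}

#' @export
print.kernel_spectrum <- function(x, ...) {
  cap <- sum(x$degeneracy * x$lambda) / x$kernel_trace
  cat(sprintf("<kernel_spectrum> D=%d, degrees 0..%d, trace capture %.2f%%\n",
              x$D, max(x$degree), 100 * cap))
  invisible(x)
}

#' Build a target-power spectrum object
#'
#' @param D sphere dimension.
#' @param degree degrees 0..k_max.
#' @param power_per_mode expected squared coefficient per harmonic mode.
#' @return an object of class `target_spectrum` with per-mode and total
#'   per-degree power.
#' @export
target_spectrum <- function(D, degree, power_per_mode) {
  stopifnot(length(degree) == length(power_per_mode), all(power_per_mode >= 0))
  deg <- sphere_degeneracy(D, degree)
  structure(list(D = D, degree = degree, power_per_mode = power_per_mode,
                 degree_power = deg * power_per_mode, degeneracy = deg),
            class = "target_spectrum")
}

#' @export
print.target_spectrum <- function(x, ...) {
  cat(sprintf("<target_spectrum> D=%d, degrees 0..%d, total power %.4g\n",
              x$D, max(x$degree), sum(x$degree_power)))
  invisible(x)
}

#' Harmonic power spectrum of a Gaussian-process target
#'
#' On the unit sphere the squared-exponential GP covariance is itself a
#' dot-product kernel, `C(t) = exp(-(1 - t) / gamma^2)` since
#' `||x - x'||^2 = 2 - 2 x . x'`. The expected squared coefficient of each
#' harmonic mode of a GP draw equals the corresponding covariance
#' eigenvalue, so the target spectrum is obtained by the same Funk-Hecke
#' reduction as the network kernel. Total power sums to `C(1) = 1`.
#'
#' @param gamma GP length scale (> 0).
#' @param D sphere ambient dimension.
#' @param k_max maximum degree.
#' @return a [target_spectrum()].
#' @export
gp_target_spectrum <- function(gamma, D, k_max) {
  .assert_scalar(gamma, "gamma", lower = 0, strict = TRUE)
  spec <- kernel_eigenvalues(function(t) exp(-(1 - t) / gamma^2), D, k_max)
  target_spectrum(D, spec$degree, spec$lambda)
}

#' Empirical harmonic decomposition of a target sampled on the sphere
#'
#' Estimates the power of a target function in each harmonic degree from
#' samples, using the addition theorem: the total degree-k power equals
#' `N(D, k) * E[f(x) f(x') P_k(x . x')]` over independent input pairs.
#' Pairs are subsampled when the full set is large.
#'
#' @param inputs n x D matrix of (approximately unit-norm) inputs.
#' @param values length-n target values.
#' @param D sphere dimension (defaults to `ncol(inputs)`).
#' @param k_max maximum degree.
#' @param max_pairs cap on the number of input pairs used.
#' @param seed optional RNG seed for pair subsampling.
#' @return a [target_spectrum()] (empirical; per-mode power is the degree
#'   power divided by the degeneracy).
#' @export
project_target_power <- function(inputs, values, D = ncol(inputs), k_max,
                                 max_pairs = 2e6, seed = NULL) {
  X <- as.matrix(inputs)
  f <- drop(values)
  stopifnot(nrow(X) == length(f))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  .set_seed_if(seed)
  n_pairs_full <- n * (n - 1) / 2
  if (n_pairs_full <= max_pairs) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
  } else {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
  }
  t_ij <- rowSums(X[i, , drop = FALSE] * X[j, , drop = FALSE])
  t_ij <- pmin(pmax(t_ij, -1), 1)
  Pk <- .gegenbauer_normalized(t_ij, k_max, D)
  ff <- f[i] * f[j]
  degree_power <- pmax(sphere_degeneracy(D, 0:k_max) *
                         drop(crossprod(Pk, ff)) / length(ff), 0)
  target_spectrum(D, 0:k_max, degree_power / sphere_degeneracy(D, 0:k_max))
}
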