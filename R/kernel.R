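#' Empirical kernel of expansion-layer activity
#'
#' The inner-product similarity of representations, `K = H_a' H_b / M`.
#' As the expansion grows this converges to the analytic dot-product kernel
#' of the network (see [analytic_kernel()]).
#'
#' @param H_a,H_b M x P activity matrices (or `expansion_activity` objects)
#'   from the same network.
#' @return a P_a x P_b kernel matrix.
#' @export
empirical_kernel <- function(H_a, H_b = H_a) {
  if (inherits(H_a, "expansion_activity")) H_a <- H_a$H
  if (inherits(H_b, "expansion_activity")) H_b <- H_b$H
  if (nrow(H_a) != nrow(H_b))
    stop("activity matrices come from different expansion sizes", call. = FALSE)
  crossprod(H_a, H_b) / nrow(H_a)
}

# truncated standard-normal moments I_j(a) = E[z^j 1{z > a}], j = 0..p,
# via the stable upward recursion I_j = a^(j-1) phi(a) + (j-1) I_{j-2}
.trunc_norm_moments <- function(a, p) {
  out <- vector("list", p + 1)
  out[[1]] <- pnorm(a, lower.tail = FALSE)
  if (p >= 1) out[[2]] <- dnorm(a)
  if (p >= 2) for (j in 2:p)
    out[[j + 1]] <- a^(j - 1) * dnorm(a) + (j - 1) * out[[j - 1]]
  out
}

# E[(m + s z)_+^p] for z ~ N(0,1); vectorized over m, scalar s >= 0
.plus_pow_gauss_mean <- function(m, s, p) {
  if (s == 0) return(pmax(m, 0)^p)
  a <- -m / s
  I <- .trunc_norm_moments(a, p)
  out <- 0
  for (j in 0:p)
    out <- out + choose(p, j) * m^(p - j) * s^j * I[[j + 1]]
  out
}

#' Semi-analytic kernel of an infinite-width thresholded expansion
#'
#' For Gaussian effective weights and unit-norm inputs, the infinite-width
#' kernel of the expansion layer depends only on the input overlap
#' `rho = x . x'`:
#' `K(rho) = E[(u - theta)_+^p (v - theta)_+^p]` with `(u, v)` standard
#' bivariate normal with correlation `rho`. The inner conditional
#' expectation over `v | u` has a closed form in truncated-normal moments
#' for integer `p`; the remaining one-dimensional integral over `u` is
#' evaluated by adaptive quadrature. The threshold sets the coding level
#' through `f = 1 - pnorm(theta)`.
#'
#' @param rho input overlap(s) in \[-1, 1\] (vectorized).
#' @param theta shared activation threshold.
#' @param power integer nonlinearity exponent p >= 1.
#' @param normalize if TRUE return `K(rho) / K(1)` so fully overlapping
#'   representations have overlap 1.
#' @return kernel values, same length as `rho`.
#' @export
#' @examples
#' analytic_kernel(0, theta = 0) # 1 / (2*pi)
analytic_kernel <- function(rho, theta, power = 1, normalize = FALSE) {
  stopifnot(is.numeric(rho))
  if (any(abs(rho) > 1 + 1e-12))
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  rho <- pmin(pmax(rho, -1), 1)
  .assert_scalar(theta, "theta")
  .assert_scalar(power, "power", lower = 1, integer = TRUE)
  p <- as.integer(power)
  k1 <- .plus_pow_gauss_mean(-theta, 1, 2L * p) # K(1) = E[(u - theta)_+^(2p)]
  Kfun <- function(r) {
    if (r >= 1) return(k1)
    s <- sqrt(1 - r^2)
    f <- function(u)
      (u - theta)^p * .plus_pow_gauss_mean(r * u - theta, s, p) * dnorm(u)
    stats::integrate(f, lower = theta, upper = Inf,
                     rel.tol = 1e-11, abs.tol = 1e-14)$value
  }
  out <- vapply(rho, Kfun, numeric(1))
  if (normalize) out / k1 else out
}

#' Kernel model of a thresholded expansion layer
#'
#' Bundles the threshold (or equivalently the coding level), the
#' nonlinearity exponent and a normalization mode into a callable
#' description of the infinite-width kernel.
#'
#' @param theta activation threshold; exactly one of `theta`, `f` must be
#'   given.
#' @param f coding level in (0, 1); converted to `theta = qnorm(1 - f)`.
#' @param power integer nonlinearity exponent.
#' @param normalize return the unit-diagonal kernel `K(rho)/K(1)`?
#' @return an object of class `kernel_model`; call it on overlaps via
#'   [kernel_value()].
#' @export
kernel_model <- function(theta = NULL, f = NULL, power = 1, normalize = FALSE) {
  if (is.null(theta) == is.null(f))
    stop("specify exactly one of `theta` or `f`", call. = FALSE)
  if (is.null(theta)) {
    .assert_scalar(f, "f", lower = 0, upper = 1, strict = TRUE)
    theta <- qnorm(1 - f)
  } else {
    .assert_scalar(theta, "theta")
    f <- 1 - pnorm(theta)
  }
  structure(list(theta = theta, f = f, power = as.integer(power),
                 normalize = normalize), class = "kernel_model")
}

#' Evaluate a kernel model at given overlaps
#'
#' @param kernel a [kernel_model()].
#' @param rho overlaps in \[-1, 1\].
#' @return kernel values.
#' @export
kernel_value <- function(kernel, rho) {
  stopifnot(inherits(kernel, "kernel_model"))
  analytic_kernel(rho, theta = kernel$theta, power = kernel$power,
                  normalize = kernel$normalize)
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("<kernel_model> theta=%.4f (coding level %.4f), power=%d%s\n",
              x$theta, x$f, x$power,
              if (x$normalize) ", unit diagonal" else ""))
  invisible(x)
}
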