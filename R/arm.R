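#' Parameters of the planar two-joint arm
#'
#' Physical parameters of the biophysical two-segment arm model used for the
#' forward-dynamics prediction task. Defaults are the standard values for a
#' human-like arm: segment masses m1, m2 (kg), lengths l1, l2 (m), lower-arm
#' center of mass lbar2 (m), moments of inertia I1, I2 (kg m^2) and viscous
#' friction coefficients D1, D2 (kg m^2 / s).
#'
#' @param m1,m2 segment masses in kg.
#' @param l1,l2 segment lengths in m.
#' @param lbar2 distance from the elbow to the lower-arm center of mass in m.
#' @param I1,I2 segment moments of inertia in kg m^2.
#' @param D1,D2 joint friction coefficients in kg m^2 / s.
#' @return an object of class `arm_parameters`.
#' @export
arm_parameters <- function(m1 = 3, m2 = 2.5, l1 = 0.3, l2 = 0.35, lbar2 = 0.21,
                           I1 = 0.1, I2 = 0.12, D1 = 0.05, D2 = 0.01) {
  p <- list(m1 = m1, m2 = m2, l1 = l1, l2 = l2, lbar2 = lbar2,
            I1 = I1, I2 = I2, D1 = D1, D2 = D2)
  for (nm in names(p)) .assert_scalar(p[[nm]], nm, lower = 0, strict = TRUE)
  structure(p, class = "arm_parameters")
}

#' State of the two-joint arm
#'
#' @param theta1,theta2 shoulder and elbow joint angles (rad).
#' @param dtheta1,dtheta2 angular velocities (rad/s).
#' @param u1,u2 constant joint torques (N m).
#' @return an object of class `arm_state`.
#' @export
arm_state <- function(theta1 = pi / 4, theta2 = pi / 4, dtheta1 = 0,
                      dtheta2 = 0, u1 = 0, u2 = 0) {
  s <- list(theta1 = theta1, theta2 = theta2, dtheta1 = dtheta1,
            dtheta2 = dtheta2, u1 = u1, u2 = u2)
  if (!all(vapply(s, function(v) is.numeric(v) && all(is.finite(v)), logical(1))))
    stop("arm state components must be finite numerics", call. = FALSE)
  n <- unique(lengths(s))
  if (length(n) != 1) stop("arm state components must share a length", call. = FALSE)
  structure(s, class = "arm_state")
}

# vectorized joint accelerations for the two-link dynamics
#   M(theta) ddtheta + C(theta, dtheta) dtheta = u
# with the Lagrangian-consistent symmetric inertia matrix (lower-arm center
# of mass lbar2 in every coupling term) and viscous friction on the diagonal
# of C. Returns a list of the two acceleration vectors.
.arm_accel <- function(th2, dth1, dth2, u1, u2, p) {
  a2 <- p$m2 * p$l1 * p$lbar2
  c2 <- cos(th2)
  m11 <- p$I1 + p$I2 + p$m2 * p$l1^2 + 2 * a2 * c2
  m12 <- p$I2 + a2 * c2
  m22 <- p$I2
  s2 <- a2 * sin(th2)
  # C(theta, dtheta) %*% dtheta, Coriolis/centrifugal plus friction
  c1 <- s2 * (-2 * dth2 * dth1 - dth2 * dth2) + p$D1 * dth1
  cc2 <- s2 * dth1 * dth1 + p$D2 * dth2
  r1 <- u1 - c1
  r2 <- u2 - cc2
  det <- m11 * m22 - m12 * m12
  if (any(abs(det) < 1e-12))
    stop("singular inertia matrix in arm dynamics", call. = FALSE)
  list(dd1 = (m22 * r1 - m12 * r2) / det,
       dd2 = (m11 * r2 - m12 * r1) / det)
}

# one RK4 step for (theta, dtheta) with constant torque, vectorized over states
.arm_rk4_step <- function(st, p, dt) {
  f <- function(s) {
    a <- .arm_accel(s$theta2, s$dtheta1, s$dtheta2, s$u1, s$u2, p)
    list(theta1 = s$dtheta1, theta2 = s$dtheta2,
         dtheta1 = a$dd1, dtheta2 = a$dd2)
  }
  add <- function(s, k, h) {
    s2 <- s
    for (nm in c("theta1", "theta2", "dtheta1", "dtheta2"))
      s2[[nm]] <- s[[nm]] + h * k[[nm]]
    s2
  }
  k1 <- f(st)
  k2 <- f(add(st, k1, dt / 2))
  k3 <- f(add(st, k2, dt / 2))
  k4 <- f(add(st, k3, dt))
  for (nm in c("theta1", "theta2", "dtheta1", "dtheta2"))
    st[[nm]] <- st[[nm]] + dt / 6 *
      (k1[[nm]] + 2 * k2[[nm]] + 2 * k3[[nm]] + k4[[nm]])
  st
}

#' Cartesian hand position of the arm
#'
#' Shoulder at the origin; the hand is the end of the lower segment.
#'
#' @param theta1,theta2 joint angles (vectors allowed).
#' @param params an [arm_parameters()] object.
#' @return a matrix with columns x, y in meters.
#' @export
arm_hand_position <- function(theta1, theta2, params = arm_parameters()) {
  cbind(x = params$l1 * cos(theta1) + params$l2 * cos(theta1 + theta2),
        y = params$l1 * sin(theta1) + params$l2 * sin(theta1 + theta2))
}

#' Total kinetic energy of the arm
#'
#' `0.5 * dtheta' M(theta) dtheta` with the configuration-dependent inertia
#' matrix. With zero torque and zero friction this quantity is conserved by
#' the dynamics, which the test suite uses to validate the integrator.
#'
#' @param state an [arm_state()].
#' @param params an [arm_parameters()].
#' @return kinetic energy in joules (vectorized over states).
#' @export
arm_kinetic_energy <- function(state, params = arm_parameters()) {
  p <- params
  a2 <- p$m2 * p$l1 * p$lbar2
  c2 <- cos(state$theta2)
  m11 <- p$I1 + p$I2 + p$m2 * p$l1^2 + 2 * a2 * c2
  m12 <- p$I2 + a2 * c2
  m22 <- p$I2
  0.5 * (m11 * state$dtheta1^2 + 2 * m12 * state$dtheta1 * state$dtheta2 +
           m22 * state$dtheta2^2)
}

#' Integrate the two-joint arm forward and return the hand displacement
#'
#' Fixed-step RK4 integration of the arm dynamics over a horizon `delta`
#' with torques held constant, returning the change in Cartesian hand
#' position. Deterministic given its inputs.
#'
#' @param state an [arm_state()] (components may be vectors for a batch of
#'   initial conditions).
#' @param params an [arm_parameters()].
#' @param delta prediction horizon in seconds (> 0).
#' @param dt integration step in seconds (default 1 ms).
#' @return an n x 2 matrix of hand displacements (m); a single state gives
#'   one row.
#' @export
#' @examples
#' simulate_arm(arm_state(u1 = 1), delta = 0.2)
simulate_arm <- function(state, params = arm_parameters(), delta = 0.2,
                         dt = 1e-3) {
  stopifnot(inherits(state, "arm_state"), inherits(params, "arm_parameters"))
  .assert_scalar(delta, "delta", lower = 0, strict = TRUE)
  .assert_scalar(dt, "dt", lower = 0, strict = TRUE)
  n_steps <- max(1L, round(delta / dt))
  h <- delta / n_steps
  p0 <- arm_hand_position(state$theta1, state$theta2, params)
  st <- state
  for (i in seq_len(n_steps)) st <- .arm_rk4_step(st, params, h)
  arm_hand_position(st$theta1, st$theta2, params) - p0
}

#' Sample a two-joint-arm forward-dynamics task
#'
#' Inputs are 6-dimensional sensorimotor states (two joint angles, two
#' angular velocities, two torques) drawn as Gaussian vectors with standard
#' deviations `(sigma_theta, sigma_theta, sigma_dtheta, sigma_dtheta,
#' sigma_u, sigma_u)` and normalized to unit norm. Initial joint angles are
#' offset by pi/4 from the first two input coordinates. The two-dimensional
#' continuous target is the Cartesian hand displacement after integrating
#' the dynamics for `delta` seconds. Test patterns are fresh draws from the
#' same distribution.
#'
#' @param P number of training patterns.
#' @param P_test number of test patterns (default `P`).
#' @param sigma_theta,sigma_dtheta,sigma_u input scales (defaults 0.1, 0.1, 1).
#' @param params an [arm_parameters()].
#' @param delta prediction horizon in seconds.
#' @param dt integrator step (s).
#' @param seed optional RNG seed.
#' @return a continuous [task_dataset()] with Q = 2 targets.
#' @export
sample_arm_task <- function(P, P_test = P, sigma_theta = 0.1,
                            sigma_dtheta = 0.1, sigma_u = 1,
                            params = arm_parameters(), delta = 0.2,
                            dt = 1e-3, seed = NULL) {
  .assert_scalar(P, "P", lower = 1, integer = TRUE)
  .assert_scalar(P_test, "P_test", lower = 1, integer = TRUE)
  for (nm in c("sigma_theta", "sigma_dtheta", "sigma_u"))
    .assert_scalar(get(nm), nm, lower = 0, strict = TRUE)
  .set_seed_if(seed)
  n <- P + P_test
  sds <- c(sigma_theta, sigma_theta, sigma_dtheta, sigma_dtheta,
           sigma_u, sigma_u)
  X <- matrix(rnorm(n * 6), n, 6) %*% diag(sds)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm < 1e-12)
  while (length(bad) > 0) { # degenerate zero draws carry no direction
    X[bad, ] <- matrix(rnorm(length(bad) * 6), ncol = 6) %*% diag(sds)
    nrm[bad] <- sqrt(rowSums(X[bad, , drop = FALSE]^2))
    bad <- bad[nrm[bad] < 1e-12]
  }
  X <- X / nrm
  st <- arm_state(theta1 = pi / 4 + X[, 1], theta2 = pi / 4 + X[, 2],
                  dtheta1 = X[, 3], dtheta2 = X[, 4], u1 = X[, 5], u2 = X[, 6])
  Y <- simulate_arm(st, params, delta = delta, dt = dt)
  task_dataset(X[seq_len(P), , drop = FALSE], Y[seq_len(P), , drop = FALSE],
               X[P + seq_len(P_test), , drop = FALSE],
               Y[P + seq_len(P_test), , drop = FALSE],
               task_kind = "continuous",
               metadata = list(family = "arm", D = 6, P = P, P_test = P_test,
                               delta = delta, seed = seed))
}
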