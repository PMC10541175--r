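#' Specification of a VOR piecewise-linear target
#'
#' Purkinje cell tuning to head velocity during vestibulo-ocular reflex
#' adaptation is modeled as a piecewise-linear function of head velocity v:
#' slope `m1` below the breakpoint `c`, slope `m2` above it, value `b` at
#' the breakpoint.
#'
#' @param m1,m2 slopes below/above the breakpoint.
#' @param b value at the breakpoint.
#' @param c breakpoint, inside the input range \[-1, 1\].
#' @return an object of class `vor_task_spec`.
#' @export
vor_task_spec <- function(m1, m2, b = 0.1, c = -0.2) {
  .assert_scalar(m1, "m1"); .assert_scalar(m2, "m2"); .assert_scalar(b, "b")
  .assert_scalar(c, "c", lower = -1, upper = 1)
  structure(list(m1 = m1, m2 = m2, b = b, c = c), class = "vor_task_spec")
}

#' Evaluate a VOR target function
#'
#' @param v head velocities.
#' @param spec a [vor_task_spec()].
#' @return target Purkinje cell-like firing rates.
#' @export
vor_target <- function(v, spec) {
  stopifnot(inherits(spec, "vor_task_spec"))
  ifelse(v < spec$c, spec$m1 * (v - spec$c) + spec$b,
         spec$m2 * (v - spec$c) + spec$b)
}

#' The standard battery of 24 mossy fiber tuning curves
#'
#' Mossy fiber responses to head velocity are exponential tuning curves
#' `n_j(v) = g_j * exp(v * r_j) + b_j`. The battery takes all combinations
#' of gain `g` over 6 equally spaced points in \[0.1, 1\], direction
#' preference `r` in \{-1, +1\}, and baseline `b` in \{0, 1\}: 24 curves.
#'
#' @return a data.frame with columns `g`, `r`, `b` (24 rows).
#' @export
vor_mossy_battery <- function() {
  expand.grid(g = seq(0.1, 1, length.out = 6), r = c(-1, 1), b = c(0, 1),
              KEEP.OUT.ATTRS = FALSE)
}

#' Mossy fiber activity for head velocities
#'
#' @param v vector of head velocities.
#' @param battery a data.frame as returned by [vor_mossy_battery()].
#' @return a `length(v)` x `nrow(battery)` activity matrix.
#' @export
vor_mossy_activity <- function(v, battery = vor_mossy_battery()) {
  sapply(seq_len(nrow(battery)), function(j)
    battery$g[j] * exp(v * battery$r[j]) + battery$b[j])
}

#' The 5 x 5 grid of VOR target slope pairs
#'
#' All combinations of slopes `m1`, `m2` over 5 equally spaced points in
#' \[-2, 2\]: 25 target functions, with `b = 0.1` and `c = -0.2`.
#'
#' @return a list of 25 [vor_task_spec()] objects.
#' @export
vor_slope_grid <- function() {
  s <- seq(-2, 2, length.out = 5)
  g <- expand.grid(m1 = s, m2 = s, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) vor_task_spec(g$m1[i], g$m2[i]))
}

#' Sample a VOR adaptation task
#'
#' Head velocities are sampled uniformly on \[-1, 1\]; inputs are the 24
#' mossy fiber tuning-curve activities evaluated at those velocities
#' (`input_mode = "direct_input_layer"`), and targets are the piecewise
#' linear tuning of `spec` (or of all 25 slope-grid targets jointly when
#' `spec = NULL`, giving a Q = 25 target matrix scored per column). Of the
#' `n_points` sampled velocities, a random subset of `P_train` is used for
#' training and the remainder for testing.
#'
#' @param spec a [vor_task_spec()], or `NULL` for the full 25-target battery.
#' @param n_points total number of sampled head velocities.
#' @param P_train number of training points (must not exceed `n_points`).
#' @param seed optional RNG seed.
#' @return a continuous [task_dataset()] with `input_mode`
#'   `"direct_input_layer"`; metadata element `v` carries the raw velocities.
#' @export
sample_vor_task <- function(spec = NULL, n_points = 100, P_train = 30,
                            seed = NULL) {
  .assert_scalar(n_points, "n_points", lower = 2, integer = TRUE)
  .assert_scalar(P_train, "P_train", lower = 1, upper = n_points - 1,
                 integer = TRUE)
  .set_seed_if(seed)
  v <- runif(n_points, -1, 1)
  N <- vor_mossy_activity(v)
  specs <- if (is.null(spec)) vor_slope_grid() else list(spec)
  Y <- sapply(specs, function(s) vor_target(v, s))
  Y <- matrix(Y, nrow = n_points)
  tr <- sort(sample.int(n_points, P_train))
  te <- setdiff(seq_len(n_points), tr)
  task_dataset(N[tr, , drop = FALSE], Y[tr, , drop = FALSE],
               N[te, , drop = FALSE], Y[te, , drop = FALSE],
               task_kind = "continuous", input_mode = "direct_input_layer",
               metadata = list(family = "vor", D = 1, P = P_train,
                               n_points = n_points, seed = seed,
                               n_targets = length(specs),
                               v_train = v[tr], v_test = v[te]))
}
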