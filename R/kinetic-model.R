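#' Kinetic parameters of the irreversible two-tissue compartment model
#'
#' Bundles the rate constants of the irreversible two-tissue (2T) compartment
#' model used for 18F-fluciclovine: delivery rate `K1` (mL/min/cm^3), efflux
#' rate `k2` (1/min), free-to-contained flux rate `k3` (1/min), and the
#' fractional blood volume `vb` (mL/mL). `k4` is fixed at 0: the tracer does
#' not leave the contained (intracellular) compartment.
#'
#' @param K1 Delivery rate from blood to tissue, mL/min per cm^3 tissue.
#' @param k2 Efflux rate constant from the free compartment, 1/min.
#' @param k3 Rate constant from the free to the contained compartment, 1/min.
#' @param vb Fractional blood volume, mL blood per mL tissue, in `[0, 1)`.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(K1 = 0.05, k2 = 0.4, k3 = 0.08, vb = 0.05)
#' macro_ki(p)
#' @export
kinetic_params <- function(K1, k2, k3, vb = 0) {
  stopifnot(is.numeric(K1), is.numeric(k2), is.numeric(k3), is.numeric(vb),
            length(K1) == 1L, length(k2) == 1L, length(k3) == 1L,
            length(vb) == 1L)
  if (!is.finite(K1) || K1 < 0) stop("K1 must be finite and >= 0")
  if (!is.finite(k2) || k2 < 0) stop("k2 must be finite and >= 0")
  if (!is.finite(k3) || k3 < 0) stop("k3 must be finite and >= 0")
  if (!is.finite(vb) || vb < 0 || vb >= 1) stop("vb must be in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = 0, vb = vb),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "2T irreversible kinetic parameters\n  K1 = %.4g mL/min/cm^3\n  k2 = %.4g /min\n  k3 = %.4g /min\n  k4 = 0 (fixed)\n  vb = %.4g mL/mL\n  Ki = %.4g mL/min/cm^3\n",
    x$K1, x$k2, x$k3, x$vb,
    if (x$k2 + x$k3 > 0) macro_ki(x) else NA_real_))
  invisible(x)
}

#' Net uptake rate Ki
#'
#' The macro-parameter Ki = K1*k3/(k2+k3), the net clearance of tracer from
#' blood into the irreversibly trapped compartment, in mL/min per cm^3
#' tissue.
#'
#' @param params A [kinetic_params] object.
#' @return Ki in mL/min/cm^3; always in `[0, K1]`.
#' @export
macro_ki <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k2 + params$k3 == 0)
    stop("Ki undefined: k2 + k3 must be > 0")
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Frame schedule of a dynamic PET acquisition
#'
#' A contiguous sequence of reconstruction frames starting at injection
#' (t = 0), stored as start/end times in seconds.
#'
#' @param durations_s Frame durations in seconds, in temporal order.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `end_s`, `mid_min` (frame midpoints in minutes).
#' @seealso [canonical_frame_schedule()]
#' @export
frame_schedule <- function(durations_s) {
  stopifnot(is.numeric(durations_s), length(durations_s) >= 1L,
            all(is.finite(durations_s)))
  if (any(durations_s <= 0)) stop("frame durations must be > 0")
  end_s <- cumsum(durations_s)
  start_s <- c(0, end_s[-length(end_s)])
  structure(list(start_s = start_s, end_s = end_s,
                 mid_min = (start_s + end_s) / 2 / 60),
            class = "frame_schedule")
}

#' Canonical 32-frame dynamic protocol
#'
#' The 25-minute dynamic acquisition used throughout: 12 x 5 s, 3 x 10 s,
#' 3 x 30 s, 6 x 60 s and 8 x 120 s frames (32 frames, 1500 s total).
#'
#' @return A [frame_schedule] with 32 frames spanning 0-25 min.
#' @export
canonical_frame_schedule <- function() {
  frame_schedule(c(rep(5, 12), rep(10, 3), rep(30, 3), rep(60, 6),
                   rep(120, 8)))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame schedule: %d frames, 0 to %.4g min\n",
              length(x$start_s), max(x$end_s) / 60))
  invisible(x)
}

n_frames <- function(schedule) length(schedule$start_s)

#' Plasma input function
#'
#' Wraps evaluable plasma (`cp`) and whole-blood (`cb`) tracer concentration
#' functions of time in minutes, in kBq/mL. By default whole blood is taken
#' equal to plasma (the image-derived aorta curve is fed in unchanged); a
#' plasma-to-whole-blood concentration ratio can be supplied, in which case
#' `cb(t) = cp(t) / ratio`.
#'
#' @param cp Function of time (min) returning plasma concentration, kBq/mL.
#' @param plasma_to_blood_ratio Scalar ratio cp/cb; default 1 (cb == cp).
#' @param model Optional label describing the functional form.
#' @return An object of class `plasma_input` with evaluable `cp` and `cb`.
#' @export
plasma_input <- function(cp, plasma_to_blood_ratio = 1, model = "custom") {
  stopifnot(is.function(cp), is.numeric(plasma_to_blood_ratio),
            length(plasma_to_blood_ratio) == 1L, plasma_to_blood_ratio > 0)
  r <- plasma_to_blood_ratio
  structure(list(cp = cp, cb = function(t) cp(t) / r,
                 plasma_to_blood_ratio = r, model = model),
            class = "plasma_input")
}

#' Tabulated plasma input function
#'
#' Builds a [plasma_input] from sampled (time, concentration) pairs by
#' linear interpolation; concentration is held at the last sample beyond the
#' tabulated range and at the first sample before it.
#'
#' @param t_min Sample times, minutes, strictly increasing.
#' @param cp Plasma concentrations at `t_min`, kBq/mL, nonnegative.
#' @param plasma_to_blood_ratio Scalar ratio cp/cb; default 1.
#' @return A [plasma_input].
#' @export
tabulated_input <- function(t_min, cp, plasma_to_blood_ratio = 1) {
  stopifnot(is.numeric(t_min), is.numeric(cp), length(t_min) == length(cp),
            length(t_min) >= 2L, all(is.finite(t_min)), all(is.finite(cp)))
  if (is.unsorted(t_min, strictly = TRUE))
    stop("t_min must be strictly increasing")
  # tolerate roundoff-scale negatives (e.g. a bolus model's exact zero at
  # t = 0 evaluated in floating point), reject real negative excursions
  if (any(cp < -1e-9 * max(cp, 1)))
    stop("plasma concentrations must be nonnegative")
  f <- stats::approxfun(t_min, pmax(cp, 0), rule = 2)
  plasma_input(f, plasma_to_blood_ratio, model = "tabulated")
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("plasma input function (%s), cp/cb ratio = %g\n",
              x$model, x$plasma_to_blood_ratio))
  invisible(x)
}

# Exponential-update propagator coefficients over one uniform step of
# length h (min) for the lower-triangular system
#   dCf/dt = K1*Cp - a*Cf,  dCc/dt = k3*Cf,
# with the input quadratic within the step, Cp(s) = c0 + b1*s + b2*s^2.
# With I_k = int_0^h e^{-a(h-s)} s^k ds (recurrence I_k = (h^k - k*I_{k-1})/a)
# and J_k = int_0^h int_0^s e^{-a(s-u)} u^k du ds:
#   Cf' = E*Cf + K1*(I0*c0 + I1*b1 + I2*b2)
#   Cc' = Cc + k3*(I0*Cf + K1*(J0*c0 + J1*b1 + J2*b2))
# Series expansions guard the a*h -> 0 limit (cancellation).
step_coefs <- function(a, h) {
  x <- a * h
  if (x < 1e-4) {
    E <- exp(-x)
    I0 <- h * (1 - x / 2 + x^2 / 6 - x^3 / 24)
    I1 <- h^2 * (1 / 2 - x / 6 + x^2 / 24 - x^3 / 120)
    I2 <- h^3 * (1 / 3 - x / 12 + x^2 / 60)
    J1 <- h^3 * (1 / 6 - x / 24 + x^2 / 120 - x^3 / 720)
    J2 <- h^4 * (1 / 12 - x / 60 + x^2 / 360)
  } else {
    E <- exp(-x)
    I0 <- (1 - E) / a
    I1 <- (h - I0) / a
    I2 <- (h^2 - 2 * I1) / a
    J1 <- (h^2 / 2 - I1) / a
    J2 <- (h^3 / 3 - 2 * J1) / a
  }
  list(E = E, I0 = I0, I1 = I1, I2 = I2, J0 = I1, J1 = J1, J2 = J2)
}

# Advance (Cf, Cc) over a uniform node grid with step h, given the input
# sampled at the nodes (cp) and at the step midpoints (cp_mid): the input is
# interpolated quadratically within each step, so node values are accurate
# to O(h^4). Vectorized via a first-order linear recursion (filter) for Cf
# and a cumulative sum of closed-form step integrals for Cc.
propagate_2tc <- function(K1, k2, k3, cp, cp_mid, h) {
  n <- length(cp)
  co <- step_coefs(k2 + k3, h)
  c0 <- cp[-n]
  c1 <- cp[-1]
  b1 <- (4 * cp_mid - 3 * c0 - c1) / h
  b2 <- 2 * (c1 - 2 * cp_mid + c0) / h^2
  bf <- K1 * (co$I0 * c0 + co$I1 * b1 + co$I2 * b2)
  cf <- c(0, stats::filter(bf, co$E, method = "recursive"))
  inc <- k3 * (co$I0 * cf[-n] + K1 * (co$J0 * c0 + co$J1 * b1 +
                                        co$J2 * b2))
  list(cf = cf, cc = c(0, cumsum(inc)))
}

#' Solve the irreversible two-tissue compartment model
#'
#' Integrates
#' \deqn{dC_f/dt = K_1 C_p(t) - (k_2 + k_3) C_f, \quad dC_c/dt = k_3 C_f}
#' with \eqn{C_f(0) = C_c(0) = 0} and returns the total measurable PET
#' signal \eqn{C_T(t) = v_b C_b(t) + (1 - v_b)(C_f(t) + C_c(t))}.
#'
#' The solver is an exact exponential update of the lower-triangular linear
#' system on the (uniform) time grid, with the input function interpolated
#' linearly within each step — unconditionally stable and exact up to the
#' piecewise-linear input approximation.
#'
#' @param params A [kinetic_params] object.
#' @param input_fn A [plasma_input].
#' @param t_grid Uniform time grid in minutes starting at 0.
#' @return A list of class `tissue_curves` with `t`, `cf`, `cc`, `ct_total`
#'   (all kBq/mL).
#' @examples
#' inp <- feng_input()
#' p <- kinetic_params(0.05, 0.4, 0.08, vb = 0.05)
#' curves <- solve_2tc(p, inp, seq(0, 25, by = 0.5 / 60))
#' @export
solve_2tc <- function(params, input_fn, t_grid) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(input_fn, "plasma_input"), is.numeric(t_grid))
  n <- length(t_grid)
  if (n < 2L) stop("invalid grid: need at least 2 time points")
  if (abs(t_grid[1]) > 1e-12) stop("invalid grid: must start at 0")
  h <- diff(t_grid)
  if (any(h <= 0) || diff(range(h)) > 1e-9 * max(h))
    stop("invalid grid: must be uniform and increasing")
  h <- mean(h)

  cp <- input_fn$cp(t_grid)
  cb <- input_fn$cb(t_grid)
  cp_mid <- input_fn$cp(t_grid[-n] + h / 2)
  if (any(!is.finite(cp)) || any(!is.finite(cb)) || any(!is.finite(cp_mid)))
    stop("invalid input: non-finite input-function values")
  if (any(cp < -1e-12) || any(cb < -1e-12))
    stop("invalid input: negative input-function values")

  sol <- propagate_2tc(params$K1, params$k2, params$k3, cp, cp_mid, h)
  cf <- sol$cf
  cc <- sol$cc
  ct <- params$vb * cb + (1 - params$vb) * (cf + cc)
  structure(list(t = t_grid, cf = cf, cc = cc, ct_total = ct),
            class = "tissue_curves")
}

#' Time-activity curve
#'
#' Frame-averaged tissue concentration on a [frame_schedule], with mid-frame
#' timestamps in minutes.
#'
#' @param schedule A [frame_schedule].
#' @param values Frame-averaged concentration, kBq/mL, one per frame.
#' @return An object of class `tac` with `schedule`, `values`, `mid_times`.
#' @export
tac <- function(schedule, values) {
  stopifnot(inherits(schedule, "frame_schedule"), is.numeric(values))
  if (length(values) != n_frames(schedule))
    stop("values length must equal the number of frames")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(schedule = schedule, values = as.numeric(values),
                 mid_times = schedule$mid_min),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("time-activity curve: %d frames, 0 to %.4g min, peak %.4g kBq/mL\n",
              length(x$values), max(x$schedule$end_s) / 60, max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_s = x$schedule$start_s,
             frame_end_s = x$schedule$end_s,
             mid_time_min = x$mid_times,
             conc_kBq_per_mL = x$values)
}

#' Average continuous tissue curves over reconstruction frames
#'
#' Converts the continuous model output of [solve_2tc()] into a frame-wise
#' [tac]: each frame value is the time average of `ct_total` over the frame,
#' computed by integrating a cubic-spline interpolant of the fine-grid
#' curve (quadrature error O(h^4), far below the solver tolerance).
#'
#' @param curves A `tissue_curves` object from [solve_2tc()].
#' @param schedule A [frame_schedule]; must be covered by the curve grid.
#' @return A [tac].
#' @export
frame_average <- function(curves, schedule) {
  stopifnot(inherits(curves, "tissue_curves"),
            inherits(schedule, "frame_schedule"))
  t <- curves$t
  y <- curves$ct_total
  if (max(schedule$end_s) / 60 > max(t) + 1e-9)
    stop("coverage error: schedule extends beyond the curve grid")
  sf <- stats::splinefun(t, y, method = "fmm")
  s0 <- schedule$start_s / 60
  s1 <- schedule$end_s / 60
  vals <- vapply(seq_along(s0), function(i) {
    stats::integrate(sf, s0[i], s1[i], rel.tol = 1e-10,
                     abs.tol = 1e-12)$value / (s1[i] - s0[i])
  }, numeric(1))
  tac(schedule, vals)
}

#' Patlak graphical analysis
#'
#' For an irreversibly trapped tracer, the normalized tissue curve
#' \eqn{C_T(t)/C_p(t)} becomes linear in the "stretched time"
#' \eqn{\int_0^t C_p ds / C_p(t)} past an equilibration time `t_star`;
#' the late-time slope estimates the net uptake rate Ki (scaled by `1 - vb`
#' when the blood term is present). Provides an independent graphical check
#' of the compartmental fit.
#'
#' @param tac A [tac] of measured frame values.
#' @param input_fn A [plasma_input].
#' @param t_star Start of the linear segment, minutes (default 10).
#' @param dt_min Integration step for the plasma integral, minutes.
#' @return List with `slope` (mL/min/cm^3), `intercept`, `n_used`.
#' @export
patlak_estimate <- function(tac, input_fn, t_star = 10, dt_min = 0.5 / 60) {
  stopifnot(inherits(tac, "tac"), inherits(input_fn, "plasma_input"))
  mid <- tac$mid_times
  use <- mid >= t_star
  if (sum(use) < 3L)
    stop("insufficient late frames: need >= 3 frames with mid-time >= t_star")
  grid <- seq(0, max(mid), by = dt_min)
  cp_g <- input_fn$cp(grid)
  cum <- c(0, cumsum((cp_g[-1] + cp_g[-length(grid)]) / 2 * diff(grid)))
  cum_f <- stats::approxfun(grid, cum, rule = 2)
  cp_mid <- input_fn$cp(mid[use])
  if (any(cp_mid <= 0))
    stop("insufficient data: Cp must be > 0 over the used frames")
  x <- cum_f(mid[use]) / cp_mid
  y <- tac$values[use] / cp_mid
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_used = sum(use))
}
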