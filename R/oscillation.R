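# Linearized ADP kernel and theta oscillation, quantized to the 0.01 grid,
# plus the sizing of the theta-neuron banks that deliver them synaptically.

.GRID_EPS <- 1e-9  # guards floor() against float representation error

#' ADP (after-depolarizing potential) specification
#'
#' The original exponential ADP kernel is replaced by a linear ramp of `slope`
#' potential units per ms, quantized on a `grid` of 0.01, and capped at
#' `slope * tau_adp` — the value the linear ramp reaches at the original
#' kernel's peak time. By convention `tau_adp = 12 * gamma_period`.
#'
#' @param slope Ramp slope in potential units (threshold = 1) per ms.
#' @param grid Fixed-point quantization step for ADP/theta values.
#' @param gamma_period Gamma cycle length in ms; sets the default `tau_adp`.
#' @param tau_adp ADP time constant in ms (default `12 * gamma_period`).
#' @return An object of class `adp_spec` with derived field `cap`.
#' @examples
#' sp <- adp_spec()
#' adp_quantized(2, sp)  # 0.01
#' @export
adp_spec <- function(slope = 0.0055, grid = 0.01, gamma_period = 9.9,
                     tau_adp = 12 * gamma_period) {
  stopifnot(slope > 0, grid > 0, tau_adp > 0)
  cap <- slope * tau_adp
  if (cap < grid)
    stop("ADP cap below one quantization step; increase slope or tau_adp")
  structure(list(slope = slope, grid = grid, gamma_period = gamma_period,
                 tau_adp = tau_adp, cap = cap),
            class = "adp_spec")
}

#' @export
print.adp_spec <- function(x, ...) {
  cat(sprintf("<adp_spec> slope=%.4g/ms grid=%.3g tau_adp=%.4g ms cap=%.4g\n",
              x$slope, x$grid, x$tau_adp, x$cap))
  invisible(x)
}

.to_grid <- function(x, grid) {
  floor(x / grid + .GRID_EPS) * grid
}

#' Quantized ADP value at a given post-spike delay
#'
#' Evaluates the linear ADP ramp `slope * dt`, floored to the quantization
#' grid (a non-decreasing staircase lying on or below the line), and capped.
#'
#' @param dt Milliseconds since the neuron's last own spike (vectorized,
#'   `dt >= 0`).
#' @param spec An [adp_spec()].
#' @return ADP values on the grid, in \[0, cap\].
#' @export
adp_quantized <- function(dt, spec = adp_spec()) {
  stopifnot(all(dt >= 0))
  pmin(.to_grid(spec$slope * dt, spec$grid), .to_grid(spec$cap, spec$grid))
}

#' Difference encoding of the ADP staircase
#'
#' Per-step increments `adp_quantized(dt) - adp_quantized(dt - 1)` delivered
#' by the attached ADP neuron: each increment is 0 or one grid step, and their
#' running sum telescopes back to the staircase.
#'
#' @param spec An [adp_spec()].
#' @param horizon Number of milliseconds to tabulate (`dt = 1..horizon`).
#' @return A data.frame with columns `dt` and `increment`.
#' @export
adp_increment_schedule <- function(spec = adp_spec(), horizon) {
  stopifnot(horizon > 0)
  dt <- seq_len(horizon)
  inc <- adp_quantized(dt, spec) - adp_quantized(dt - 1, spec)
  data.frame(dt = dt, increment = inc)
}

#' Theta oscillation specification
#'
#' A sine waveform `amplitude * sin(2*pi*t/period)` quantized to the 0.01
#' grid. The amplitude must be an integer multiple of the synaptic quantum
#' `w_theta`, since each quantum is carried by one theta-bank neuron. Inputs
#' are presented at theta valleys, i.e. at phase `phase_of_valley`
#' (3/4 period by default).
#'
#' @param period Theta period in ms (default 66).
#' @param amplitude Peak amplitude in potential units (default 0.6, at most 1).
#' @param w_theta Synaptic weight quantum of theta-bank neurons (default 0.01).
#' @param phase_of_valley Time (ms, within one period) of the waveform
#'   minimum; default `0.75 * period`.
#' @return An object of class `theta_spec`.
#' @export
theta_spec <- function(period = 66, amplitude = 0.6, w_theta = 0.01,
                       phase_of_valley = 0.75 * period) {
  stopifnot(period > 0, amplitude > 0, amplitude <= 1, w_theta > 0)
  n1 <- amplitude / w_theta
  if (abs(n1 - round(n1)) > 1e-8)
    stop("theta amplitude must be an integer multiple of w_theta")
  structure(list(period = period, amplitude = amplitude, w_theta = w_theta,
                 waveform = "sine", phase_of_valley = phase_of_valley),
            class = "theta_spec")
}

#' @export
print.theta_spec <- function(x, ...) {
  cat(sprintf("<theta_spec> period=%.4g ms amplitude=%.3g w_theta=%.3g\n",
              x$period, x$amplitude, x$w_theta))
  invisible(x)
}

#' Quantized theta oscillation value
#'
#' @param t Time in ms (vectorized, `t >= 0`).
#' @param spec A [theta_spec()].
#' @return `amplitude * sin(2*pi*t/period)` floored to the `w_theta` grid.
#' @examples
#' sp <- theta_spec()
#' theta_value(sp$period / 4, sp)  # 0.60, the quantized peak
#' @export
theta_value <- function(t, spec = theta_spec()) {
  stopifnot(all(t >= 0))
  .theta_quanta(t, spec) * spec$w_theta
}

# theta value in integer quanta of w_theta (exact integer arithmetic for
# the difference encoding)
.theta_quanta <- function(t, spec) {
  x <- spec$amplitude * sin(2 * pi * t / spec$period)
  floor(x / spec$w_theta + .GRID_EPS)
}

#' Size the theta-neuron banks
#'
#' The theta drive is delivered by two banks of auxiliary neurons, each with
#' synaptic weight quantum `w_theta` onto every recall-layer normal neuron:
#' amplitude-encoding neurons re-inject the previous step's theta value after
#' a fire-and-reset, and difference-encoding neurons deliver the step-to-step
#' change of the waveform. Their counts are `amplitude / w_theta` and
#' `ceiling(max |d theta/dt| * 1 ms / w_theta)` respectively: 60 and 6 for the
#' default 66 ms / 0.6 / 0.01 configuration.
#'
#' @param spec A [theta_spec()].
#' @return An object of class `theta_bank` with fields `n_theta1`, `n_theta2`
#'   and `weight_quantum`.
#' @export
theta_bank <- function(spec = theta_spec()) {
  n1 <- as.integer(round(spec$amplitude / spec$w_theta))
  n2 <- as.integer(ceiling(2 * pi * spec$amplitude /
                             (spec$period * spec$w_theta) - .GRID_EPS))
  structure(list(n_theta1 = n1, n_theta2 = n2, weight_quantum = spec$w_theta),
            class = "theta_bank")
}

#' @export
print.theta_bank <- function(x, ...) {
  cat(sprintf("<theta_bank> %d amplitude neurons + %d difference neurons (quantum %.3g)\n",
              x$n_theta1, x$n_theta2, x$weight_quantum))
  invisible(x)
}

#' Signed theta-bank activations for one evaluation step
#'
#' Returns how many theta-bank neurons are active at step `t` (negative
#' counts denote delivery through the negative-weight side of the bank):
#' the difference bank delivers `(theta(t) - theta(t-1)) / w_theta` every
#' step, and the amplitude bank re-injects `theta(t-1) / w_theta` only on the
#' step after the target neuron fired and reset (restoring the theta baseline
#' lost at reset).
#'
#' @param t Time in ms, `t >= 1`.
#' @param fired_last_step Did the target neuron fire at `t - 1`?
#' @param spec A [theta_spec()].
#' @return A list with integer fields `n_theta1_active` and `n_theta2_active`.
#' @export
theta_drive <- function(t, fired_last_step, spec = theta_spec()) {
  stopifnot(t >= 1)
  q_now <- .theta_quanta(t, spec)
  q_prev <- .theta_quanta(t - 1, spec)
  list(n_theta1_active = if (fired_last_step) as.integer(q_prev) else 0L,
       n_theta2_active = as.integer(q_now - q_prev))
}

#' Times of theta valleys
#'
#' Valley times within `[0, horizon)`: `phase_of_valley + k * period`.
#' Inputs are presented at these times.
#'
#' @param spec A [theta_spec()].
#' @param horizon Simulation horizon in ms.
#' @return Numeric vector of valley times.
#' @export
theta_valleys <- function(spec = theta_spec(), horizon) {
  v0 <- spec$phase_of_valley %% spec$period
  out <- seq(v0, horizon, by = spec$period)
  out[out < horizon]
}
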