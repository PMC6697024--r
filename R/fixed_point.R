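#' stmnet: fixed-point spiking memory network simulator
#'
#' Software model of a hardware-adapted spatio-temporal memory (STM) spiking
#' neural network: fixed-point leaky integrate-and-fire (LIF) neurons,
#' theta-oscillation and after-depolarizing-potential (ADP) machinery realized
#' as auxiliary neuron banks, assembly-coded associative and episodic memory,
#' tempotron/STDP training with post-hoc quantization, and robustness
#' experiments scored with a Gaussian-filtered spike-train correlation.
#'
#' @keywords internal
"_PACKAGE"

# 14-bit signed membrane-potential range shared by all neurons.
.POT_MIN <- -8192L
.POT_MAX <- 8191L

#' Fixed-point conversion specification
#'
#' Describes how trained floating-point parameters are converted to the
#' hardware integer representation: `scale` integer units per 1.0 of trained
#' value (the training threshold of 1 maps to the hardware threshold of
#' `scale`), the signed bit width of synaptic weights, the signed bit width of
#' neuron potentials/thresholds, and the rounding rule.
#'
#' @param scale Integer units per 1.0 of trained float value. Default 1000,
#'   which maps the float training threshold 1 to the integer threshold 1000.
#' @param weight_bits Signed bit width of synaptic weights (default 11,
#'   i.e. weights in \[-1024, 1023\]).
#' @param neuron_bits Signed bit width of potentials, thresholds and reset
#'   potentials (default 14).
#' @param rounding Rounding mode; only `"half-away-from-zero"` is implemented.
#' @return An object of class `fixed_point_spec`.
#' @examples
#' spec <- fixed_point_spec()
#' fp_quantize(1.0, spec)   # 1000
#' fp_quantize(-1.5, spec)  # clamped to -1024
#' @export
fixed_point_spec <- function(scale = 1000L, weight_bits = 11L,
                             neuron_bits = 14L,
                             rounding = "half-away-from-zero") {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0,
            weight_bits >= 2, neuron_bits >= 2)
  rounding <- match.arg(rounding, "half-away-from-zero")
  structure(list(scale = as.integer(scale),
                 weight_bits = as.integer(weight_bits),
                 neuron_bits = as.integer(neuron_bits),
                 rounding = rounding),
            class = "fixed_point_spec")
}

#' @export
print.fixed_point_spec <- function(x, ...) {
  cat(sprintf("<fixed_point_spec> scale=%d weight_bits=%d neuron_bits=%d (%s)\n",
              x$scale, x$weight_bits, x$neuron_bits, x$rounding))
  invisible(x)
}

.bit_range <- function(bits) {
  c(-(2^(bits - 1)), 2^(bits - 1) - 1)
}

#' Per-neuron fixed-point parameter record
#'
#' Bundles the four per-neuron hardware parameters: a 14-bit signed membrane
#' potential, an 8-bit signed leak, a 14-bit signed reset potential and a
#' 14-bit signed threshold. Validity: `reset_potential <= threshold`, and the
#' threshold must be positive for ordinary neurons (auxiliary ADP neurons may
#' use `reset_potential == threshold` to fire continuously once activated).
#'
#' @param leak Integer leak subtracted each millisecond (8-bit signed).
#' @param reset_potential Potential after a spike (14-bit signed).
#' @param threshold Firing threshold (14-bit signed, positive).
#' @param potential Initial potential (14-bit signed), default 0.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(leak, reset_potential, threshold, potential = 0L) {
  stopifnot(length(leak) == 1, length(reset_potential) == 1,
            length(threshold) == 1, length(potential) == 1)
  pr <- .bit_range(14)
  lr <- .bit_range(8)
  if (potential < pr[1] || potential > pr[2])
    stop("potential outside the 14-bit signed range")
  if (leak < lr[1] || leak > lr[2])
    stop("leak outside the 8-bit signed range")
  if (reset_potential < pr[1] || reset_potential > pr[2] ||
      threshold < pr[1] || threshold > pr[2])
    stop("reset_potential/threshold outside the 14-bit signed range")
  if (reset_potential > threshold)
    stop("reset_potential must not exceed threshold")
  if (threshold <= 0)
    stop("threshold must be positive")
  structure(list(potential = as.integer(potential), leak = as.integer(leak),
                 reset_potential = as.integer(reset_potential),
                 threshold = as.integer(threshold)),
            class = "neuron_params")
}

#' Synaptic integration with saturating arithmetic
#'
#' Adds the weights of all synapses whose presynaptic neuron spiked in the
#' previous step to the membrane potential, saturating (clamping, not
#' wrapping) at the 14-bit signed boundaries. Each weight must lie in the
#' 11-bit signed range.
#'
#' @param v Membrane potential (14-bit signed integer).
#' @param active_weights Numeric vector of weights of the active synapses
#'   (may be empty).
#' @param weight_bits Signed bit width weights are checked against.
#' @return Updated potential, clamped to \[-8192, 8191\].
#' @examples
#' fp_integrate(0, c(300, 300))  # 600
#' fp_integrate(8100, 300)       # saturates at 8191
#' @export
fp_integrate <- function(v, active_weights = numeric(0), weight_bits = 11L) {
  wr <- .bit_range(weight_bits)
  if (length(active_weights) &&
      (any(active_weights < wr[1]) || any(active_weights > wr[2])))
    stop(sprintf("weight outside the %d-bit signed range", weight_bits))
  out <- v + sum(active_weights)
  min(max(out, .POT_MIN), .POT_MAX)
}

#' Leak with a resting floor
#'
#' Subtracts the per-step leak from the potential, clamping the result at
#' `floor` (0 by default) so the recovery terminates at rest. A zero leak is
#' the identity (used by ADP and theta neurons, whose potentials are managed
#' exactly); the floor only engages through a non-zero leak.
#'
#' @param v Membrane potential (vectorized).
#' @param leak Non-negative leak value, one per element of `v` or scalar.
#' @param floor Resting floor, default 0.
#' @return Updated potential(s).
#' @examples
#' fp_leak(1000, 45)  # 955
#' fp_leak(30, 45)    # clamped at 0
#' @export
fp_leak <- function(v, leak, floor = 0) {
  leak <- rep_len(leak, length(v))
  out <- v
  pos <- leak > 0
  out[pos] <- pmax(v[pos] - leak[pos], floor)
  out
}

#' Threshold comparison with fire-and-reset
#'
#' The neuron fires iff `v >= threshold`; on firing the potential is set to
#' the reset potential, otherwise it is unchanged. A neuron configured with
#' `reset_potential == threshold` and zero leak therefore fires on every step
#' after its first activation (the ADP-neuron contract).
#'
#' @param v Membrane potential.
#' @param params A [neuron_params()] object, or a list with `threshold` and
#'   `reset_potential` fields.
#' @return A list with elements `fired` (logical) and `potential`.
#' @examples
#' fp_fire_reset(1000, neuron_params(45, 0, 1000))   # fires, resets to 0
#' fp_fire_reset(999, neuron_params(45, 0, 1000))    # no fire
#' @export
fp_fire_reset <- function(v, params) {
  fired <- v >= params$threshold
  list(fired = fired,
       potential = if (fired) params$reset_potential else v)
}

#' Round-half-away-from-zero
#'
#' Base R's `round()` rounds halves to even; hardware conversion uses
#' half-away-from-zero.
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Quantize a trained float value to a signed fixed-point integer
#'
#' Multiplies by the scale, rounds half-away-from-zero, and clamps to the
#' signed range of the requested bit width.
#'
#' @param x Numeric vector of trained float values (must be finite).
#' @param spec A [fixed_point_spec()].
#' @param bits Signed bit width to clamp to; defaults to `spec$weight_bits`.
#' @return Integer-valued numeric vector.
#' @examples
#' fp_quantize(1.0, fixed_point_spec(), bits = 14)  # 1000
#' fp_quantize(-1.5, fixed_point_spec())            # -1024
#' @export
fp_quantize <- function(x, spec = fixed_point_spec(), bits = spec$weight_bits) {
  if (any(!is.finite(x)))
    stop("cannot quantize non-finite values")
  r <- .bit_range(bits)
  pmin(pmax(round_half_away(x * spec$scale), r[1]), r[2])
}
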