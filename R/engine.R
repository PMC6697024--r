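# Time-stepped (1 ms) simulation of the memory network. Per neuron and step:
# synaptic integration over the spikes emitted at t-1, then leak, then
# threshold/fire/reset; all synapses carry a uniform one-step delay. The
# theta banks and ADP staircase increments are delivered by the engine as
# signed activation counts of the auxiliary neurons (see the methods
# vignette for the difference-encoding convention).

#' Stimulus schedule
#'
#' Pairs pattern labels with presentation times. When `times` is NULL the
#' k-th requested pattern is presented at the k-th theta valley (the model's
#' presentation convention); explicit times are snapped to the valley phase
#' when `align_to_valley` is TRUE.
#'
#' @param labels Pattern labels to present, in order.
#' @param patterns An `input_patterns` object from [generate_patterns()].
#' @param theta A [theta_spec()] (sets the valley times).
#' @param times Optional explicit presentation times (ms).
#' @param align_to_valley Snap explicit times to the valley phase.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(labels, patterns, theta = theta_spec(),
                              times = NULL, align_to_valley = TRUE) {
  if (is.null(times)) {
    v0 <- theta$phase_of_valley %% theta$period
    times <- v0 + (seq_along(labels) - 1) * theta$period
  } else if (align_to_valley) {
    v0 <- theta$phase_of_valley %% theta$period
    times <- round((times - v0) / theta$period) * theta$period + v0
  }
  stopifnot(length(times) == length(labels), all(times >= 0))
  structure(list(labels = labels, times = times, patterns = patterns),
            class = "stimulus_schedule")
}

# Build the static engine context: dense delivery matrix (theta columns
# zeroed; their drive is added analytically), per-neuron parameter vectors,
# id groups, scaled constants.
.engine_context <- function(net) {
  scale <- attr(net, "scale")
  neurons <- net$neurons
  n <- nrow(neurons)
  Wt <- matrix(0, n, n)  # Wt[post, pre]
  syn <- net$synapses
  keep <- !(syn$kind %in% c("theta1", "theta2"))
  s <- syn[keep, ]
  for (r in seq_len(nrow(s)))
    Wt[s$post[r], s$pre[r]] <- Wt[s$post[r], s$pre[r]] + s$weight[r]
  recall_ids <- neurons$id[neurons$role == "normal" & neurons$layer == "recall"]
  adp_ids <- neurons$id[neurons$role == "adp"]
  # attachment: adp neuron i <-> recall normal i (same construction order)
  wq <- if (scale > 1) fp_quantize(net$theta$w_theta, fixed_point_spec(scale))
        else net$theta$w_theta
  grid_u <- if (scale > 1) fp_quantize(net$adp$grid, fixed_point_spec(scale))
            else net$adp$grid
  bounds <- c(.POT_MIN, .POT_MAX) * scale / 1000
  thr <- neurons$threshold
  thr[!is.finite(thr)] <- Inf
  list(n = n, Wt = Wt, scale = scale, neurons = neurons,
       recall_ids = recall_ids, adp_ids = adp_ids,
       input_ids = neurons$id[neurons$role == "input"],
       th1_ids = neurons$id[neurons$role == "theta1"],
       th2_ids = neurons$id[neurons$role == "theta2"],
       lif = neurons$role %in% c("normal", "interneuron", "adp"),
       leak = neurons$leak, reset = neurons$reset, thr = thr,
       wq = wq, grid_u = grid_u, bounds = bounds,
       theta = net$theta, adp = net$adp)
}

.blank_state <- function(ctx) {
  list(t = 0L, v = numeric(ctx$n), prev_fired = logical(ctx$n),
       last_fire = rep(NA_integer_, length(ctx$recall_ids)))
}

# map a schedule into per-ms input-channel spike lists
.input_events <- function(schedule, ctx, horizon) {
  ev <- vector("list", horizon)
  if (is.null(schedule)) return(ev)
  for (i in seq_along(schedule$labels)) {
    p <- schedule$patterns$patterns[[as.character(schedule$labels[i])]]
    tt <- as.integer(round(schedule$times[i] + p$time))
    for (r in seq_along(tt)) {
      t1 <- tt[r]
      if (t1 >= 1 && t1 <= horizon) {
        id <- ctx$input_ids[p$channel[r]]
        ev[[t1]] <- c(ev[[t1]], id)
      }
    }
  }
  ev
}

# one engine step; returns list(state, fired_ids)
.engine_step <- function(state, ctx, input_spike_ids, t) {
  v <- state$v
  prev <- state$prev_fired
  # synaptic integration over spikes emitted at t-1
  ids <- which(prev)
  if (length(ids))
    v <- v + rowSums(ctx$Wt[, ids, drop = FALSE])
  # theta drive onto recall normals: difference bank every step, amplitude
  # bank re-injection on the step after a fire-and-reset
  q_now <- .theta_quanta(t, ctx$theta)
  q_prev <- .theta_quanta(t - 1, ctx$theta)
  d2 <- q_now - q_prev
  v[ctx$recall_ids] <- v[ctx$recall_ids] + d2 * ctx$wq
  fired_rc_prev <- prev[ctx$recall_ids]
  if (any(fired_rc_prev))
    v[ctx$recall_ids[fired_rc_prev]] <-
      v[ctx$recall_ids[fired_rc_prev]] + q_prev * ctx$wq
  # ADP staircase increments for active chains (ADP neuron fired at t-1)
  chain <- prev[ctx$adp_ids]
  if (any(chain)) {
    dt <- t - state$last_fire[chain]
    inc <- adp_quantized(pmax(dt, 0), ctx$adp) -
           adp_quantized(pmax(dt - 1, 0), ctx$adp)
    v[ctx$recall_ids[chain]] <- v[ctx$recall_ids[chain]] +
      round(inc / ctx$adp$grid) * ctx$grid_u
  }
  # saturate, leak (with resting floor), threshold/fire/reset
  v <- pmin(pmax(v, ctx$bounds[1]), ctx$bounds[2])
  v <- ifelse(ctx$leak > 0, pmax(v - ctx$leak, 0), v)
  fired <- ctx$lif & (v >= ctx$thr)
  v[fired] <- ctx$reset[fired]
  # externally driven populations
  if (length(input_spike_ids)) fired[input_spike_ids] <- TRUE
  if (d2 != 0) fired[ctx$th2_ids[seq_len(min(abs(d2), length(ctx$th2_ids)))]] <- TRUE
  if (any(fired_rc_prev) && q_prev != 0)
    fired[ctx$th1_ids[seq_len(min(abs(q_prev), length(ctx$th1_ids)))]] <- TRUE
  # record last fire times of recall normals (drives the ADP staircase age)
  rc_fired <- fired[ctx$recall_ids]
  state$last_fire[rc_fired] <- t
  state$v <- v
  state$prev_fired <- fired
  state$t <- t
  list(state = state, fired_ids = which(fired))
}

#' Run the network for a horizon of milliseconds
#'
#' Deterministic time-stepped simulation. Returns the spike raster of all
#' roles (filterable by layer/role); optionally also the final engine state,
#' which can be passed back via `init_state` to resume a run — the
#' continuation is identical to an uninterrupted run.
#'
#' @param net An `stm_network` (float or fixed-point).
#' @param schedule A [stimulus_schedule()] or NULL.
#' @param horizon Number of 1 ms steps to simulate.
#' @param seed Optional RNG seed (the dynamics are deterministic; accepted
#'   for interface uniformity).
#' @param init_state Engine state from a previous `return_state = TRUE` run.
#' @param return_state Also return the final state.
#' @return A `spike_raster` data.frame (`time_ms`, `neuron_id`, `role`,
#'   `layer`, `assembly`), or `list(raster, state)` when
#'   `return_state = TRUE`.
#' @export
run_network <- function(net, schedule = NULL, horizon = 400, seed = NULL,
                        init_state = NULL, return_state = FALSE) {
  stopifnot(horizon >= 1)
  if (!is.null(seed)) set.seed(seed)
  ctx <- .engine_context(net)
  state <- if (is.null(init_state)) .blank_state(ctx) else init_state
  t0 <- state$t
  ev <- .input_events(schedule, ctx, t0 + horizon)
  times <- integer(0); ids <- integer(0)
  acc <- list(); n_acc <- 0
  for (t in seq.int(t0 + 1L, t0 + horizon)) {
    spikes_in <- if (t <= length(ev)) ev[[t]] else NULL
    res <- .engine_step(state, ctx, spikes_in, t)
    state <- res$state
    if (length(res$fired_ids)) {
      n_acc <- n_acc + 1
      acc[[n_acc]] <- cbind(t, res$fired_ids)
    }
  }
  m <- if (n_acc) do.call(rbind, acc) else matrix(integer(0), ncol = 2)
  idx <- match(m[, 2], ctx$neurons$id)
  raster <- data.frame(time_ms = m[, 1], neuron_id = m[, 2],
                       role = ctx$neurons$role[idx],
                       layer = ctx$neurons$layer[idx],
                       assembly = ctx$neurons$assembly[idx])
  class(raster) <- c("spike_raster", "data.frame")
  attr(raster, "horizon") <- t0 + horizon
  if (return_state) list(raster = raster, state = state) else raster
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d events over %s ms\n", nrow(x),
              attr(x, "horizon")))
  print(table(x$role))
  invisible(x)
}

#' Spike times of one layer's normal neurons
#'
#' @param raster A `spike_raster`.
#' @param layer Layer name (`"recall"` or `"layer2"`).
#' @param assembly Optional assembly label filter.
#' @param window Optional `c(from, to)` half-open time window.
#' @return The filtered raster rows.
#' @export
raster_slice <- function(raster, layer = "recall", assembly = NULL,
                         window = NULL) {
  out <- raster[raster$layer == layer & raster$role == "normal", ]
  if (!is.null(assembly)) out <- out[!is.na(out$assembly) &
                                       out$assembly %in% assembly, ]
  if (!is.null(window)) out <- out[out$time_ms >= window[1] &
                                     out$time_ms < window[2], ]
  out
}

#' Episodic recall from a single cue
#'
#' Presents only `cue` at the first theta valley and returns the distinct
#' layer-II assemblies in order of first activation. With a trained episodic
#' sequence whose first element is the cue, the full sequence is returned in
#' its stored order; an untrained network returns an empty vector.
#'
#' @param net A trained `stm_network`.
#' @param patterns The `input_patterns` the network was trained on.
#' @param cue Pattern label to present.
#' @param horizon Simulation horizon in ms.
#' @return Integer vector of layer-II assembly labels in first-activation
#'   order.
#' @export
recall_episode <- function(net, patterns, cue, horizon = 300) {
  if (!as.character(cue) %in% names(patterns$patterns))
    stop(sprintf("unknown cue label '%s'", cue))
  sched <- stimulus_schedule(cue, patterns, net$theta)
  raster <- run_network(net, sched, horizon = horizon)
  l2 <- raster_slice(raster, "layer2")
  if (!nrow(l2)) return(integer(0))
  first <- tapply(l2$time_ms, l2$assembly, min)
  as.integer(names(sort(first)))
}
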