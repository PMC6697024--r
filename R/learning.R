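# Floating-point training: tempotron rule for the inter-layer feedforward
# weights, STDP for the intra-layer lateral weights, then fixed-point
# conversion of the trained network.

#' Learning hyper-parameters
#'
#' The temporal learning rules themselves are standard; their constants are
#' exposed here. The tempotron uses a single-exponential synaptic trace
#' (matching the LIF inference neurons) with time constant
#' `tempotron_kernel_tau`, a learning rate `tempotron_lr`, and a decision
#' margin: a target neuron must peak at least `margin` above threshold, a
#' non-target neuron must stay `margin` below it. STDP is additive with
#' exponential windows and weight clipping.
#'
#' @param tempotron_lr Tempotron learning rate.
#' @param tempotron_kernel_tau Trace time constant in ms (default: one gamma
#'   period).
#' @param margin Decision margin in threshold units.
#' @param stdp_a_plus,stdp_a_minus Potentiation/depression amplitudes.
#' @param stdp_tau_plus,stdp_tau_minus Window time constants in ms.
#' @param w_max_ff Cap on feedforward weights (threshold units).
#' @param w_max_lat Cap on recall-layer (auto-associative) lateral weights;
#'   kept below threshold / assembly size so a synchronized volley cannot
#'   re-excite itself through the recurrent connections.
#' @param w_max_lat2 Cap on layer-II (episodic) lateral weights; sized so one
#'   full assembly volley ignites the next assembly in the stored sequence.
#' @param n_stdp_reps Number of presentations in the STDP phase.
#' @param epochs Maximum tempotron epochs (early stop on zero errors).
#' @param seed RNG seed for the weight initialization.
#' @return A named list of class `learning_config`.
#' @export
learning_config <- function(tempotron_lr = 0.02, tempotron_kernel_tau = 9.9,
                            margin = 0.1, stdp_a_plus = 0.02,
                            stdp_a_minus = 0.02, stdp_tau_plus = 9.9,
                            stdp_tau_minus = 9.9, w_max_ff = 0.25,
                            w_max_lat = 0.08, w_max_lat2 = 0.15,
                            n_stdp_reps = 20,
                            epochs = 200, seed = 42L) {
  stopifnot(tempotron_lr > 0, tempotron_kernel_tau > 0, stdp_a_plus > 0,
            stdp_a_minus > 0, stdp_tau_plus > 0, stdp_tau_minus > 0,
            epochs >= 1)
  structure(list(tempotron_lr = tempotron_lr,
                 tempotron_kernel_tau = tempotron_kernel_tau, margin = margin,
                 stdp_a_plus = stdp_a_plus, stdp_a_minus = stdp_a_minus,
                 stdp_tau_plus = stdp_tau_plus,
                 stdp_tau_minus = stdp_tau_minus, w_max_ff = w_max_ff,
                 w_max_lat = w_max_lat, w_max_lat2 = w_max_lat2,
                 n_stdp_reps = n_stdp_reps,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "learning_config")
}

# Leaky potential trajectories (no reset, floor at 0) for a bank of
# postsynaptic neurons sharing the same presynaptic channels.
# W: n_post x n_pre; spikes: data.frame(pre, time); one-step delivery delay.
# ext: optional common per-step external drive (the theta increments the
# recall layer receives in situ, so training sees the inference condition).
.potential_traj <- function(W, spikes, leak, window, ext = NULL) {
  n_post <- nrow(W)
  V <- matrix(0, n_post, window)
  v <- numeric(n_post)
  for (t in seq_len(window)) {
    ids <- spikes$pre[spikes$time == t - 1]
    if (length(ids))
      v <- v + rowSums(W[, ids, drop = FALSE])
    if (!is.null(ext)) v <- v + ext[t]
    v <- pmax(v - leak, 0)
    V[, t] <- v
  }
  V
}

# quantized theta increments over a training window starting at the
# presentation valley (the drive the difference bank delivers at inference)
.valley_theta_ext <- function(theta, window) {
  v0 <- theta$phase_of_valley %% theta$period
  tt <- v0 + seq_len(window)
  (.theta_quanta(tt, theta) - .theta_quanta(tt - 1, theta)) * theta$w_theta
}

#' One tempotron weight update for a single postsynaptic neuron
#'
#' Implements the fire/no-fire tempotron correction: when the neuron should
#' have fired but did not (a miss), every presynaptic spike preceding the time
#' of maximal potential is potentiated by `lr * K(t_max - t_j)` with
#' `K(s) = exp(-s / tau)`; a false alarm applies the same magnitude
#' negatively; a correct decision leaves the weights unchanged. Weights are
#' clipped to `[0, w_max]`.
#'
#' @param w Numeric weight vector, one entry per presynaptic channel.
#' @param pre_spikes data.frame with columns `pre` (channel index into `w`)
#'   and `time` (ms within the decision window).
#' @param target_fired,actual_fired Desired and observed decisions.
#' @param cfg A [learning_config()].
#' @param t_max Time of maximal potential within the window; computed from a
#'   leaky no-reset trajectory when NULL.
#' @param leak,window Used only when `t_max` is NULL.
#' @param w_max Weight cap; defaults to `cfg$w_max_ff`.
#' @return The updated weight vector.
#' @export
tempotron_update <- function(w, pre_spikes, target_fired, actual_fired, cfg,
                             t_max = NULL, leak = 0.045, window = NULL,
                             w_max = cfg$w_max_ff) {
  if (target_fired == actual_fired) return(w)
  if (is.null(t_max)) {
    if (is.null(window)) window <- max(pre_spikes$time) + 5
    V <- .potential_traj(matrix(w, nrow = 1), pre_spikes, leak, window)
    t_max <- if (max(V) == 0) max(pre_spikes$time) + 1 else which.max(V[1, ])
  }
  sgn <- if (target_fired) 1 else -1
  for (r in which(pre_spikes$time <= t_max)) {
    j <- pre_spikes$pre[r]
    w[j] <- w[j] + sgn * cfg$tempotron_lr *
      exp(-(t_max - pre_spikes$time[r]) / cfg$tempotron_kernel_tau)
  }
  pmin(pmax(w, 0), w_max)
}

#' One STDP weight update
#'
#' Additive spike-timing-dependent plasticity with exponential windows:
#' potentiation by `A_plus * exp(-dt / tau_plus)` when the presynaptic spike
#' precedes the postsynaptic one (`dt = t_post - t_pre > 0`), depression by
#' `A_minus * exp(dt / tau_minus)` for the reverse order, no change at
#' `dt = 0`. The result is clipped to `[0, w_max]`.
#'
#' @param w Weight (vectorized).
#' @param delta_t `t_post - t_pre` in ms (vectorized).
#' @param cfg A [learning_config()].
#' @param w_max Weight cap; defaults to `cfg$w_max_lat`.
#' @return Updated weight(s).
#' @export
stdp_update <- function(w, delta_t, cfg, w_max = cfg$w_max_lat) {
  dw <- ifelse(delta_t > 0, cfg$stdp_a_plus * exp(-delta_t / cfg$stdp_tau_plus),
        ifelse(delta_t < 0, -cfg$stdp_a_minus * exp(delta_t / cfg$stdp_tau_minus),
               0))
  pmin(pmax(w + dw, 0), w_max)
}

# Train one feedforward stage by the tempotron rule.
# pre_trains: list over patterns of data.frame(pre, time) (pre indexes the
# columns of W); targets: list over patterns of logical vectors (n_post).
# margins: per-postsynaptic-neuron firing margin (scalar recycled); when the
# stage has not converged after half the epoch budget, margins are annealed
# down to the base cfg$margin (margins above the base are reach goals that
# buy noise robustness where the pattern geometry allows them).
# Returns list(W, log, converged).
.train_stage <- function(W, pre_trains, targets, leak, cfg, w_max, window,
                         stage, margins = cfg$margin, ext = NULL) {
  n_post <- nrow(W)
  margins <- rep_len(margins, n_post)
  log <- NULL
  converged <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    if (epoch == floor(cfg$epochs / 2) + 1 && !converged)
      margins <- rep_len(cfg$margin, n_post)
    errors <- 0L
    for (p in seq_along(pre_trains)) {
      sp <- pre_trains[[p]]
      V <- .potential_traj(W, sp, leak, window, ext)
      if (!nrow(sp)) next
      vmax <- apply(V, 1, max)
      tmax <- apply(V, 1, which.max)
      tmax[vmax == 0] <- max(sp$time) + 1
      tgt <- targets[[p]]
      miss <- tgt & (vmax < 1 + margins)
      false <- !tgt & (vmax >= 1 - cfg$margin)
      for (i in which(miss | false)) {
        errors <- errors + 1L
        keep <- sp$time <= tmax[i]
        sgn <- if (tgt[i]) 1 else -1
        kern <- exp(-(tmax[i] - sp$time[keep]) / cfg$tempotron_kernel_tau)
        dw <- numeric(ncol(W))
        dwk <- sgn * cfg$tempotron_lr * kern
        for (r in seq_along(dwk)) {
          j <- sp$pre[keep][r]
          dw[j] <- dw[j] + dwk[r]
        }
        W[i, ] <- pmin(pmax(W[i, ] + dw, 0), w_max)
      }
    }
    log <- rbind(log, data.frame(stage = stage, epoch = epoch,
                                 errors = errors))
    if (errors == 0L) { converged <- TRUE; break }
  }
  list(W = W, log = log, converged = converged)
}

# First threshold-crossing times (teacher trains) for a trained stage:
# returns data.frame(pre, time) of postsynaptic first-fire times, with `pre`
# indexing the postsynaptic bank.
.crossing_times <- function(W, spikes, leak, window, ext = NULL) {
  V <- .potential_traj(W, spikes, leak, window, ext)
  cross <- apply(V >= 1, 1, function(z) if (any(z)) which(z)[1] else NA)
  data.frame(pre = which(!is.na(cross)), time = cross[!is.na(cross)])
}

#' Train the memory network
#'
#' Offline floating-point training in three phases. (1) The input-to-layer-I
#' feedforward weights are trained by the tempotron rule so that each
#' layer-I/recall assembly fires iff its own pattern is presented. (2) The
#' recall-to-layer-II feedforward weights are trained the same way on the
#' layer-I response volleys. (3) Lateral weights are shaped by STDP on the
#' teacher spike trains produced by the trained feedforward stages: each
#' pattern presented in isolation potentiates the recurrent connections
#' within its own recall assembly (auto-association / pattern completion),
#' and, when a pattern `sequence` is given, a temporally compressed
#' presentation of the sequence (one gamma period between items) potentiates
#' the forward inter-assembly connections in layer II (episodic memory).
#' There is no online learning at inference time.
#'
#' @param net An untrained float-unit `stm_network` (hardware mode).
#' @param patterns An `input_patterns` object from [generate_patterns()].
#' @param sequence Ordered pattern labels of the episodic item, or NULL.
#' @param cfg A [learning_config()].
#' @return The network with trained float weights; attributes `training_log`
#'   (data.frame stage/epoch/errors) and `trained = TRUE`. Issues a warning
#'   (with diagnostics) when a tempotron stage has residual errors after
#'   `cfg$epochs` epochs.
#' @export
train_network <- function(net, patterns, sequence = NULL,
                          cfg = learning_config()) {
  stopifnot(inherits(net, "stm_network"), attr(net, "scale") == 1,
            net$on_hardware)
  set.seed(cfg$seed)
  neurons <- net$neurons
  input_ids <- neurons$id[neurons$role == "input"]
  recall_ids <- neurons$id[neurons$role == "normal" & neurons$layer == "recall"]
  l2_ids <- neurons$id[neurons$role == "normal" & neurons$layer == "layer2"]
  rc_assembly <- neurons$assembly[match(recall_ids, neurons$id)]
  l2_assembly <- neurons$assembly[match(l2_ids, neurons$id)]
  labels <- net$map$labels
  window <- as.integer(ceiling(net$adp$gamma_period)) + 6L

  # ---- stage 1: input -> recall (tempotron) ----
  W1 <- matrix(stats::runif(length(recall_ids) * length(input_ids), 0, 0.05),
               nrow = length(recall_ids))
  trains1 <- lapply(labels, function(k) {
    p <- patterns$patterns[[as.character(k)]]
    data.frame(pre = p$channel, time = round(p$time))
  })
  tg1 <- lapply(labels, function(k) rc_assembly == k)
  # graded firing margins across each assembly: the high-margin members keep
  # firing under partial cues and ignite the rest through the lateral
  # (auto-associative) connections
  sz1 <- attr(net$map, "sizes")[["layer1"]]
  margins1 <- rep(seq(cfg$margin + 0.15, cfg$margin + 0.75,
                      length.out = sz1), times = length(labels))
  ext1 <- .valley_theta_ext(net$theta, window)
  s1 <- .train_stage(W1, trains1, tg1, net$params$leak_recall, cfg,
                     cfg$w_max_ff, window, "input->layerI",
                     margins = margins1, ext = ext1)
  W1 <- s1$W

  # ---- teacher trains: recall first-crossing times per pattern ----
  rc_trains <- lapply(seq_along(labels), function(p)
    .crossing_times(s1$W, trains1[[p]], net$params$leak_recall, window,
                    ext = ext1))

  # ---- stage 2: recall -> layer II (tempotron) ----
  W2 <- matrix(stats::runif(length(l2_ids) * length(recall_ids), 0, 0.05),
               nrow = length(l2_ids))
  tg2 <- lapply(labels, function(k) l2_assembly == k)
  s2 <- .train_stage(W2, rc_trains, tg2, net$params$leak_layer2, cfg,
                     cfg$w_max_ff, window + 6L, "layerI->layerII")
  W2 <- s2$W

  l2_trains <- lapply(seq_along(labels), function(p)
    .crossing_times(s2$W, rc_trains[[p]], net$params$leak_layer2,
                    window + 6L))

  # ---- stage 3: STDP on the teacher trains ----
  # auto-association: isolated presentations, recurrent weights within each
  # recall assembly
  Wlat1 <- .stdp_accumulate(length(recall_ids), rc_trains, cfg,
                            reps = cfg$n_stdp_reps, w_max = cfg$w_max_lat)
  # episodic item: compressed sequence presentation, layer-II lateral weights
  Wlat2 <- matrix(0, length(l2_ids), length(l2_ids))
  if (!is.null(sequence)) {
    stopifnot(all(sequence %in% labels))
    step_ms <- round(net$adp$gamma_period)
    seq_train <- do.call(rbind, lapply(seq_along(sequence), function(m) {
      p <- match(sequence[m], labels)
      tt <- l2_trains[[p]]
      data.frame(pre = tt$pre, time = tt$time + (m - 1) * step_ms)
    }))
    Wlat2 <- .stdp_accumulate(length(l2_ids), list(seq_train), cfg,
                              reps = cfg$n_stdp_reps, w_max = cfg$w_max_lat2,
                              groups = l2_assembly)
  }

  # ---- write the trained weights back into the synapse table ----
  syn <- net$synapses
  idx <- function(kind, pre_ids, post_ids)
    which(syn$kind == kind & syn$pre %in% pre_ids & syn$post %in% post_ids)
  i1 <- idx("feedforward", input_ids, recall_ids)
  syn$weight[i1] <- W1[cbind(match(syn$post[i1], recall_ids),
                             match(syn$pre[i1], input_ids))]
  i2 <- idx("feedforward", recall_ids, l2_ids)
  syn$weight[i2] <- W2[cbind(match(syn$post[i2], l2_ids),
                             match(syn$pre[i2], recall_ids))]
  i3 <- idx("lateral", recall_ids, recall_ids)
  syn$weight[i3] <- Wlat1[cbind(match(syn$post[i3], recall_ids),
                                match(syn$pre[i3], recall_ids))]
  i4 <- idx("lateral", l2_ids, l2_ids)
  syn$weight[i4] <- Wlat2[cbind(match(syn$post[i4], l2_ids),
                                match(syn$pre[i4], l2_ids))]
  net$synapses <- syn
  log <- rbind(s1$log, s2$log)
  if (!s1$converged || !s2$converged) {
    tail_err <- log$errors[nrow(log)]
    warning(sprintf("tempotron training did not converge within %d epochs (%d residual errors); see attr(net, 'training_log')",
                    cfg$epochs, tail_err))
  }
  attr(net, "training_log") <- log
  attr(net, "trained") <- TRUE
  attr(net, "learning_config") <- cfg
  net
}

# Additive STDP over repeated presentations of teacher spike trains.
# trains: list of data.frame(pre, time) with `pre` indexing the population.
.stdp_accumulate <- function(n, trains, cfg, reps = 1,
                             w_max = cfg$w_max_lat, groups = NULL) {
  W <- matrix(0, n, n)
  for (r in seq_len(reps)) for (tt in trains) {
    if (nrow(tt) < 2) next
    for (a in seq_len(nrow(tt))) {
      dt <- tt$time - tt$time[a]            # post times minus pre time a
      dw <- ifelse(dt > 0, cfg$stdp_a_plus * exp(-dt / cfg$stdp_tau_plus),
            ifelse(dt < 0, -cfg$stdp_a_minus * exp(dt / cfg$stdp_tau_minus),
                   0))
      dw[a] <- 0
      if (!is.null(groups))  # restrict to between-assembly pairs
        dw[groups[tt$pre] == groups[tt$pre[a]]] <- 0
      W[tt$pre, tt$pre[a]] <- pmin(pmax(W[tt$pre, tt$pre[a]] + dw, 0),
                                   w_max)
    }
  }
  diag(W) <- 0
  W
}

#' Convert a trained float network to fixed point
#'
#' Rounds all synaptic weights to signed 11-bit integers at the spec's scale,
#' leaks to signed 8-bit integers, and thresholds/reset potentials to signed
#' 14-bit integers (the float training threshold 1 becomes `scale`). Issues a
#' warning listing any synapse whose weight saturated the 11-bit range.
#'
#' @param net A trained float-unit `stm_network`.
#' @param spec A [fixed_point_spec()].
#' @return The quantized network (attribute `scale` set to `spec$scale`).
#' @export
fixpoint_network <- function(net, spec = fixed_point_spec()) {
  stopifnot(inherits(net, "stm_network"))
  if (attr(net, "scale") != 1)
    stop("network is already fixed-point")
  w_raw <- net$synapses$weight * spec$scale
  wr <- .bit_range(spec$weight_bits)
  clipped <- which(round_half_away(w_raw) < wr[1] |
                     round_half_away(w_raw) > wr[2])
  if (length(clipped))
    warning(sprintf("%d synapse weight(s) saturated the %d-bit range (rows: %s)",
                    length(clipped), spec$weight_bits,
                    paste(utils::head(clipped, 10), collapse = ", ")))
  net$synapses$weight <- fp_quantize(net$synapses$weight, spec,
                                     bits = spec$weight_bits)
  net$neurons$leak <- fp_quantize(net$neurons$leak, spec, bits = 8L)
  fin <- is.finite(net$neurons$threshold)
  net$neurons$threshold[fin] <- fp_quantize(net$neurons$threshold[fin], spec,
                                            bits = spec$neuron_bits)
  net$neurons$reset <- fp_quantize(net$neurons$reset, spec,
                                   bits = spec$neuron_bits)
  attr(net, "scale") <- spec$scale
  attr(net, "fixed_point_spec") <- spec
  net
}
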