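# Synthetic population-coded input patterns, noise injection (spike-time
# jitter / spike deletion), the Gaussian-filtered spike-train correlation,
# and the robustness / overlap / gamma-period sweep experiments.

#' Generate population-coded input patterns
#'
#' Each input channel carries exactly one spike at a time drawn uniformly on
#' the 1 ms grid of one gamma cycle. Patterns are the chained-overlap channel
#' assemblies of [build_assemblies()]; since a spike time belongs to the
#' channel, neurons shared between overlapping assemblies carry identical
#' times in every pattern that contains them.
#'
#' @param n_patterns Number of patterns.
#' @param assembly_size Channels per pattern.
#' @param overlap_ratio Overlap between consecutive assemblies.
#' @param gamma_period Gamma cycle length in ms (spike times lie in
#'   `[0, gamma_period)`).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return An object of class `input_patterns`: named list `patterns`
#'   (label -> data.frame(channel, time)) plus the generation constants.
#' @export
generate_patterns <- function(n_patterns = 4, assembly_size = 10,
                              overlap_ratio = 0.5, gamma_period = 9.9,
                              seed = 1L) {
  stopifnot(n_patterns >= 1, assembly_size >= 1, gamma_period >= 1)
  map <- suppressWarnings(
    build_assemblies(n_patterns,
                     c(input = assembly_size, layer1 = 1, layer2 = 1),
                     overlap_ratio))
  n_channels <- length(unique(unlist(map$input)))
  set.seed(seed)
  grid <- seq.int(0L, as.integer(ceiling(gamma_period)) - 1L)
  channel_time <- sample(grid, n_channels, replace = TRUE)
  pats <- lapply(map$input, function(idx)
    data.frame(channel = idx, time = channel_time[idx]))
  names(pats) <- as.character(map$labels)
  structure(list(patterns = pats, n_channels = n_channels,
                 assembly_size = as.integer(assembly_size),
                 overlap_ratio = overlap_ratio, gamma_period = gamma_period,
                 seed = as.integer(seed)),
            class = "input_patterns")
}

#' @export
print.input_patterns <- function(x, ...) {
  cat(sprintf("<input_patterns> %d patterns x %d spikes over %d channels (gamma %.3g ms, overlap %.0f%%)\n",
              length(x$patterns), x$assembly_size, x$n_channels,
              x$gamma_period, 100 * x$overlap_ratio))
  invisible(x)
}

#' Noise specification for input perturbation
#'
#' @param jitter_sd Standard deviation (ms) of the Gaussian spike-time shift;
#'   0 disables jitter.
#' @param n_missing Number of spikes removed uniformly at random (surviving
#'   spike times are left unchanged).
#' @param seed Optional RNG seed.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(jitter_sd = 0, n_missing = 0L, seed = NULL) {
  stopifnot(jitter_sd >= 0, n_missing >= 0)
  structure(list(jitter_sd = jitter_sd, n_missing = as.integer(n_missing),
                 seed = seed),
            class = "noise_spec")
}

#' Perturb one input pattern
#'
#' Jitter adds an independent Gaussian offset (sd `jitter_sd`) to every spike
#' time, then clips to the valid `[0, gamma_period)` window; deletion removes
#' exactly `n_missing` spikes chosen uniformly without replacement, leaving
#' the surviving spike times unchanged. `jitter_sd = 0, n_missing = 0` is the
#' identity.
#'
#' @param pattern A single-pattern data.frame(channel, time).
#' @param spec A [noise_spec()].
#' @param gamma_period Clipping window length in ms.
#' @return The perturbed pattern data.frame.
#' @export
apply_noise <- function(pattern, spec, gamma_period = 9.9) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$n_missing > nrow(pattern))
    stop("n_missing exceeds the pattern's spike count")
  out <- pattern
  if (spec$jitter_sd > 0) {
    out$time <- out$time + stats::rnorm(nrow(out), 0, spec$jitter_sd)
    out$time <- pmin(pmax(out$time, 0), gamma_period - 1e-6)
  }
  if (spec$n_missing > 0) {
    keep <- sort(sample.int(nrow(out), nrow(out) - spec$n_missing))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Correlation of Gaussian-filtered spike trains
#'
#' Both trains are convolved with a Gaussian of width `sigma_c` on a `dt`
#' grid; the metric is the cosine of the filtered vectors, in \[0, 1\]. By
#' convention the correlation is 0 when either filtered train is all-zero
#' (an empty train). Identical non-empty trains score 1; two single spikes
#' offset by `d` score `exp(-d^2 / (4 * sigma_c^2))` in the continuous limit.
#'
#' @param actual,desired Numeric vectors of spike times (ms).
#' @param sigma_c Gaussian filter width in ms (default 2).
#' @param dt Evaluation grid step in ms (default 0.1).
#' @param t_range Optional `c(from, to)` evaluation support; defaults to the
#'   joint spike range padded by `4 * sigma_c`.
#' @return Correlation in \[0, 1\].
#' @export
r_corr <- function(actual, desired, sigma_c = 2, dt = 0.1, t_range = NULL) {
  stopifnot(sigma_c > 0, dt > 0)
  if (!length(actual) || !length(desired)) return(0)
  if (is.null(t_range))
    t_range <- range(c(actual, desired)) + c(-4, 4) * sigma_c
  grid <- seq(t_range[1], t_range[2], by = dt)
  filt <- function(times) {
    s <- numeric(length(grid))
    for (tt in times) s <- s + stats::dnorm(grid, tt, sigma_c)
    s
  }
  sa <- filt(actual); sd_ <- filt(desired)
  na <- sqrt(sum(sa^2)); nd <- sqrt(sum(sd_^2))
  if (na == 0 || nd == 0) return(0)
  min(sum(sa * sd_) / (na * nd), 1)
}

# per-neuron spike-time lists of the recall layer within a window after the
# presentation time, keyed by neuron id
.recall_trains <- function(raster, net, t_pres, window_ms) {
  sl <- raster_slice(raster, "recall", window = c(t_pres, t_pres + window_ms))
  split(sl$time_ms - t_pres, factor(sl$neuron_id,
        levels = net$neurons$id[net$neurons$role == "normal" &
                                net$neurons$layer == "recall"]))
}

#' Clean reference responses of a trained network
#'
#' Presents each pattern alone, noise-free, and records the recall-layer
#' response trains over one theta period from the presentation — the target
#' trains the noisy responses are scored against.
#'
#' @param net A trained `stm_network`.
#' @param patterns The `input_patterns` the network was trained on.
#' @return List: label -> list of per-neuron spike-time vectors.
#' @export
reference_responses <- function(net, patterns) {
  period <- net$theta$period
  horizon <- as.integer(ceiling(2.2 * period))
  out <- list()
  for (k in names(patterns$patterns)) {
    sched <- stimulus_schedule(as.integer(k), patterns, net$theta)
    raster <- run_network(net, sched, horizon = horizon)
    out[[k]] <- .recall_trains(raster, net, sched$times[1], period)
  }
  out
}

#' Score one (possibly noisy) recall trial
#'
#' Presents `cue` (after applying `noise` to its pattern) and scores every
#' assembly: the mean over the assembly's recall neurons of the filtered
#' spike-train correlation between the observed response and that assembly's
#' clean reference response. The cued assembly should score high; all others
#' should stay low (their reference is the response they give when their own
#' pattern is cued, so silence scores 0).
#'
#' @param net A trained `stm_network`.
#' @param patterns The training `input_patterns`.
#' @param cue Pattern label to present.
#' @param refs Reference trains from [reference_responses()].
#' @param noise A [noise_spec()] applied to the cue pattern.
#' @param sigma_c Filter width for [r_corr()].
#' @return Named numeric vector of per-assembly scores.
#' @export
recall_scores <- function(net, patterns, cue, refs = NULL,
                          noise = noise_spec(), sigma_c = 2) {
  if (is.null(refs)) refs <- reference_responses(net, patterns)
  period <- net$theta$period
  noisy <- patterns
  noisy$patterns[[as.character(cue)]] <-
    apply_noise(noisy$patterns[[as.character(cue)]], noise,
                patterns$gamma_period)
  sched <- stimulus_schedule(as.integer(cue), noisy, net$theta)
  raster <- run_network(net, sched, horizon = as.integer(ceiling(2.2 * period)))
  actual <- .recall_trains(raster, net, sched$times[1], period)
  rc <- net$neurons[net$neurons$role == "normal" & net$neurons$layer == "recall", ]
  scores <- sapply(sort(unique(rc$assembly)), function(a) {
    ids <- as.character(rc$id[rc$assembly == a])
    mean(vapply(ids, function(id)
      r_corr(actual[[id]], refs[[as.character(a)]][[id]], sigma_c), 0))
  })
  names(scores) <- sort(unique(rc$assembly))
  scores
}

#' Is a trial a correct, selective recall?
#'
#' @param scores Output of [recall_scores()].
#' @param cue The cued label.
#' @param accept Minimum score of the cued assembly (default 0.9).
#' @param reject Maximum score of any other assembly (default 0.5).
#' @return Logical.
#' @export
recall_success <- function(scores, cue, accept = 0.9, reject = 0.5) {
  k <- as.character(cue)
  scores[k] >= accept && all(scores[names(scores) != k] <= reject)
}

# build + train a default-architecture network for a given input assembly
# size / overlap / gamma, returning list(net, patterns, refs)
.trained_system <- function(input_size = 10, overlap = 0.5,
                            gamma_period = 9.9, n_patterns = 4, seed = 1L,
                            cfg = NULL, quantize = TRUE,
                            sequence = NULL) {
  l1 <- max(1L, round(3 * input_size / 4))
  map <- suppressWarnings(
    build_assemblies(n_patterns, c(input = input_size, layer1 = l1,
                                   layer2 = input_size), overlap))
  theta <- theta_spec(period = gamma_period * 20 / 3)
  adp <- adp_spec(slope = 0.0055 * 118.8 / (12 * gamma_period),
                  gamma_period = gamma_period)
  net <- build_network(map, theta = theta, adp = adp)
  patterns <- generate_patterns(n_patterns, input_size, overlap,
                                gamma_period, seed = seed)
  if (is.null(cfg))
    cfg <- learning_config(tempotron_kernel_tau = gamma_period,
                           stdp_tau_plus = gamma_period,
                           stdp_tau_minus = gamma_period, seed = seed)
  net <- suppressWarnings(train_network(net, patterns, sequence = sequence,
                                        cfg = cfg))
  if (quantize) net <- fixpoint_network(net)
  list(net = net, patterns = patterns)
}

#' Noise-robustness sweep
#'
#' For each input assembly size, trains the default four-pattern network
#' (layer-I assemblies three-quarters of the input size, layer-II equal to
#' it), then repeatedly perturbs each pattern — Gaussian spike-time jitter at
#' each `jitter_sds` level, or uniform deletion of each `n_missing` count —
#' and scores the recall-layer response against the clean reference with the
#' filtered-train correlation.
#'
#' @param sizes Input assembly sizes to sweep.
#' @param jitter_sds Jitter standard deviations (ms).
#' @param n_missing Deleted-spike counts (cells infeasible for a size are
#'   skipped).
#' @param repeats Noise redraws per cell.
#' @param seed Master seed; all trial seeds derive from it.
#' @param cfg Optional [learning_config()].
#' @return data.frame(size, noise_type, level, mean_rcorr, sd_rcorr, repeats).
#' @export
experiment_noise <- function(sizes = c(5, 10, 15, 20), jitter_sds = 1:5,
                             n_missing = c(2, 3, 5, 8), repeats = 20,
                             seed = 1L, cfg = NULL) {
  stopifnot(repeats >= 1)
  rows <- list()
  for (s in sizes) {
    sys <- .trained_system(input_size = s, seed = seed, cfg = cfg)
    refs <- reference_responses(sys$net, sys$patterns)
    labels <- as.integer(names(sys$patterns$patterns))
    cells <- rbind(
      data.frame(noise_type = "jitter", level = jitter_sds),
      data.frame(noise_type = "missing",
                 level = n_missing[n_missing <= s]))
    for (ci in seq_len(nrow(cells))) {
      vals <- numeric(0)
      for (r in seq_len(repeats)) {
        k <- labels[1 + (r - 1) %% length(labels)]
        ns <- if (cells$noise_type[ci] == "jitter")
          noise_spec(jitter_sd = cells$level[ci],
                     seed = seed + 7919 * ci + 104729 * r + 13 * s)
        else
          noise_spec(n_missing = cells$level[ci],
                     seed = seed + 7919 * ci + 104729 * r + 13 * s)
        sc <- recall_scores(sys$net, sys$patterns, k, refs, ns)
        vals <- c(vals, sc[as.character(k)])
      }
      rows[[length(rows) + 1]] <-
        data.frame(size = s, noise_type = cells$noise_type[ci],
                   level = cells$level[ci], mean_rcorr = mean(vals),
                   sd_rcorr = stats::sd(vals), repeats = repeats)
    }
  }
  do.call(rbind, rows)
}

#' Assembly-overlap sweep
#'
#' Trains the default four-pattern network at each input overlap ratio and
#' reports the fraction of patterns that are correctly and selectively
#' recalled (clean inputs).
#'
#' @param ratios Overlap ratios to sweep.
#' @param repeats Independent pattern draws (and trainings) per ratio.
#' @param seed Master seed.
#' @param cfg Optional [learning_config()].
#' @return data.frame(overlap, repeat_id, n_patterns, n_recalled, success).
#' @export
experiment_overlap <- function(ratios = seq(0.05, 0.75, by = 0.05),
                               repeats = 2, seed = 1L, cfg = NULL) {
  rows <- list()
  for (ratio in ratios) for (r in seq_len(repeats)) {
    sys <- .trained_system(overlap = ratio, seed = seed + 1000 * r, cfg = cfg)
    refs <- reference_responses(sys$net, sys$patterns)
    labels <- as.integer(names(sys$patterns$patterns))
    ok <- vapply(labels, function(k)
      recall_success(recall_scores(sys$net, sys$patterns, k, refs), k),
      logical(1))
    rows[[length(rows) + 1]] <-
      data.frame(overlap = ratio, repeat_id = r, n_patterns = length(labels),
                 n_recalled = sum(ok), success = mean(ok))
  }
  do.call(rbind, rows)
}

#' Gamma-period sweep
#'
#' Varies the gamma period with the theta period locked at 20/3 gamma and the
#' ADP time constant at 12 gamma (the ADP cap is held constant by scaling the
#' ramp slope). For each gamma the default network is trained with the full
#' episodic sequence and probed with its first pattern; reported are the
#' associative recall rate, whether the episodic replay preserves the trained
#' order, and whether distinct layer-II assemblies stay temporally
#' distinguishable (no two assemblies firing in the same millisecond during
#' the replay window).
#'
#' @param gamma_periods Gamma periods (ms) to sweep.
#' @param seed Master seed.
#' @param cfg Optional [learning_config()].
#' @return data.frame(gamma, theta_period, tau_adp, assoc_success,
#'   replay_ordered, collision_rate, distinguishable).
#' @export
experiment_gamma <- function(gamma_periods = c(1, 5, 10, 15, 20, 25),
                             seed = 1L, cfg = NULL) {
  rows <- list()
  for (g in gamma_periods) {
    sys <- .trained_system(gamma_period = g, seed = seed, cfg = cfg,
                           sequence = 0:3)
    refs <- reference_responses(sys$net, sys$patterns)
    labels <- as.integer(names(sys$patterns$patterns))
    ok <- vapply(labels, function(k)
      recall_success(recall_scores(sys$net, sys$patterns, k, refs), k),
      logical(1))
    order_seen <- recall_episode(sys$net, sys$patterns, cue = 0,
                                 horizon = as.integer(ceiling(4 * g * 20 / 3)))
    sched <- stimulus_schedule(0L, sys$patterns, sys$net$theta)
    raster <- run_network(sys$net, sched,
                          horizon = as.integer(ceiling(4 * g * 20 / 3)))
    l2 <- raster_slice(raster, "layer2")
    coll <- if (nrow(l2)) {
      per_step <- tapply(l2$assembly, l2$time_ms,
                         function(a) length(unique(a)))
      mean(per_step > 1)
    } else NA_real_
    ordered <- length(order_seen) == length(labels) &&
      all(order_seen == sort(labels))
    rows[[length(rows) + 1]] <-
      data.frame(gamma = g, theta_period = g * 20 / 3, tau_adp = 12 * g,
                 assoc_success = mean(ok), replay_ordered = ordered,
                 collision_rate = coll,
                 distinguishable = ordered && !is.na(coll) && coll == 0)
  }
  do.call(rbind, rows)
}
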