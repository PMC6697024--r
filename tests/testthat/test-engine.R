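test_that("one evaluation step is integrate, then leak, then fire/reset", {
  # hand trace of the per-step order on a single neuron
  p <- neuron_params(45, 0, 1000, potential = 955)
  v <- fp_integrate(p$potential, 300)   # 1255
  v <- fp_leak(v, p$leak)               # 1210
  r <- fp_fire_reset(v, p)
  expect_true(r$fired)
  expect_identical(r$potential, 0L)
  # no input at threshold - leak: decays to rest without firing
  v2 <- fp_leak(fp_integrate(45, numeric(0)), 45)
  expect_identical(fp_fire_reset(v2, p), list(fired = FALSE, potential = 0))
})

test_that("runs are deterministic and state serialization resumes exactly", {
  sys <- trained_default()
  sched <- stimulus_schedule(0L, sys$patterns, sys$qnet$theta)
  a <- run_network(sys$qnet, sched, horizon = 200)
  b <- run_network(sys$qnet, sched, horizon = 200)
  expect_identical(a, b)
  part1 <- run_network(sys$qnet, sched, horizon = 120, return_state = TRUE)
  st <- unserialize(serialize(part1$state, NULL))  # state is plain data
  part2 <- run_network(sys$qnet, sched, horizon = 80, init_state = st)
  expect_equal(rbind(as.data.frame(part1$raster), as.data.frame(part2)),
               as.data.frame(a), ignore_attr = TRUE)
})

# two disjoint single-neuron assemblies with hand-set feedforward weights:
# the cleanest stage on which to watch one ADP chain start and stop
micro_system <- function(adp_inhibition_weight = 0) {
  map <- build_assemblies(2, c(input = 2, layer1 = 1, layer2 = 1), 0)
  net <- build_network(map, params = network_params(
    adp_inhibition_weight = adp_inhibition_weight))
  nr <- net$neurons
  for (k in 0:1) {
    pre <- nr$id[nr$role == "input"][2 * k + 1:2]
    post <- nr$id[nr$role == "normal" & nr$layer == "recall" &
                    nr$assembly %in% k]
    net$synapses$weight[net$synapses$pre %in% pre &
                          net$synapses$post == post] <- 0.6
  }
  net <- fixpoint_network(net)
  pats <- structure(list(
    patterns = list("0" = data.frame(channel = 1:2, time = c(0, 0)),
                    "1" = data.frame(channel = 3:4, time = c(0, 0))),
    n_channels = 4L, assembly_size = 2L, overlap_ratio = 0,
    gamma_period = 9.9, seed = 0L), class = "input_patterns")
  list(net = net, patterns = pats)
}

test_that("an activated ADP neuron fires continuously until inhibited", {
  on <- micro_system(adp_inhibition_weight = -1)
  sched <- stimulus_schedule(c(0L, 1L), on$patterns, on$net$theta)
  raster <- run_network(on$net, sched, horizon = 250)
  adp0 <- raster[raster$role == "adp" & raster$assembly == 0, ]
  t_int1 <- min(raster$time_ms[raster$role == "interneuron" &
                                 raster$assembly == 1])
  # continuous firing (one event per step) while the chain is active
  pre_tt <- sort(adp0$time_ms[adp0$time_ms <= t_int1])
  expect_identical(pre_tt, seq(min(pre_tt), max(pre_tt)))
  # the rival assembly's interneuron terminates the chain for good
  expect_lte(max(adp0$time_ms), t_int1 + 1)
  # control: without the inhibitory synapses the chain never stops
  off <- micro_system(adp_inhibition_weight = 0)
  r2 <- run_network(off$net, sched, horizon = 250)
  a2 <- r2[r2$role == "adp" & r2$assembly == 0, ]
  expect_equal(max(a2$time_ms), 250)
  expect_true(all(diff(sort(a2$time_ms)) == 1))
})

test_that("without ADP inhibition the chain persists and sustains maintenance", {
  sys <- trained_default()
  sched <- stimulus_schedule(0L, sys$patterns, sys$qnet$theta)
  raster <- run_network(sys$qnet, sched, horizon = 300)
  adp0 <- raster[raster$role == "adp" & raster$assembly == 0, ]
  expect_equal(max(adp0$time_ms), 300)
  # layer-II assemblies keep firing through later theta cycles with no input
  l2 <- raster_slice(raster, "layer2", assembly = 0)
  cyc <- unique((l2$time_ms - sched$times[1]) %/% sys$qnet$theta$period)
  expect_gte(length(cyc[cyc >= 1]), 2)
})

test_that("at most one assembly per layer fires in any step (gamma separation)", {
  sys <- trained_default()
  sched <- stimulus_schedule(0L, sys$patterns, sys$qnet$theta)
  raster <- run_network(sys$qnet, sched, horizon = 300)
  for (layer in c("recall", "layer2")) {
    sl <- raster_slice(raster, layer)
    per_step <- tapply(sl$assembly, sl$time_ms, function(a) length(unique(a)))
    expect_true(all(per_step == 1))
  }
})

test_that("a partial cue with up to three missing spikes completes the assembly", {
  sys <- trained_default()
  for (k in 1:3) for (s in c(11, 22, 33)) {
    noisy <- sys$patterns
    noisy$patterns[["0"]] <- apply_noise(sys$patterns$patterns[["0"]],
                                         noise_spec(n_missing = k, seed = s),
                                         sys$patterns$gamma_period)
    sched <- stimulus_schedule(0L, noisy, sys$qnet$theta)
    raster <- run_network(sys$qnet, sched, horizon = 120)
    rc <- raster_slice(raster, "recall", assembly = 0,
                       window = c(sched$times[1], sched$times[1] + 66))
    expect_identical(length(unique(rc$neuron_id)), 8L)
  }
})

test_that("episodic recall replays the stored sequence from its first cue", {
  sys <- trained_default()
  expect_identical(recall_episode(sys$qnet, sys$patterns, 0), 0:3)
  expect_error(recall_episode(sys$qnet, sys$patterns, 9), "unknown cue")
  # untrained network: no layer-II activations at all
  bare <- fixpoint_network(build_network(build_assemblies()))
  expect_identical(recall_episode(bare, sys$patterns, 0), integer(0))
})

test_that("a cue outside the stored sequence activates only its own assembly", {
  net <- build_network(build_assemblies())
  patterns <- default_patterns()
  net <- suppressWarnings(train_network(net, patterns, sequence = 0:2,
                                        cfg = learning_config(seed = 1L)))
  qnet <- fixpoint_network(net)
  expect_identical(recall_episode(qnet, patterns, 3), 3L)
  expect_identical(recall_episode(qnet, patterns, 0), 0:2)
  # confirmed in the weights: no potentiated lateral leaving assembly 3
  nr <- qnet$neurons
  l2 <- nr$id[nr$role == "normal" & nr$layer == "layer2"]
  sy <- qnet$synapses
  out3 <- sy[sy$kind == "lateral" & sy$pre %in% l2 & sy$post %in% l2 &
               nr$assembly[match(sy$pre, nr$id)] == 3 &
               nr$assembly[match(sy$post, nr$id)] != 3, ]
  expect_true(all(out3$weight == 0))
})

test_that("presentation times align to theta valleys", {
  p <- default_patterns()
  sp <- theta_spec()
  s1 <- stimulus_schedule(c(0L, 1L), p, sp)
  expect_equal(s1$times %% sp$period, rep(sp$phase_of_valley %% sp$period, 2))
  s2 <- stimulus_schedule(0L, p, sp, times = 60)
  expect_equal(s2$times %% sp$period, sp$phase_of_valley %% sp$period)
})
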