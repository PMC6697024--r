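test_that("tempotron corrections follow the exponential-trace closed form", {
  cfg <- learning_config(tempotron_lr = 0.05, tempotron_kernel_tau = 9.9)
  w <- c(0.1, 0.1)
  # correct decision: unchanged
  expect_identical(tempotron_update(w, data.frame(pre = 1, time = 3),
                                    TRUE, TRUE, cfg), w)
  # miss with a single pre-spike at t_max: +lr exactly
  up <- tempotron_update(w, data.frame(pre = 1, time = 5), TRUE, FALSE, cfg,
                         t_max = 5)
  expect_equal(up[1], 0.1 + 0.05)
  expect_equal(up[2], 0.1)
  # false alarm with a pre-spike one kernel tau before t_max: -lr/e
  dn <- tempotron_update(w, data.frame(pre = 2, time = 5), FALSE, TRUE, cfg,
                         t_max = 5 + 9.9)
  expect_equal(dn[2], 0.1 - 0.05 * exp(-1))
  # weights stay in [0, w_max]
  expect_equal(tempotron_update(c(0.01, 0), data.frame(pre = 1, time = 5),
                                FALSE, TRUE, cfg, t_max = 5)[1], 0)
})

test_that("the STDP window is sign-correct and matches its closed form", {
  cfg <- learning_config(stdp_a_plus = 0.03, stdp_a_minus = 0.02,
                         stdp_tau_plus = 10, stdp_tau_minus = 10)
  expect_equal(stdp_update(0.05, 1e-9, cfg), 0.05 + 0.03, tolerance = 1e-6)
  expect_equal(stdp_update(0.05, 10, cfg), 0.05 + 0.03 * exp(-1))
  expect_equal(stdp_update(0.05, -10, cfg), 0.05 - 0.02 * exp(-1))
  expect_equal(stdp_update(0.05, 0, cfg), 0.05)
  expect_equal(stdp_update(0.05, -1e6, cfg), 0.05)
  # potentiation iff pre precedes post (property over random lags)
  set.seed(3)
  dt <- runif(200, -30, 30)
  dw <- stdp_update(0.06, dt, cfg) - 0.06
  expect_true(all(sign(dw[abs(dt) > 1e-9]) == sign(dt[abs(dt) > 1e-9])))
  # clipping
  expect_equal(stdp_update(cfg$w_max_lat, 1e-9, cfg), cfg$w_max_lat)
  expect_equal(stdp_update(0.001, -1e-9, cfg), 0)
})

test_that("training is reproducible bit for bit given the seed", {
  net <- build_network(build_assemblies())
  patterns <- default_patterns()
  cfg <- learning_config(seed = 5L, epochs = 40L)
  a <- suppressWarnings(train_network(net, patterns, sequence = 0:3, cfg = cfg))
  b <- suppressWarnings(train_network(net, patterns, sequence = 0:3, cfg = cfg))
  expect_identical(a$synapses$weight, b$synapses$weight)
})

test_that("a single stored pattern yields a selective assembly", {
  map <- build_assemblies(1)
  net <- build_network(map)
  patterns <- generate_patterns(1, seed = 2)
  net <- train_network(net, patterns, cfg = learning_config(seed = 2L))
  qnet <- fixpoint_network(net)
  expect_identical(layer1_decision(qnet, patterns, 0), 0L)
  # silent without a stimulus: only theta-bank events in the raster
  r <- run_network(qnet, schedule = NULL, horizon = 150)
  expect_true(all(r$role %in% c("theta1", "theta2")))
})

test_that("the trained default network stores four selective assemblies", {
  sys <- trained_default()
  for (k in 0:3)
    expect_identical(layer1_decision(sys$qnet, sys$patterns, k),
                     as.integer(k))
})

test_that("quantization preserves the clean-input layer-I decisions", {
  sys <- trained_default()
  for (k in 0:3)
    expect_identical(layer1_decision(sys$fnet, sys$patterns, k),
                     layer1_decision(sys$qnet, sys$patterns, k))
})

test_that("trained weights quantize into the 11-bit range without saturation", {
  sys <- trained_default()
  expect_no_warning(fixpoint_network(sys$fnet))
  w <- sys$qnet$synapses$weight
  expect_true(all(w >= -1024 & w <= 1023))
  # excitatory trainable weights stay in the hardware's used band
  tr <- sys$qnet$synapses$weight[sys$qnet$synapses$trainable]
  expect_true(all(tr >= 0 & tr <= 300))
  expect_identical(
    sys$qnet$neurons$threshold[sys$qnet$neurons$role == "normal"][1], 1000)
})

test_that("non-convergence warns with diagnostics instead of failing", {
  net <- build_network(build_assemblies())
  patterns <- default_patterns()
  expect_warning(
    out <- train_network(net, patterns,
                         cfg = learning_config(epochs = 1L, seed = 1L)),
    "did not converge")
  expect_s3_class(attr(out, "training_log"), "data.frame")
})
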