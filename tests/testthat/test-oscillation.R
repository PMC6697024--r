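test_that("the quantized ADP ramp is a capped, monotone staircase under the line", {
  sp <- adp_spec()
  expect_equal(adp_quantized(0, sp), 0)
  expect_equal(adp_quantized(1, sp), 0)     # 0.0055 floors to 0
  expect_equal(adp_quantized(2, sp), 0.01)  # 0.011 floors to 0.01
  v <- adp_quantized(0:300, sp)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= sp$cap + 1e-9))
  expect_true(all(v <= sp$slope * (0:300) + 1e-9))
  expect_true(all(sp$slope * pmin(0:300, sp$tau_adp) - v < sp$grid + 1e-9))
})

test_that("the ADP increment schedule telescopes back to the staircase", {
  sp <- adp_spec()
  sched <- adp_increment_schedule(sp, 200)
  expect_true(all(abs(sched$increment) < sp$grid + 1e-9 |
                    abs(sched$increment - sp$grid) < 1e-9))
  expect_true(all(sched$increment >= -1e-12))
  expect_equal(cumsum(sched$increment), adp_quantized(1:200, sp))
  expect_equal(sum(sched$increment[sched$dt <= ceiling(sp$tau_adp)]),
               adp_quantized(ceiling(sp$tau_adp), sp))
})

test_that("the quantized theta waveform hits its grid-exact landmarks", {
  sp <- theta_spec()
  expect_equal(theta_value(0, sp), 0)
  expect_equal(theta_value(sp$period / 4, sp), 0.60)
  expect_equal(theta_value(3 * sp$period / 4, sp), -0.60)
  tv <- theta_value(0:660, sp)
  expect_true(all(abs(tv) <= sp$amplitude + 1e-9))
  # quantization error below one grid step
  raw <- sp$amplitude * sin(2 * pi * (0:660) / sp$period)
  expect_true(all(raw - tv >= -1e-9 & raw - tv < sp$w_theta + 1e-9))
})

test_that("theta bank sizes follow from the amplitude and the peak slope", {
  bank <- theta_bank(theta_spec())
  expect_identical(bank$n_theta1, 60L)
  expect_identical(bank$n_theta2, 6L)
  expect_identical(theta_bank(theta_spec(amplitude = 0.01))$n_theta1, 1L)
  expect_error(theta_spec(amplitude = 0.605), "integer multiple")
  # the difference bank covers the largest per-ms quantized step (brute force)
  sp <- theta_spec()
  q <- stmnet:::.theta_quanta(seq(0, 2 * sp$period, by = 1), sp)
  expect_lte(max(abs(diff(q))), bank$n_theta2)
})

test_that("theta drive difference-encodes the waveform and re-injects after a fire", {
  sp <- theta_spec()
  # reconstruction: cumulative difference drive telescopes exactly
  total <- 0
  for (t in 1:66) total <- total + theta_drive(t, FALSE, sp)$n_theta2_active
  expect_equal(total * sp$w_theta, theta_value(66, sp) - theta_value(0, sp))
  # amplitude re-injection only on the step after a fire
  t_prev <- 8
  q_prev <- as.integer(round(theta_value(t_prev, sp) / sp$w_theta))
  d <- theta_drive(t_prev + 1, TRUE, sp)
  expect_identical(d$n_theta1_active, q_prev)
  expect_identical(theta_drive(t_prev + 1, FALSE, sp)$n_theta1_active, 0L)
})

test_that("combined quantized ADP + theta track the continuous curves within one step", {
  sp <- adp_spec(); th <- theta_spec()
  dt <- 0:150
  err <- abs((adp_quantized(dt, sp) + theta_value(dt, th)) -
             (pmin(sp$slope * dt, sp$cap) +
                th$amplitude * sin(2 * pi * dt / th$period)))
  expect_true(all(err <= sp$grid + th$w_theta + 1e-9))
})

test_that("a neuron that fires at an input valley fires again within one theta period", {
  sys <- trained_default()
  sched <- stimulus_schedule(0L, sys$patterns, sys$qnet$theta)
  raster <- run_network(sys$qnet, sched, horizon = 300)
  rc <- raster_slice(raster, "recall", assembly = 0)
  for (id in unique(rc$neuron_id)) {
    tt <- sort(rc$time_ms[rc$neuron_id == id])
    expect_gte(length(tt), 2)
    expect_lte(tt[2] - tt[1], sys$qnet$theta$period)
    # and keeps refiring roughly cycle-locked thereafter (a refire may slip
    # to the next threshold crossing while the ADP ramp is still young)
    expect_true(all(diff(tt) <= 1.25 * sys$qnet$theta$period))
  }
})

test_that("theta valley times respect the phase convention", {
  sp <- theta_spec()
  v <- theta_valleys(sp, 300)
  expect_equal(v, c(49.5, 115.5, 181.5, 247.5))
  expect_equal(theta_value(v[1], sp), -0.6)
})
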