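test_that("the default assembly map reproduces the published census", {
  m <- build_assemblies()
  expect_identical(normal_neuron_count(m), 97L)
  expect_identical(length(unique(unlist(m$input))), 25L)
  expect_identical(normal_neuron_count(build_assemblies(1)), 28L)
})

test_that("chained overlap counts match a set-union oracle", {
  for (ov in c(0, 0.2, 0.5, 0.75)) {
    m <- suppressWarnings(build_assemblies(4, overlap_ratio = ov))
    share <- attr(m, "share")
    # brute-force: build the union and check consecutive intersections
    expect_identical(length(Reduce(union, m$input)),
                     10L + 3L * (10L - share))
    for (k in 1:3)
      expect_identical(length(intersect(m$input[[k]], m$input[[k + 1]])),
                       as.integer(share))
  }
  expect_warning(build_assemblies(4, overlap_ratio = 0.75), "rounded")
  expect_identical(
    length(unique(unlist(suppressWarnings(
      build_assemblies(4, overlap_ratio = 0.75))$input))), 16L)
})

test_that("the hardware network realizes 178 LIF neurons in the published roles", {
  net <- build_network(build_assemblies())
  expect_identical(lif_neuron_count(net), 178L)
  expect_identical(lif_neuron_count(net, "adp"), 32L)
  expect_identical(lif_neuron_count(net, "theta1"), 60L)
  expect_identical(lif_neuron_count(net, "theta2"), 6L)
  expect_identical(lif_neuron_count(net, "interneuron"), 8L)
  expect_identical(lif_neuron_count(net, "normal"), 72L)
})

test_that("a minimal one-pattern instance counts exhaustively", {
  m <- build_assemblies(1, c(input = 1, layer1 = 1, layer2 = 1), 0)
  net <- build_network(m, theta = theta_spec(amplitude = 0.01))
  # 1 recall + 1 layer-II + 2 interneurons + 1 ADP + 1 theta1 + 1 theta2
  expect_identical(lif_neuron_count(net), 7L)
})

test_that("neuron and synapse tables are referentially consistent", {
  net <- build_network(build_assemblies())
  expect_true(all(net$synapses$pre %in% net$neurons$id))
  expect_true(all(net$synapses$post %in% net$neurons$id))
  expect_true(all(net$synapses$kind %in%
                    c("feedforward", "lateral", "inhibitory", "adp",
                      "theta1", "theta2")))
  expect_true(all(net$synapses$kind[net$synapses$trainable] %in%
                    c("feedforward", "lateral")))
})

test_that("interneuron, ADP and theta wiring follow the architecture", {
  net <- build_network(build_assemblies(),
                       params = network_params(adp_inhibition_weight = -1))
  nr <- net$neurons; sy <- net$synapses
  ints <- nr[nr$role == "interneuron", ]
  for (i in seq_len(nrow(ints))) {
    own <- nr$id[nr$role == "normal" & nr$layer == ints$layer[i] &
                   nr$assembly %in% ints$assembly[i]]
    others <- nr$id[nr$role == "normal" & nr$layer == ints$layer[i] &
                      !(nr$assembly %in% ints$assembly[i])]
    fan_in <- sy[sy$post == ints$id[i] & sy$kind == "feedforward", ]
    expect_setequal(fan_in$pre, own)
    fan_out <- sy[sy$pre == ints$id[i] & sy$kind == "inhibitory" &
                    sy$post %in% nr$id[nr$role == "normal"], ]
    expect_setequal(fan_out$post, others)
  }
  # recall interneurons also reach the other assemblies' ADP neurons
  int0 <- ints$id[ints$layer == "recall" & ints$assembly == 0]
  adp_hit <- sy$post[sy$pre == int0 & sy$kind == "inhibitory" &
                       sy$post %in% nr$id[nr$role == "adp"]]
  expect_identical(length(adp_hit), 24L)  # 32 ADP minus own assembly's 8
  # one ADP neuron per recall normal, paired both ways
  rc <- nr$id[nr$role == "normal" & nr$layer == "recall"]
  expect_identical(sum(sy$kind == "adp" & sy$pre %in% rc), length(rc))
  expect_identical(sum(sy$kind == "adp" & sy$post %in% rc), length(rc))
  # theta fan-out covers every recall normal from every bank neuron
  expect_identical(sum(sy$kind %in% c("theta1", "theta2")),
                   66L * length(rc))
})

test_that("the off-hardware build keeps the input and layer-I populations", {
  net <- build_network(build_assemblies(), on_hardware = FALSE)
  expect_identical(sum(net$neurons$layer == "layer1"), 32L)
  expect_identical(sum(net$neurons$role == "input"), 25L)
})

test_that("memory cost is an exact integer-bit sum", {
  ct <- memory_cost_report(n_neurons = 178, n_synapses = 8512)
  expect_equal(ct$total_kb[ct$item == "neuron"], 8.9)
  expect_equal(ct$total_kb[ct$item == "weight"], 93.632)
  expect_equal(ct$total_kb[ct$item == "spike"], 0.178)
  expect_equal(ct$total_kb[ct$item == "total"], 102.71)
  expect_equal(ct$total_kb[4] * 1000,
               sum(c(50 * 178, 11 * 8512, 1 * 178)))
  z <- memory_cost_report(n_neurons = 0, n_synapses = 0)
  expect_true(all(z$total_kb == 0))
})

test_that("weight memory hex words are 11-bit two's complement", {
  expect_identical(weight_to_hex(c(300, -1)), c("12C", "7FF"))
  expect_identical(weight_to_hex(c(0, -1024, 1023)), c("000", "400", "3FF"))
  w <- sample(-1024:1023, 500)
  expect_equal(hex_to_weight(weight_to_hex(w)), w)
  expect_error(weight_to_hex(1024))
})

test_that("a quantized network round-trips through the hex dump", {
  sys <- trained_default()
  lines <- export_weight_memory(sys$qnet)
  net2 <- sys$qnet
  net2$synapses$weight <- 0
  net2 <- load_weight_memory(lines, net2)
  expect_identical(net2$synapses$weight, sys$qnet$synapses$weight)
  expect_error(export_weight_memory(sys$fnet), "not quantized")
})

test_that("a network round-trips through the TSV serialization", {
  sys <- trained_default()
  dir <- withr::local_tempdir()
  write_network_tsv(sys$qnet, dir)
  back <- read_network_tsv(dir)
  expect_equal(back$synapses$weight, sys$qnet$synapses$weight)
  expect_equal(back$neurons$threshold, sys$qnet$neurons$threshold)
  expect_identical(attr(back, "scale"), attr(sys$qnet, "scale"))
})
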