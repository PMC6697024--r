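# Assembly-coded network construction: chained-overlap input assemblies,
# disjoint layer-I/recall and layer-II assemblies, interneurons, ADP neurons,
# theta banks, and the hardware memory-cost accounting.

#' Build the neural-assembly map
#'
#' Assigns neuron indices to per-pattern assemblies. Input assemblies are
#' chained: consecutive assemblies share `round(overlap_ratio * size)`
#' neurons (half-away-from-zero rounding; a warning is issued when the share
#' is not exact). Layer-I (mirrored one-to-one by the recall layer) and
#' layer-II assemblies are pairwise disjoint.
#'
#' @param n_patterns Number of stored patterns (default 4).
#' @param sizes Named vector/list with per-layer assembly sizes
#'   `c(input = 10, layer1 = 8, layer2 = 10)`.
#' @param overlap_ratio Fraction of an input assembly shared with its
#'   predecessor, in \[0, 1).
#' @return An object of class `assembly_map`: lists of neuron-index vectors
#'   per layer (`input`, `layer1`, `layer2`; the recall layer mirrors
#'   `layer1`), with the pattern labels `0..n_patterns-1`.
#' @examples
#' m <- build_assemblies()
#' normal_neuron_count(m)  # 97 for the default configuration
#' @export
build_assemblies <- function(n_patterns = 4,
                             sizes = c(input = 10, layer1 = 8, layer2 = 10),
                             overlap_ratio = 0.5) {
  sizes <- as.list(sizes)
  stopifnot(n_patterns >= 1, overlap_ratio >= 0, overlap_ratio < 1,
            all(unlist(sizes) >= 1))
  s_in <- as.integer(sizes$input)
  share_exact <- overlap_ratio * s_in
  share <- as.integer(round_half_away(share_exact))
  if (abs(share - share_exact) > 1e-8)
    warning(sprintf("overlap share %.2f rounded to %d neurons",
                    share_exact, share))
  stride <- s_in - share
  if (n_patterns > 1 && stride == 0)
    stop("overlap_ratio too large: consecutive input assemblies coincide")
  input <- lapply(seq_len(n_patterns) - 1L,
                  function(k) seq.int(k * stride + 1L, k * stride + s_in))
  s1 <- as.integer(sizes$layer1); s2 <- as.integer(sizes$layer2)
  layer1 <- lapply(seq_len(n_patterns) - 1L,
                   function(k) seq.int(k * s1 + 1L, (k + 1L) * s1))
  layer2 <- lapply(seq_len(n_patterns) - 1L,
                   function(k) seq.int(k * s2 + 1L, (k + 1L) * s2))
  structure(list(input = input, layer1 = layer1, layer2 = layer2,
                 labels = seq_len(n_patterns) - 1L),
            n_patterns = as.integer(n_patterns),
            sizes = c(input = s_in, layer1 = s1, layer2 = s2),
            overlap_ratio = overlap_ratio, share = share,
            class = "assembly_map")
}

#' @export
print.assembly_map <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat(sprintf("<assembly_map> %d patterns; sizes input=%d layer1=%d layer2=%d; overlap %.0f%% (share %d)\n",
              attr(x, "n_patterns"), sz["input"], sz["layer1"], sz["layer2"],
              100 * attr(x, "overlap_ratio"), attr(x, "share")))
  cat(sprintf("  distinct normal neurons (input + layer I + layer II): %d\n",
              normal_neuron_count(x)))
  invisible(x)
}

#' Count distinct normal neurons in the logical network
#'
#' Distinct neurons across the input, layer-I and layer-II assemblies
#' (the recall layer mirrors layer I and is not counted here): 97 for the
#' default 4-pattern configuration.
#'
#' @param map An [build_assemblies()] map.
#' @return Integer count.
#' @export
normal_neuron_count <- function(map) {
  length(unique(unlist(map$input))) +
    length(unique(unlist(map$layer1))) +
    length(unique(unlist(map$layer2)))
}

#' Default per-network scalar parameters
#'
#' Leaks and thresholds are in trained float units (threshold 1); they are
#' scaled by [fixpoint_network()]. The interneuron threshold is set so that a
#' strict majority of its assembly firing within one step triggers it; its
#' inhibition weight is delivered to every normal neuron of every other
#' assembly in the same layer. `adp_inhibition_weight` optionally extends that
#' inhibition to other assemblies' ADP neurons (0 disables the synapses).
#'
#' @param leak_recall,leak_layer2 Per-ms leak of recall-layer / layer-II
#'   normal neurons.
#' @param threshold Firing threshold of normal neurons (training convention 1).
#' @param w_interneuron Weight of each assembly-member synapse onto its
#'   interneuron.
#' @param interneuron_leak Interneuron leak per ms.
#' @param inhibition_weight (Negative) weight of interneuron synapses onto
#'   other assemblies' normal neurons.
#' @param adp_inhibition_weight (Negative) weight of interneuron synapses onto
#'   other assemblies' ADP neurons; 0 omits them (an active ADP chain is then
#'   stopped only by the engine's end-of-schedule clear).
#' @param reset_layer2 Reset potential of layer-II neurons. The negative
#'   default acts as a one-step relative refractory period: the trailing
#'   millisecond of a spread-out recall volley is absorbed instead of
#'   retriggering the assembly, which keeps one assembly per gamma subcycle.
#' @return A named list.
#' @export
network_params <- function(leak_recall = 0.045, leak_layer2 = 0.028,
                           threshold = 1, w_interneuron = 0.3,
                           interneuron_leak = 0.12,
                           inhibition_weight = -0.2,
                           adp_inhibition_weight = 0,
                           reset_layer2 = -1) {
  list(leak_recall = leak_recall, leak_layer2 = leak_layer2,
       threshold = threshold, w_interneuron = w_interneuron,
       interneuron_leak = interneuron_leak,
       inhibition_weight = inhibition_weight,
       adp_inhibition_weight = adp_inhibition_weight,
       reset_layer2 = reset_layer2)
}

#' Build the four-layer memory network
#'
#' Constructs the neuron and synapse tables. In hardware mode (the default)
#' the layer-I and recall layers are collapsed: one recall-layer normal neuron
#' per layer-I assembly slot carries the layer-I response role, and external
#' stimuli are routed directly onto the recall layer through the trainable
#' feedforward synapses; input channels appear in the table as spike sources
#' (`role == "input"`), not LIF neurons. With `on_hardware = FALSE` a distinct
#' layer-I population is kept between the input sources and the recall layer.
#'
#' Fixed wiring: one ADP neuron per recall normal (threshold = reset, zero
#' leak, so it fires continuously once activated); theta-bank neurons fully
#' connected to all recall normals with quantum weights; one interneuron per
#' assembly in the recall and II layers, driven by its own assembly and
#' inhibiting all other same-layer assemblies. Trainable synapses
#' (feedforward and lateral) are created with weight 0 and filled by
#' [train_network()].
#'
#' @param map An [build_assemblies()] map.
#' @param theta A [theta_spec()].
#' @param adp An [adp_spec()].
#' @param on_hardware Collapse layer I into the recall layer (default TRUE).
#' @param params A [network_params()] list.
#' @return An object of class `stm_network`: list with data.frames `neurons`
#'   (id, role, layer, assembly, slot, leak, reset, threshold) and `synapses`
#'   (pre, post, weight, kind, trainable), plus the specs. Attribute `scale`
#'   is 1 (float units) until [fixpoint_network()] is applied.
#' @examples
#' net <- build_network(build_assemblies())
#' lif_neuron_count(net)  # 178
#' @export
build_network <- function(map, theta = theta_spec(), adp = adp_spec(),
                          on_hardware = TRUE, params = network_params()) {
  n_pat <- attr(map, "n_patterns")
  sz <- attr(map, "sizes")
  bank <- theta_bank(theta)
  n_in <- length(unique(unlist(map$input)))
  n_rc <- n_pat * sz[["layer1"]]
  n_l2 <- n_pat * sz[["layer2"]]

  neurons <- list()
  add <- function(role, layer, assembly, slot, leak, reset, threshold) {
    data.frame(role = role, layer = layer, assembly = assembly, slot = slot,
               leak = leak, reset = reset, threshold = threshold)
  }
  neurons$input <- add("input", "input", NA_integer_, seq_len(n_in), 0, 0, Inf)
  if (!on_hardware) {
    neurons$layer1 <- add("normal", "layer1",
                          rep(map$labels, each = sz[["layer1"]]),
                          unlist(map$layer1), params$leak_recall, 0,
                          params$threshold)
  }
  neurons$recall <- add("normal", "recall",
                        rep(map$labels, each = sz[["layer1"]]),
                        unlist(map$layer1), params$leak_recall, 0,
                        params$threshold)
  neurons$layer2 <- add("normal", "layer2",
                        rep(map$labels, each = sz[["layer2"]]),
                        unlist(map$layer2), params$leak_layer2,
                        params$reset_layer2, params$threshold)
  thr_int <- function(size)
    params$w_interneuron * (floor(size / 2) + 1) - params$w_interneuron / 2
  neurons$int_rc <- add("interneuron", "recall", map$labels, seq_len(n_pat),
                        params$interneuron_leak, 0, thr_int(sz[["layer1"]]))
  neurons$int_l2 <- add("interneuron", "layer2", map$labels, seq_len(n_pat),
                        params$interneuron_leak, 0, thr_int(sz[["layer2"]]))
  # ADP neurons: reset == threshold, zero leak -> continuous firing once lit
  neurons$adp <- add("adp", "recall", rep(map$labels, each = sz[["layer1"]]),
                     seq_len(n_rc), 0, params$threshold, params$threshold)
  neurons$theta1 <- add("theta1", "recall", NA_integer_,
                        seq_len(bank$n_theta1), 0, 0, params$threshold)
  neurons$theta2 <- add("theta2", "recall", NA_integer_,
                        seq_len(bank$n_theta2), 0, 0, params$threshold)
  neurons <- do.call(rbind, neurons)
  neurons$id <- seq_len(nrow(neurons))
  rownames(neurons) <- NULL
  neurons <- neurons[, c("id", "role", "layer", "assembly", "slot",
                         "leak", "reset", "threshold")]

  nid <- function(layer, role = NULL, assembly = NULL, slot = NULL) {
    keep <- neurons$layer == layer
    if (!is.null(role)) keep <- keep & neurons$role == role
    if (!is.null(assembly)) keep <- keep & neurons$assembly %in% assembly &
        !is.na(neurons$assembly)
    if (!is.null(slot)) keep <- keep & neurons$slot %in% slot
    neurons$id[keep]
  }
  input_ids <- nid("input")
  recall_ids <- nid("recall", "normal")
  l2_ids <- nid("layer2", "normal")
  adp_ids <- nid("recall", "adp")
  th1_ids <- nid("recall", "theta1")
  th2_ids <- nid("recall", "theta2")

  syn <- list()
  edge <- function(pre, post, weight, kind, trainable = FALSE) {
    if (!length(pre) || !length(post)) return(NULL)
    data.frame(pre = pre, post = post, weight = weight, kind = kind,
               trainable = trainable)
  }
  cross <- function(pre, post, weight, kind, trainable = FALSE) {
    g <- expand.grid(pre = pre, post = post)
    edge(g$pre, g$post, weight, kind, trainable)
  }
  # feedforward stage 1: input channels -> first selective layer
  ff1_post <- if (on_hardware) recall_ids else nid("layer1", "normal")
  syn$ff1 <- cross(input_ids, ff1_post, 0, "feedforward", TRUE)
  if (!on_hardware) {
    # one-to-one relay layer1 -> recall (fixed)
    l1_ids <- nid("layer1", "normal")
    syn$relay <- edge(l1_ids, recall_ids, params$threshold, "feedforward")
  }
  # feedforward stage 2: recall -> layer II
  syn$ff2 <- cross(recall_ids, l2_ids, 0, "feedforward", TRUE)
  # full lateral connectivity within recall and within layer II (trainable,
  # pruned by learning)
  lat <- function(ids) {
    g <- expand.grid(pre = ids, post = ids)
    g <- g[g$pre != g$post, ]
    edge(g$pre, g$post, 0, "lateral", TRUE)
  }
  syn$lat_rc <- lat(recall_ids)
  syn$lat_l2 <- lat(l2_ids)
  # ADP wiring: normal -> its ADP neuron (trigger at threshold weight);
  # ADP neuron -> its normal (leak-compensating base; staircase increments
  # are added by the engine on top, see the methods vignette)
  syn$adp_trig <- edge(recall_ids, adp_ids, params$threshold, "adp")
  syn$adp_out <- edge(adp_ids, recall_ids, params$leak_recall, "adp")
  # theta banks: fully connected onto recall normals with quantum weights
  syn$th1 <- cross(th1_ids, recall_ids, theta$w_theta, "theta1")
  syn$th2 <- cross(th2_ids, recall_ids, theta$w_theta, "theta2")
  # interneurons: driven by own assembly, inhibit all other same-layer
  # assemblies (and optionally their ADP neurons)
  for (layer in c("recall", "layer2")) {
    normals <- if (layer == "recall") recall_ids else l2_ids
    for (k in map$labels) {
      own <- nid(layer, "normal", assembly = k)
      others <- setdiff(normals, own)
      int_id <- nid(layer, "interneuron", assembly = k)
      syn[[paste0("int_in_", layer, k)]] <-
        cross(own, int_id, params$w_interneuron, "feedforward")
      syn[[paste0("int_out_", layer, k)]] <-
        cross(int_id, others, params$inhibition_weight, "inhibitory")
      if (layer == "recall" && params$adp_inhibition_weight != 0) {
        other_adp <- setdiff(adp_ids, nid("recall", "adp", assembly = k))
        syn[[paste0("int_adp_", k)]] <-
          cross(int_id, other_adp, params$adp_inhibition_weight, "inhibitory")
      }
    }
  }
  synapses <- do.call(rbind, syn)
  rownames(synapses) <- NULL

  structure(list(neurons = neurons, synapses = synapses, map = map,
                 theta = theta, adp = adp, bank = bank, params = params,
                 on_hardware = on_hardware),
            scale = 1, class = "stm_network")
}

#' @export
print.stm_network <- function(x, ...) {
  cat(sprintf("<stm_network> %d neurons (%d LIF), %d synapses [scale %g]\n",
              nrow(x$neurons), lif_neuron_count(x), nrow(x$synapses),
              attr(x, "scale")))
  print(table(x$neurons$role))
  invisible(x)
}

#' Count LIF neurons realized in hardware
#'
#' Counts all neurons except the input spike sources (input channels are not
#' implemented as LIF neurons on the hardware): 178 for the default
#' configuration (32 recall + 40 layer-II normals, 8 interneurons, 32 ADP,
#' 60 + 6 theta neurons).
#'
#' @param net An `stm_network`.
#' @param role Optionally restrict to one role
#'   (`"normal"`, `"interneuron"`, `"adp"`, `"theta1"`, `"theta2"`).
#' @return Integer count.
#' @export
lif_neuron_count <- function(net, role = NULL) {
  n <- net$neurons[net$neurons$role != "input", ]
  if (!is.null(role)) n <- n[n$role == role, ]
  nrow(n)
}

#' Hardware memory-cost table
#'
#' Tabulates the on-chip memory cost: per-neuron parameter storage, synaptic
#' weight storage, and the one-bit-per-neuron spike registers, in kilobits
#' (1 kb = 1000 bits). Totals are computed as exact integer bit sums. The
#' synapse count may be given directly (the hardware configuration constant)
#' or derived from a network.
#'
#' @param net Optional `stm_network`; supplies the neuron and synapse counts.
#' @param n_neurons,n_synapses Counts used when `net` is NULL.
#' @param neuron_bits Bits per neuron record (default 50 = 14 + 8 + 14 + 14).
#' @param weight_bits Bits per synaptic weight (default 11).
#' @param spike_bits Bits per neuron spike register (default 1).
#' @return A `cost_table` data.frame with columns `item`, `single_cost_bits`,
#'   `count`, `total_kb`, including a `total` row.
#' @examples
#' memory_cost_report(n_neurons = 178, n_synapses = 8512)
#' @export
memory_cost_report <- function(net = NULL, n_neurons = NULL, n_synapses = NULL,
                               neuron_bits = 50L, weight_bits = 11L,
                               spike_bits = 1L) {
  if (!is.null(net)) {
    if (is.null(n_neurons)) n_neurons <- lif_neuron_count(net)
    if (is.null(n_synapses)) n_synapses <- nrow(net$synapses)
  }
  stopifnot(n_neurons >= 0, n_synapses >= 0)
  bits <- c(neuron = neuron_bits * n_neurons,
            weight = weight_bits * n_synapses,
            spike = spike_bits * n_neurons)
  out <- data.frame(
    item = c("neuron", "weight", "spike", "total"),
    single_cost_bits = c(neuron_bits, weight_bits, spike_bits, NA),
    count = c(n_neurons, n_synapses, n_neurons, NA),
    total_kb = c(bits, sum(bits)) / 1000)
  class(out) <- c("cost_table", "data.frame")
  out
}
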