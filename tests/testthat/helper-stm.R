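# Shared fixtures: the default four-pattern system is trained once per test
# run and memoized (float and quantized variants share the training).

.stm_cache <- new.env(parent = emptyenv())

default_patterns <- function(seed = 1L) {
  generate_patterns(n_patterns = 4, assembly_size = 10, overlap_ratio = 0.5,
                    gamma_period = 9.9, seed = seed)
}

trained_default <- function() {
  if (is.null(.stm_cache$sys)) {
    net <- build_network(build_assemblies())
    patterns <- default_patterns()
    fnet <- suppressWarnings(
      train_network(net, patterns, sequence = 0:3,
                    cfg = learning_config(seed = 1L)))
    qnet <- fixpoint_network(fnet)
    .stm_cache$sys <- list(fnet = fnet, qnet = qnet, patterns = patterns)
  }
  .stm_cache$sys
}

default_refs <- function() {
  if (is.null(.stm_cache$refs)) {
    sys <- trained_default()
    .stm_cache$refs <- reference_responses(sys$qnet, sys$patterns)
  }
  .stm_cache$refs
}

# which recall assemblies fire within the presentation theta cycle
layer1_decision <- function(net, patterns, cue) {
  sched <- stimulus_schedule(as.integer(cue), patterns, net$theta)
  raster <- run_network(net, sched, horizon = 120)
  rc <- raster_slice(raster, "recall",
                     window = c(sched$times[1], sched$times[1] + net$theta$period))
  sort(unique(rc$assembly))
}

# continuous closed-form Gaussian inner-product correlation (independent
# oracle for the grid-based r_corr)
r_corr_closed_form <- function(a, d, sigma_c = 2) {
  if (!length(a) || !length(d)) return(0)
  g <- function(x, y) sum(exp(-outer(x, y, "-")^2 / (4 * sigma_c^2)))
  g(a, d) / sqrt(g(a, a) * g(d, d))
}
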