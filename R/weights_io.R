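# Serialization: network TSV tables, hex weight-memory dumps for hardware
# loading, and spike-raster TSV output.

#' Export the synaptic weight memory as a hex dump
#'
#' Writes one 11-bit two's-complement weight per line (three zero-padded hex
#' digits), in deterministic post-neuron-major, pre-neuron-minor order, so the
#' file can be streamed into the hardware weight memory. Only quantized
#' networks (integer weights at scale > 1) can be exported.
#'
#' @param net A quantized `stm_network` (see [fixpoint_network()]).
#' @param path Optional file path; when NULL the lines are returned.
#' @return Invisibly (or visibly when `path` is NULL) the character vector of
#'   hex lines, with a `#`-prefixed header.
#' @examples
#' weight_to_hex(c(300, -1))  # "12C" "7FF"
#' @export
export_weight_memory <- function(net, path = NULL) {
  w <- net$synapses$weight
  if (attr(net, "scale") <= 1 || any(w != round(w)))
    stop("weights are not quantized; run fixpoint_network() first")
  ord <- order(net$synapses$post, net$synapses$pre)
  lines <- c(sprintf("# stmnet weight memory: %d synapses, 11-bit two's complement",
                     length(w)),
             weight_to_hex(w[ord]))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname export_weight_memory
#' @param w Integer weight vector in \[-1024, 1023\].
#' @export
weight_to_hex <- function(w) {
  stopifnot(all(w >= -1024), all(w <= 1023), all(w == round(w)))
  sprintf("%03X", ifelse(w < 0, w + 2048, w))
}

#' @rdname export_weight_memory
#' @param hex Character vector of three-digit hex words.
#' @export
hex_to_weight <- function(hex) {
  v <- strtoi(hex, base = 16L)
  if (any(is.na(v)) || any(v < 0) || any(v > 2047))
    stop("malformed 11-bit hex word")
  ifelse(v >= 1024, v - 2048, v)
}

#' Load a hex weight dump back into a network
#'
#' Inverse of [export_weight_memory()]; restores weights bit-exactly using the
#' same deterministic ordering.
#'
#' @param x Path to a dump file, or the character lines themselves.
#' @param net The quantized `stm_network` the dump belongs to.
#' @return The network with weights replaced.
#' @export
load_weight_memory <- function(x, net) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) != nrow(net$synapses))
    stop("dump length does not match the network's synapse count")
  ord <- order(net$synapses$post, net$synapses$pre)
  net$synapses$weight[ord] <- hex_to_weight(lines)
  net
}

.header_lines <- function(config_hash = NULL, seed = NULL) {
  c(sprintf("# stmnet %s", as.character(utils::packageVersion("stmnet"))),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash),
    if (!is.null(seed)) sprintf("# seed: %s", seed))
}

.write_tsv <- function(df, path, config_hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(config_hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a network as TSV tables
#'
#' Serializes the neuron and synapse tables as `neurons.tsv` and
#' `synapses.tsv` plus a YAML header (`network.yaml`) holding the scalar
#' specs, in the given directory. `read_network_tsv()` restores the object;
#' the round trip is exact.
#'
#' @param net An `stm_network`.
#' @param dir Directory to write into (created if missing).
#' @param config_hash,seed Optional provenance stamps for the file headers.
#' @return `dir`, invisibly.
#' @export
write_network_tsv <- function(net, dir, config_hash = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(net$neurons, file.path(dir, "neurons.tsv"), config_hash, seed)
  .write_tsv(net$synapses, file.path(dir, "synapses.tsv"), config_hash, seed)
  hdr <- list(scale = attr(net, "scale"), on_hardware = net$on_hardware,
              theta = unclass(net$theta), adp = unclass(net$adp),
              params = net$params,
              map = list(n_patterns = attr(net$map, "n_patterns"),
                         sizes = as.list(attr(net$map, "sizes")),
                         overlap_ratio = attr(net$map, "overlap_ratio")))
  yaml::write_yaml(hdr, file.path(dir, "network.yaml"))
  invisible(dir)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(dir) {
  hdr <- yaml::read_yaml(file.path(dir, "network.yaml"))
  map <- build_assemblies(hdr$map$n_patterns, unlist(hdr$map$sizes),
                          hdr$map$overlap_ratio)
  net <- build_network(map,
                       theta = do.call(theta_spec, hdr$theta[c("period", "amplitude", "w_theta", "phase_of_valley")]),
                       adp = do.call(adp_spec, hdr$adp[c("slope", "grid", "gamma_period", "tau_adp")]),
                       on_hardware = hdr$on_hardware,
                       params = hdr$params)
  neurons <- .read_tsv(file.path(dir, "neurons.tsv"))
  synapses <- .read_tsv(file.path(dir, "synapses.tsv"))
  net$neurons <- neurons
  net$synapses <- synapses
  attr(net, "scale") <- hdr$scale
  net
}

#' Write a spike raster as TSV
#'
#' Columns: `time_ms`, `neuron_id`, `role`, `layer`, `assembly`.
#'
#' @param raster A `spike_raster` data.frame from [run_network()].
#' @param path Output path.
#' @param config_hash,seed Optional provenance stamps.
#' @return `path`, invisibly.
#' @export
write_raster_tsv <- function(raster, path, config_hash = NULL, seed = NULL) {
  .write_tsv(as.data.frame(raster), path, config_hash, seed)
}
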