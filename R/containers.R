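#' Read and write epochs in the native container
#'
#' Serializes the full [epochs()] schema (data array, fs, time base,
#' labels, annotations, baseline, processing log) via R serialization;
#' round trips are bit-exact.
#'
#' @param ep an [epochs()] object.
#' @param path file path.
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "epochs"))
  saveRDS(unclass(ep), path, version = 2)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  epochs(obj$data, fs = obj$fs, t_start = obj$t_start, labels = obj$labels,
         annotations = obj$annotations, baseline = obj$baseline,
         log = obj$log)
}

#' Read and write network specifications as YAML
#'
#' Serializes a [network_spec()] (node dynamics, couplings, per-condition
#' overrides) to a YAML config. Requires the `yaml` package.
#'
#' @param spec a [network_spec()].
#' @param path file path.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("the yaml package is required for YAML configs")
  }
  obj <- list(n_nodes = spec$n_nodes, f0 = spec$f0, damping = spec$damping,
              noise_sd = spec$noise_sd, fs = spec$fs, labels = spec$labels,
              couplings = if (nrow(spec$couplings)) spec$couplings,
              condition_deltas = lapply(spec$condition_deltas, function(d)
                if (nrow(d)) d))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("the yaml package is required for YAML configs")
  }
  obj <- yaml::read_yaml(path)
  as_cp <- function(x) if (is.null(x)) NULL else as.data.frame(x)
  network_spec(n_nodes = obj$n_nodes, f0 = obj$f0, damping = obj$damping,
               couplings = as_cp(obj$couplings), noise_sd = obj$noise_sd,
               fs = obj$fs,
               condition_deltas = lapply(obj$condition_deltas, as_cp),
               labels = obj$labels)
}
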