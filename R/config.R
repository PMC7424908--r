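#' Default pipeline configuration
#'
#' One serialisable list holding the geometry and every threshold parameter of
#' the pipeline at its reference default, suitable for writing to YAML with
#' [write_config()] and editing per rig.
#'
#' @return A nested list of class `fp_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = unclass(geometry()),
    blink = unclass(blink_params()),
    filter = unclass(filter_params()),
    detection = unclass(detection_params()),
    selection = unclass(selection_params()),
    epoch = lapply(unclass(epoch_params()), as.numeric),
    cluster = unclass(cluster_params())),
    class = "fp_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config An `fp_config` list (default [default_config()]).
#' @return `read_config()` returns an `fp_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config = default_config(), path) {
  yaml::write_yaml(unclass(lapply(config, unclass)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(raw))
    for (k in names(raw[[sec]]))
      cfg[[sec]][[k]] <- raw[[sec]][[k]]
  cfg
}

#' Typed parameter objects from a configuration
#'
#' Rebuilds the validated parameter objects from a (possibly edited)
#' configuration list.
#'
#' @param config An `fp_config`.
#' @return A list with `geometry`, `blink`, `filter`, `detection`,
#'   `selection`, `epoch`, `cluster` objects.
#' @export
config_params <- function(config) {
  list(geometry = do.call(geometry, config$geometry),
       blink = do.call(blink_params, config$blink),
       filter = do.call(filter_params, config$filter),
       detection = do.call(detection_params, config$detection),
       selection = do.call(selection_params, config$selection),
       epoch = epoch_params(config$epoch$window_ms, config$epoch$baseline_ms),
       cluster = do.call(cluster_params, config$cluster))
}
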