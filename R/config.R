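#' Read a simulation config file
#'
#' Configs are YAML (if the `yaml` package is available) or JSON with up to
#' four blocks: `neuron` and `astrocyte` (parameter overrides), `protocol`
#' (either `preset: <name>` or an explicit spec with `kind` plus
#' `levels`/`durations`, `T_total`/`rate_scale`, or `spike_file`), and
#' `solver` (`dt_out`, `rtol`, `atol`, `dt`, `pwl_tol`).
#'
#' @param path config file path
#' @return list with `neuron`, `astro`, `protocol`, `solver`
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)

  np <- do.call(neuron_params, as.list(cfg$neuron %||% list()))
  acfg <- as.list(cfg$astrocyte %||% list())
  preset_name <- acfg$preset %||% "base"
  acfg$preset <- NULL
  ap <- do.call(astro_preset, c(list(name = preset_name), acfg))

  proto <- NULL
  pc <- cfg$protocol
  if (!is.null(pc)) {
    if (!is.null(pc$preset)) {
      proto <- experiment_spec(pc$preset)$protocol
    } else {
      proto <- switch(pc$kind %||% "ip3_clamp_piecewise_constant",
        ip3_clamp_piecewise_constant = {
          if (isTRUE(pc$cumulative))
            protocol_staircase(pc$levels, pc$durations %||% 100)
          else protocol_clamp(pc$levels, pc$durations)
        },
        spike_driven = protocol_spike_driven(pc$T_total %||% 500,
                                             pc$rate_scale %||% 0.01),
        spike_file = protocol_spike_file(pc$spike_file, pc$T_total),
        stop("unknown protocol kind: ", pc$kind))
    }
  }
  list(neuron = np, astro = ap, protocol = proto,
       solver = as.list(cfg$solver %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
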