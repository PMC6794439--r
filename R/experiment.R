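#' Preset experiments
#'
#' Named end-to-end experiments combining a parameter set and a protocol:
#' \describe{
#'   \item{`staircase`}{base parameters; five-level incremental IP3
#'     staircase (increments 0.125, 0.275, 0.13125, 0.09375, 0.575 uM,
#'     100 s per level, cumulative levels 0.125, 0.4, 0.53125, 0.625,
#'     1.2 uM) spanning the steady / oscillatory / damped regimes.}
#'   \item{`spike_driven`}{base parameters; 500 s of IF-neuron spike drive
#'     (thinned by `rate_scale = 0.01`) through the full 2-AG / IP3 chain.}
#'   \item{`step_am`, `step_fm`, `step_afm`}{modulation presets (see
#'     [astro_preset()]); IP3 clamp at 0.4 uM, stepped to 0.6 uM during
#'     150-350 s, back to 0.4 uM until 500 s.}
#' }
#' The names `fig6`, `fig8`, `fig9_am`, `fig9_fm`, `fig9_afm` are accepted
#' as aliases in the same order.
#'
#' @param preset experiment name (see above)
#' @param overrides named list of [astro_params()] overrides
#' @param dt digital Euler step (s); also the comparison grid
#' @param pwl_tol PWL error budget per function for the digital designs
#' @param out_dir optional directory for the output bundle (trace CSVs,
#'   comparison JSON/CSV, design JSON, modulation JSON)
#' @param rtol,atol reference solver tolerances
#' @return invisibly, a list with `reference`, `digital` (traces),
#'   `report` (comparison), `mode` (for clamp protocols), `regimes`
#'   (per-level calls for the staircase), `designs`, `protocol`
#' @export
run_experiment <- function(preset, overrides = list(), dt = 1e-3,
                           pwl_tol = 1e-4, out_dir = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  spec <- experiment_spec(preset)
  ap <- do.call(astro_preset, c(list(name = spec$astro), overrides))
  np <- neuron_params()
  proto <- spec$protocol
  designs <- build_designs(np, ap, dt = dt, pwl_tol = pwl_tol)
  ref <- simulate_reference(proto, np, ap, dt_out = dt, rtol = rtol, atol = atol)
  dig <- run_digital(proto, np, ap, designs = designs)
  rep <- compare_traces(ref, dig, window_policy = "ten_cycles")

  mode <- NULL; regimes <- NULL
  if (proto$kind == "ip3_clamp_piecewise_constant") {
    mode <- list(reference = analyze_modulation(ref, proto),
                 digital = analyze_modulation(dig, proto))
    regimes <- segment_regimes(ref, proto)
  }
  bundle <- list(preset = spec$name, reference = ref, digital = dig,
                 report = rep, mode = mode, regimes = regimes,
                 designs = designs, protocol = proto)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

experiment_spec <- function(preset) {
  alias <- c(fig6 = "staircase", fig8 = "spike_driven",
             fig9_am = "step_am", fig9_fm = "step_fm", fig9_afm = "step_afm")
  if (preset %in% names(alias)) preset <- alias[[preset]]
  step_proto <- protocol_clamp(c(0.4, 0.6, 0.4), c(150, 200, 150))
  specs <- list(
    staircase = list(astro = "base",
                     protocol = protocol_staircase(
                       c(0.125, 0.275, 0.13125, 0.09375, 0.575), each = 100)),
    spike_driven = list(astro = "base",
                        protocol = protocol_spike_driven(500, rate_scale = 0.01)),
    step_am = list(astro = "am", protocol = step_proto),
    step_fm = list(astro = "fm", protocol = step_proto),
    step_afm = list(astro = "afm", protocol = step_proto))
  if (!preset %in% names(specs))
    stop("unknown preset '", preset, "'; available: ",
         paste(c(names(specs), names(alias)), collapse = ", "))
  c(specs[[preset]], name = preset)
}

# Regime call per clamp segment, each segment judged on its own window.
# Unlike the modulation stats, no post-edge guard is applied: the damping
# transient right after a level edge is exactly what distinguishes a damped
# segment from a steady one. The first segment discards half its length as
# burn-in from the global initial conditions.
segment_regimes <- function(trace, proto, prominence = 0.05) {
  seg <- proto$segments
  edges <- c(0, cumsum(seg$duration))
  calls <- character(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    t0 <- edges[k] + if (k == 1) seg$duration[1] / 2 else 0
    sub <- trace[trace$t >= t0 & trace$t <= edges[k + 1], , drop = FALSE]
    pk <- detect_peaks(as_trace(sub, attr(trace, "dt")), burn_in = -Inf,
                       prominence = prominence)
    calls[k] <- if (nrow(pk) == 0) "steady"
    else {
      final <- sub$Ca[sub$t >= edges[k + 1] - (edges[k + 1] - t0) / 4]
      if (all(diff(pk$amplitude) <= 1e-6) &&
          diff(range(final)) < 0.1 * pk$amplitude[1]) "damped" else "oscillatory"
    }
  }
  data.frame(level = seg$level, regime = calls)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trace(bundle$reference, file.path(out_dir, "reference_trace.csv"))
  write_trace(bundle$digital, file.path(out_dir, "digital_trace.csv"))
  rep <- bundle$report
  utils::write.csv(as.data.frame(rep), file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report_to_list(rep),
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(designs_to_list(bundle$designs),
                       file.path(out_dir, "designs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$mode)) {
    jsonlite::write_json(
      lapply(bundle$mode, mode_to_list),
      file.path(out_dir, "modulation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$regimes))
    utils::write.csv(bundle$regimes, file.path(out_dir, "regimes.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}

designs_to_list <- function(des) {
  list(dt = des$dt, pwl_tol = des$pwl_tol, cube = des$cube,
       pwl = lapply(des$pwl, pwl_to_list),
       scm = lapply(des$scm, scm_to_list))
}

mode_to_list <- function(mc) {
  list(mode = mc$mode, amplitude_change = mc$amplitude_change,
       frequency_change = mc$frequency_change,
       diagnostic = mc$diagnostic,
       thresholds = as.list(mc$thresholds),
       per_level = lapply(mc$per_level, function(s)
         list(n_peaks = s$n_peaks, mean_amplitude = s$mean_amplitude,
              mean_frequency = s$mean_frequency)))
}

#' Write PWL/SCM design tables as JSON
#'
#' @param designs a `digital_designs` object
#' @param path output file
#' @export
write_designs_json <- function(designs, path) {
  jsonlite::write_json(designs_to_list(designs), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
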