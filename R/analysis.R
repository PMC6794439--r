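#' Detect calcium oscillation peaks
#'
#' Finds local maxima of the Ca series after a burn-in period; each peak's
#' amplitude is measured against the preceding trough (the minimum since
#' the previously accepted peak), and peaks whose amplitude falls below
#' `prominence` are discarded.
#'
#' @param trace an `astro_trace`, or a numeric series (then supply `times`)
#' @param burn_in seconds discarded at the start
#' @param prominence minimum peak-to-preceding-trough amplitude (uM)
#' @param times sample times when `trace` is a bare numeric series
#' @return data frame with columns `time`, `value`, `trough`, `amplitude`
#' @export
detect_peaks <- function(trace, burn_in = 100, prominence = 0.05,
                         times = NULL) {
  if (inherits(trace, "astro_trace")) {
    v <- trace$Ca; t <- trace$t
  } else {
    v <- as.numeric(trace)
    t <- if (is.null(times)) seq_along(v) else times
  }
  keep <- t >= burn_in
  v <- v[keep]; t <- t[keep]
  empty <- data.frame(time = numeric(0), value = numeric(0),
                      trough = numeric(0), amplitude = numeric(0))
  if (length(v) < 3) return(empty)
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  if (!length(cand)) return(empty)
  out_t <- out_v <- out_tr <- numeric(0)
  last <- 1L
  for (j in cand) {
    tr <- min(v[last:j])
    if (v[j] - tr >= prominence) {
      out_t <- c(out_t, t[j]); out_v <- c(out_v, v[j]); out_tr <- c(out_tr, tr)
      last <- j
    }
  }
  data.frame(time = out_t, value = out_v, trough = out_tr,
             amplitude = out_v - out_tr)
}

#' Oscillation statistics over one or several time windows
#'
#' Pools peaks detected inside each window; inter-peak intervals are only
#' taken between peaks of the same window, so disjoint windows (e.g. the
#' two low-level epochs of a step protocol) never contribute spurious
#' intervals. Frequency is the reciprocal mean interval; it is 0 when
#' fewer than two peaks exist.
#'
#' @param trace an `astro_trace`
#' @param windows a `c(t0, t1)` pair or list of such pairs (s)
#' @param prominence peak prominence threshold (uM)
#' @return an `oscillation_stats` object
#' @export
oscillation_stats <- function(trace, windows, prominence = 0.05) {
  if (!is.list(windows)) windows <- list(windows)
  amps <- numeric(0); intervals <- numeric(0); n <- 0L; times <- numeric(0)
  for (w in windows) {
    sub <- trace[trace$t >= w[1] & trace$t <= w[2], , drop = FALSE]
    pk <- detect_peaks(as_trace(sub, attr(trace, "dt")), burn_in = -Inf,
                       prominence = prominence)
    n <- n + nrow(pk)
    amps <- c(amps, pk$amplitude)
    times <- c(times, pk$time)
    if (nrow(pk) > 1) intervals <- c(intervals, diff(pk$time))
  }
  structure(list(
    n_peaks = n, peak_times = times, peak_amplitudes = amps,
    mean_amplitude = if (n) mean(amps) else NA_real_,
    inter_peak_intervals = intervals,
    mean_frequency = if (length(intervals)) 1 / mean(intervals) else 0,
    amplitude_cv = if (n > 1) stats::sd(amps) / mean(amps) else NA_real_,
    interval_cv = if (length(intervals) > 1)
      stats::sd(intervals) / mean(intervals) else NA_real_,
    window = range(unlist(windows))), class = "oscillation_stats")
}

#' @export
print.oscillation_stats <- function(x, ...) {
  cat(sprintf(
    "Oscillation stats [%g, %g] s: %d peaks, mean amplitude %.3f uM, mean frequency %.4f Hz\n",
    x$window[1], x$window[2], x$n_peaks, x$mean_amplitude, x$mean_frequency))
  invisible(x)
}

#' Classify the calcium response regime
#'
#' `oscillatory` when peaks persist past the burn-in without a monotone
#' decay; `damped` when the response rings -- peaks whose amplitudes decay
#' monotonically (possibly entirely inside the burn-in window, as a strong
#' stimulus can ring down within seconds) -- and the calcium excursion in
#' the final quarter of the record is below 10% of the first peak
#' amplitude; `steady` when no ringing occurred at all. The burn-in guards
#' the steady/oscillatory statistics against the initial transient, but
#' ring-down evidence is sought over the whole record.
#'
#' @inheritParams detect_peaks
#' @return one of `"steady"`, `"damped"`, `"oscillatory"`
#' @export
classify_regime <- function(trace, burn_in = 100, prominence = 0.05) {
  if (max(trace$t) < 2 * burn_in)
    stop("trace must be at least twice the burn-in long")
  t_end <- max(trace$t)
  final <- trace$Ca[trace$t >= t_end - (t_end - burn_in) / 4]
  final_amp <- diff(range(final))
  pk <- detect_peaks(trace, burn_in = burn_in, prominence = prominence)
  if (nrow(pk) == 0) {
    pk_all <- detect_peaks(trace, burn_in = 0, prominence = prominence)
    return(if (nrow(pk_all) > 0 && final_amp < 0.1 * pk_all$amplitude[1])
      "damped" else "steady")
  }
  decaying <- all(diff(pk$amplitude) <= 1e-6)
  if (decaying && final_amp < 0.1 * pk$amplitude[1]) "damped" else "oscillatory"
}

#' Classify the information-encoding mode between two stimulus levels
#'
#' Relative changes of mean peak amplitude and mean frequency between a low
#' and a high stimulus level decide the call: amplitude modulation (AM)
#' when only the amplitude change exceeds its threshold, frequency
#' modulation (FM) when only the frequency change does, AFM when both do,
#' `none` otherwise. Non-oscillatory input (fewer than two peaks at either
#' level) yields `none` with a diagnostic.
#'
#' @param stats_low,stats_high `oscillation_stats` at the two levels
#' @param amp_thresh,freq_thresh relative-change thresholds
#' @return a `mode_call` object
#' @export
classify_modulation <- function(stats_low, stats_high,
                                amp_thresh = 0.15, freq_thresh = 0.15) {
  if (stats_low$n_peaks < 2 || stats_high$n_peaks < 2) {
    return(structure(list(mode = "none",
                          amplitude_change = NA_real_,
                          frequency_change = NA_real_,
                          diagnostic = "non-oscillatory window(s)",
                          stats = list(low = stats_low, high = stats_high),
                          thresholds = c(amp = amp_thresh, freq = freq_thresh)),
                     class = "mode_call"))
  }
  dA <- abs(stats_high$mean_amplitude - stats_low$mean_amplitude) /
    stats_low$mean_amplitude
  dF <- abs(stats_high$mean_frequency - stats_low$mean_frequency) /
    stats_low$mean_frequency
  mode <- if (dA > amp_thresh && dF <= freq_thresh) "AM"
  else if (dF > freq_thresh && dA <= amp_thresh) "FM"
  else if (dA > amp_thresh && dF > freq_thresh) "AFM"
  else "none"
  structure(list(mode = mode, amplitude_change = dA, frequency_change = dF,
                 diagnostic = NULL,
                 stats = list(low = stats_low, high = stats_high),
                 thresholds = c(amp = amp_thresh, freq = freq_thresh)),
            class = "mode_call")
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf("Modulation mode: %s (amplitude change %.3f, frequency change %.3f)\n",
              x$mode, x$amplitude_change, x$frequency_change))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Modulation analysis of a clamp-protocol trace
#'
#' Groups the protocol's clamp segments by level, builds pooled oscillation
#' statistics per level (excluding `guard` seconds after each level edge
#' and the global burn-in), and classifies the modulation mode between the
#' lowest and highest level.
#'
#' @param trace an `astro_trace` from a clamp protocol
#' @param proto the protocol that produced the trace (defaults to the
#'   trace's snapshot)
#' @param burn_in initial transient to discard (s)
#' @param guard post-edge transient to discard in every segment (s)
#' @param prominence peak prominence (uM)
#' @inheritParams classify_modulation
#' @return a `mode_call` with an extra `per_level` list of stats
#' @export
analyze_modulation <- function(trace, proto = attr(trace, "protocol"),
                               burn_in = 100, guard = 30, prominence = 0.05,
                               amp_thresh = 0.15, freq_thresh = 0.15) {
  if (is.null(proto) || proto$kind != "ip3_clamp_piecewise_constant")
    stop("analyze_modulation needs a clamp protocol")
  seg <- proto$segments
  edges <- c(0, cumsum(seg$duration))
  wins <- lapply(seq_len(nrow(seg)), function(k)
    c(max(edges[k] + guard, burn_in), edges[k + 1]))
  ok <- vapply(wins, function(w) w[2] > w[1], logical(1))
  levels <- sort(unique(seg$level[ok]))
  per_level <- lapply(levels, function(lv)
    oscillation_stats(trace, wins[ok & seg$level == lv], prominence))
  names(per_level) <- as.character(levels)
  call <- classify_modulation(per_level[[1]], per_level[[length(per_level)]],
                              amp_thresh, freq_thresh)
  call$per_level <- per_level
  call$levels <- levels
  call
}

#' Phase-plane trajectory
#'
#' Extracts paired post-burn-in samples of two trace variables for
#' phase-plane inspection of the limit cycle. No resampling is applied.
#'
#' @param trace an `astro_trace`
#' @param pair two of `"Ca"`, `"h"`, `"J_chan"` (e.g. `c("Ca", "h")`)
#' @param burn_in seconds discarded at the start
#' @return two-column data frame
#' @export
phase_plane <- function(trace, pair = c("Ca", "h"), burn_in = 100) {
  valid <- list(c("Ca", "h"), c("Ca", "J_chan"), c("h", "J_chan"))
  if (!any(vapply(valid, function(v) identical(v, pair), logical(1))))
    stop("pair must be one of: ",
         paste(vapply(valid, paste, "", collapse = "-"), collapse = ", "))
  sub <- trace[trace$t >= burn_in, pair, drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Hausdorff distance between two planar point sets
#'
#' Symmetric Hausdorff distance under the Euclidean metric; point sets are
#' thinned to at most `max_points` evenly spaced samples first.
#'
#' @param a,b two-column matrices or data frames
#' @param max_points thinning cap per set
#' @return a non-negative scalar
#' @export
hausdorff_distance <- function(a, b, max_points = 2000) {
  thin <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) > max_points)
      m <- m[round(seq(1, nrow(m), length.out = max_points)), , drop = FALSE]
    m
  }
  a <- thin(a); b <- thin(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}
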