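#' Stimulation protocols
#'
#' A protocol declares how the astrocyte is driven: either the IP3
#' concentration is clamped to a piecewise-constant waveform (the IP3 and
#' 2-AG production equations are bypassed), or spikes release 2-AG and IP3
#' follows its own dynamics. Spikes come from the IF neuron
#' (`protocol_spike_driven`), an explicit time list
#' (`protocol_spike_times`), or a plain-text file with one spike time in
#' seconds per line (`protocol_spike_file`).
#'
#' @param levels IP3 clamp levels (uM), one per segment
#' @param durations segment durations (s); recycled against `levels`
#' @name protocols
NULL

new_protocol <- function(kind, segments = NULL, spike_times = NULL,
                         T_total, rate_scale = NA_real_) {
  if (!is.null(segments)) {
    if (any(segments$duration <= 0)) stop("segment durations must be > 0")
    if (any(segments$level < 0)) stop("IP3 levels must be >= 0")
  }
  if (!is.numeric(T_total) || length(T_total) != 1 || T_total < 0)
    stop("T_total must be a non-negative scalar")
  if (!is.null(spike_times) && length(spike_times)) {
    if (is.unsorted(spike_times, strictly = TRUE))
      stop("spike times must be strictly increasing")
    if (any(spike_times < 0) || any(spike_times >= T_total))
      stop("spike times must lie in [0, T_total)")
  }
  structure(list(kind = kind, segments = segments, spike_times = spike_times,
                 T_total = T_total, rate_scale = rate_scale),
            class = "astro_protocol")
}

#' @rdname protocols
#' @export
protocol_clamp <- function(levels, durations) {
  seg <- data.frame(duration = rep_len(durations, length(levels)),
                    level = levels)
  new_protocol("ip3_clamp_piecewise_constant", segments = seg,
               T_total = sum(seg$duration))
}

#' @rdname protocols
#' @param increments per-segment IP3 increments (uM); the clamp level of
#'   segment k is the cumulative sum of the first k increments
#' @param each common segment duration (s)
#' @param cumulative if `FALSE`, `increments` are used directly as absolute
#'   levels
#' @export
protocol_staircase <- function(increments, each = 100, cumulative = TRUE) {
  levels <- if (cumulative) cumsum(increments) else increments
  protocol_clamp(levels, each)
}

#' @rdname protocols
#' @param T_total protocol duration (s)
#' @param rate_scale fraction of IF spikes retained as 2-AG release events;
#'   the default thins the ~45 Hz IF train to an effective gliotransmission
#'   drive of ~0.45 Hz
#' @export
protocol_spike_driven <- function(T_total = 500, rate_scale = 0.01) {
  if (rate_scale <= 0 || rate_scale > 1) stop("rate_scale must be in (0, 1]")
  new_protocol("spike_driven", T_total = T_total, rate_scale = rate_scale)
}

#' @rdname protocols
#' @param times spike times (s), strictly increasing
#' @export
protocol_spike_times <- function(times, T_total = NULL) {
  if (is.null(T_total)) T_total <- if (length(times)) max(times) + 1 else 0
  new_protocol("spike_file", spike_times = as.numeric(times),
               T_total = T_total)
}

#' @rdname protocols
#' @param path text file with one spike time (seconds) per line
#' @export
protocol_spike_file <- function(path, T_total = NULL) {
  times <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  protocol_spike_times(times, T_total)
}

#' @export
print.astro_protocol <- function(x, ...) {
  cat(sprintf("Protocol <%s>, duration %g s\n", x$kind, x$T_total))
  if (!is.null(x$segments)) {
    cat("  clamp segments (duration s -> level uM):\n")
    with(x$segments, cat(sprintf("    %g s -> %g uM\n", duration, level), sep = ""))
  }
  if (!is.null(x$spike_times))
    cat(sprintf("  %d spike times\n", length(x$spike_times)))
  if (!is.na(x$rate_scale))
    cat(sprintf("  IF spike train thinned by rate_scale = %g\n", x$rate_scale))
  invisible(x)
}

#' Spike times of the IF neuron under constant drive
#'
#' Uses the exact solution of the membrane equation between resets, then
#' optionally thins the train by keeping every `1/rate_scale`-th spike.
#'
#' @param np a `neuron_params` object
#' @param T_total duration (s)
#' @param rate_scale retained fraction of spikes (1 = keep all)
#' @return numeric vector of spike times (s)
#' @export
if_spike_times <- function(np, T_total, rate_scale = 1) {
  isi <- if_interspike_interval(np)
  if (!is.finite(isi) || T_total <= 0) return(numeric(0))
  t <- seq(isi, T_total, by = isi)
  t <- t[t < T_total]
  if (rate_scale < 1) {
    keep <- max(1L, round(1 / rate_scale))
    t <- t[seq_along(t) %% keep == 0]
  }
  t
}

# resolve the spike times a protocol implies (empty for clamp protocols)
protocol_spikes <- function(proto, np) {
  switch(proto$kind,
         ip3_clamp_piecewise_constant = numeric(0),
         spike_driven = if_spike_times(np, proto$T_total, proto$rate_scale),
         spike_file = proto$spike_times,
         stop("unknown protocol kind: ", proto$kind))
}

# piecewise-constant clamp level at arbitrary times
clamp_level_at <- function(proto, t) {
  seg <- proto$segments
  edges <- c(0, cumsum(seg$duration))
  idx <- findInterval(t, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > nrow(seg)] <- nrow(seg)
  seg$level[idx]
}
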