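#' Root-mean-square error between two equal-length series
#'
#' @param ref,test numeric vectors of equal length (>= 2)
#' @return RMSE in the units of the series
#' @export
rmse <- function(ref, test) {
  if (length(ref) != length(test)) stop("series lengths differ")
  if (length(ref) < 2) stop("need at least 2 samples")
  sqrt(mean((ref - test)^2))
}

#' Range-normalized RMSE
#'
#' RMSE divided by the range (max - min) of the *reference* series, making
#' errors comparable across variables of different magnitude.
#'
#' @inheritParams rmse
#' @return dimensionless NRMSE
#' @export
nrmse <- function(ref, test) {
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("zero range: reference series is constant")
  rmse(ref, test) / rng
}

report_vars <- c("V", "AG", "IP3", "J_pump", "m_inf3", "n_inf3", "h", "Ca")

#' Reference-versus-digital comparison report
#'
#' Aligns the two traces on their shared timestamps and reports RMSE and
#' NRMSE for each of the eight signals of the datapath (V, AG, IP3,
#' J_pump, m_inf^3, n_inf^3, h, Ca). With `window_policy = "ten_cycles"`
#' the evaluation window runs from t = 0 to the tenth reference calcium
#' peak -- the point where accumulated error has settled -- falling back to
#' the full record (with a warning) when fewer than ten cycles exist.
#' NRMSE entries are `NA` for signals whose reference is constant over the
#' window (e.g. the clamped IP3 waveform).
#'
#' @param ref,dig reference and digital `astro_trace`s with the same `dt`
#' @param window_policy `"ten_cycles"`, `"full"`, or `"explicit"`
#' @param window `c(t0, t1)` when `window_policy = "explicit"`
#' @param prominence peak prominence used to locate cycles (uM)
#' @return a `comparison_report`: data frame (`variable`, `rmse`, `nrmse`)
#'   with window/design metadata in attributes
#' @export
compare_traces <- function(ref, dig,
                           window_policy = c("ten_cycles", "full", "explicit"),
                           window = NULL, prominence = 0.05) {
  window_policy <- match.arg(window_policy)
  if (!isTRUE(all.equal(attr(ref, "dt"), attr(dig, "dt"))))
    stop("traces have different sampling steps")
  pr <- attr(ref, "protocol"); pd <- attr(dig, "protocol")
  if (!is.null(pr) && !is.null(pd) && !identical(pr$kind, pd$kind))
    stop("traces come from different protocols")
  shared <- intersect(round(ref$t / attr(ref, "dt")),
                      round(dig$t / attr(dig, "dt")))
  r <- ref[match(shared, round(ref$t / attr(ref, "dt"))), , drop = FALSE]
  d <- dig[match(shared, round(dig$t / attr(dig, "dt"))), , drop = FALSE]

  if (window_policy == "ten_cycles") {
    pk <- detect_peaks(as_trace(r, attr(ref, "dt")), burn_in = 0,
                       prominence = prominence)
    if (nrow(pk) >= 10) {
      window <- c(min(r$t), pk$time[10])
    } else {
      warning("fewer than 10 reference calcium peaks: using the full window")
      window_policy <- "full"
    }
  }
  if (window_policy == "full") window <- range(r$t)
  if (is.null(window)) stop("explicit window_policy needs a window")
  keep <- r$t >= window[1] & r$t <= window[2]
  r <- r[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]

  tab <- data.frame(variable = report_vars,
                    rmse = NA_real_, nrmse = NA_real_)
  for (i in seq_along(report_vars)) {
    v <- report_vars[i]
    tab$rmse[i] <- rmse(r[[v]], d[[v]])
    rng <- max(r[[v]]) - min(r[[v]])
    tab$nrmse[i] <- if (rng > 0) tab$rmse[i] / rng else NA_real_
  }
  structure(tab, window = window, window_policy = window_policy,
            n = sum(keep), dt = attr(ref, "dt"),
            protocol_kind = if (!is.null(pr)) pr$kind else NA_character_,
            designs = attr(dig, "designs"),
            class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Reference vs digital over [%g, %g] s (%s, %d samples):\n",
              w[1], w[2], attr(x, "window_policy"), attr(x, "n")))
  print.data.frame(transform(as.data.frame(x),
                             rmse = signif(rmse, 4), nrmse = signif(nrmse, 4)),
                   row.names = FALSE)
  invisible(x)
}

report_to_list <- function(rep) {
  des <- attr(rep, "designs")
  list(window = attr(rep, "window"), window_policy = attr(rep, "window_policy"),
       n = attr(rep, "n"), dt = attr(rep, "dt"),
       protocol = attr(rep, "protocol_kind"),
       design = if (!is.null(des)) list(
         dt = des$dt, pwl_tol = des$pwl_tol,
         pwl_segments = vapply(des$pwl, function(p) length(p$slopes), 1L),
         scm_max_terms = des$scm_max_terms) else NULL,
       metrics = setNames(
         lapply(seq_len(nrow(rep)),
                function(i) list(rmse = rep$rmse[i], nrmse = rep$nrmse[i])),
         rep$variable))
}
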