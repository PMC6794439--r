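#' Time-series traces
#'
#' Both simulation pipelines return an `astro_trace`: a data frame with one
#' row per sample and columns `t`, `V`, `AG`, `IP3`, `Ca`, `h`, the derived
#' fluxes `J_chan`, `J_leak`, `J_pump` (uM/s) and the cubed gating signals
#' `m_inf3`, `n_inf3`. Attributes carry the sampling step `dt`, the pipeline
#' kind (`"reference"` or `"digital"`), parameter and protocol snapshots,
#' and, for digital traces, the saturation-event count.
#'
#' @param df data frame with at least `t`, `V`, `AG`, `IP3`, `Ca`, `h`
#' @param dt sampling step (s)
#' @param kind `"reference"` or `"digital"`
#' @param np,ap,proto parameter and protocol snapshots
#' @return an `astro_trace`
#' @export
as_trace <- function(df, dt, kind = "reference", np = NULL, ap = NULL,
                     proto = NULL) {
  need <- c("t", "V", "AG", "IP3", "Ca", "h")
  if (!all(need %in% names(df)))
    stop("trace needs columns: ", paste(need, collapse = ", "))
  structure(df, dt = dt, kind = kind, neuron = np, astro = ap,
            protocol = proto, class = c("astro_trace", "data.frame"))
}

# derive fluxes/gating columns from the state series and finalize
finish_trace <- function(df, dt, kind, np, ap, proto) {
  g <- gating_steady_states(df$IP3, pmax(df$Ca, 0), ap)
  drive <- ap$c0 - (1 + ap$c1) * df$Ca
  h <- pmin(pmax(df$h, 0), 1)
  df$J_chan <- ap$r_C * g$m_inf^3 * g$n_inf^3 * h^3 * drive
  df$J_leak <- ap$r_L * drive
  df$J_pump <- ap$v_ER * df$Ca^2 / (ap$k_ER^2 + df$Ca^2)
  df$m_inf3 <- g$m_inf^3
  df$n_inf3 <- g$n_inf^3
  as_trace(df, dt, kind, np, ap, proto)
}

empty_trace <- function(dt, kind, np, ap, proto) {
  df <- data.frame(t = numeric(0), V = numeric(0), AG = numeric(0),
                   IP3 = numeric(0), Ca = numeric(0), h = numeric(0),
                   J_chan = numeric(0), J_leak = numeric(0),
                   J_pump = numeric(0), m_inf3 = numeric(0),
                   n_inf3 = numeric(0))
  as_trace(df, dt, kind, np, ap, proto)
}

# convert a core output matrix (cpp_run_euler / dequantized digital) to a trace
matrix_to_trace <- function(m, t_out, dt, kind, np, ap, proto) {
  df <- data.frame(t = t_out, V = m[, "V"], AG = m[, "AG"], IP3 = m[, "IP3"],
                   Ca = m[, "Ca"], h = m[, "h"], J_chan = m[, "J_chan"],
                   J_leak = m[, "J_leak"], J_pump = m[, "J_pump"],
                   m_inf3 = m[, "m_inf3"], n_inf3 = m[, "n_inf3"])
  as_trace(df, dt, kind, np, ap, proto)
}

#' @export
print.astro_trace <- function(x, ...) {
  cat(sprintf("<astro_trace: %s> %d samples, dt = %g s, duration %g s\n",
              attr(x, "kind"), nrow(x), attr(x, "dt"),
              if (nrow(x)) max(x$t) else 0))
  sat <- attr(x, "saturations")
  if (!is.null(sat)) cat(sprintf("  saturation events: %g\n", sat))
  if (nrow(x)) {
    cat(sprintf("  Ca range [%.4f, %.4f] uM, IP3 range [%.4f, %.4f] uM\n",
                min(x$Ca), max(x$Ca), min(x$IP3), max(x$IP3)))
  }
  invisible(x)
}

#' Write / read a trace as CSV
#'
#' Column layout: `t,V,AG,IP3,Ca,h,J_chan,J_leak,J_pump,m_inf3,n_inf3`
#' (SI seconds and uM), plus a `saturations` column on digital traces.
#'
#' @param trace an `astro_trace`
#' @param path output file
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  sat <- attr(trace, "saturations")
  if (!is.null(sat)) df$saturations <- sat
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param dt sampling step; inferred from the time column when omitted
#' @export
read_trace <- function(path, dt = NULL) {
  df <- read.csv(path)
  sat <- if ("saturations" %in% names(df)) df$saturations[1] else NULL
  df$saturations <- NULL
  if (is.null(dt)) dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  tr <- as_trace(df, dt, kind = if (is.null(sat)) "reference" else "digital")
  attr(tr, "saturations") <- sat
  tr
}
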