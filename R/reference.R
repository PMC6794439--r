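#' IP3 receptor inactivation affinity Q2
#'
#' `Q2 = d2 (IP3 + d1) / (IP3 + d3)`, the calcium affinity of the slow
#' inactivation gate as a function of IP3.
#'
#' @param ip3 IP3 concentration (uM), vectorized
#' @param p an `astro_params` object
#' @return Q2 (uM)
#' @export
#' @examples
#' compute_q2(0.16, astro_params())  # 0.27570
compute_q2 <- function(ip3, p) {
  if (any(ip3 < 0)) stop("ip3 must be non-negative")
  p$d2 * (ip3 + p$d1) / (ip3 + p$d3)
}

#' Channel gating steady states and h time constant
#'
#' `m_inf = IP3/(IP3+d1)` (IP3-induced release), `n_inf = Ca/(Ca+d5)`
#' (calcium-induced release), `h_inf = Q2/(Q2+Ca)` and
#' `tau_h = 1/(a2 (Q2+Ca))` for the slow inactivation gate.
#'
#' @param ip3,ca concentrations (uM), vectorized
#' @param p an `astro_params` object
#' @return list with components `m_inf`, `n_inf`, `h_inf`, `tau_h`
#' @export
gating_steady_states <- function(ip3, ca, p) {
  if (any(ip3 < 0) || any(ca < 0)) stop("ip3 and ca must be non-negative")
  q2 <- compute_q2(ip3, p)
  list(m_inf = ip3 / (ip3 + p$d1),
       n_inf = ca / (ca + p$d5),
       h_inf = q2 / (q2 + ca),
       tau_h = 1 / (p$a2 * (q2 + ca)))
}

#' ER calcium fluxes
#'
#' CICR channel flux `J_chan = r_C m_inf^3 n_inf^3 h^3 (c0 - (1+c1) Ca)`,
#' leak `J_leak = r_L (c0 - (1+c1) Ca)`, and SERCA pump
#' `J_pump = v_ER Ca^2/(k_ER^2 + Ca^2)`.
#'
#' @param ca cytosolic calcium (uM)
#' @param h inactivation gate fraction in `[0, 1]`
#' @param ip3 IP3 concentration (uM)
#' @param p an `astro_params` object
#' @return list with components `J_chan`, `J_leak`, `J_pump` (uM/s)
#' @export
compute_fluxes <- function(ca, h, ip3, p) {
  if (any(ca < 0) || any(ip3 < 0) || any(h < 0)) stop("inputs must be non-negative")
  if (any(h > 1)) stop("h must not exceed 1")
  g <- gating_steady_states(ip3, ca, p)
  drive <- p$c0 - (1 + p$c1) * ca
  list(J_chan = p$r_C * g$m_inf^3 * g$n_inf^3 * h^3 * drive,
       J_leak = p$r_L * drive,
       J_pump = p$v_ER * ca^2 / (p$k_ER^2 + ca^2))
}

#' Time derivatives of the astrocyte state
#'
#' Continuous part of the dynamics: 2-AG decay (spike impulses are applied
#' by the integrator), gatekeeper IP3 production `r_ip3 * AG` with
#' first-order decay to baseline, calcium balance of the three ER fluxes,
#' and first-order relaxation of the inactivation gate.
#'
#' @param s named list or vector with `AG`, `IP3`, `Ca`, `h`
#' @param p an `astro_params` object
#' @param ag_input_rate additional continuous 2-AG input rate (uM/s)
#' @return named numeric vector of derivatives `(dAG, dIP3, dCa, dh)`
#' @export
astro_derivatives <- function(s, p, ag_input_rate = 0) {
  s <- as.list(s)
  g <- gating_steady_states(s$IP3, s$Ca, p)
  fl <- compute_fluxes(s$Ca, min(max(s$h, 0), 1), s$IP3, p)
  c(dAG = -s$AG / p$tau_AG + ag_input_rate,
    dIP3 = (p$IP3_star - s$IP3) / p$tau_ip3 + p$r_ip3 * s$AG,
    dCa = fl$J_chan + fl$J_leak - fl$J_pump,
    dh = (g$h_inf - s$h) / g$tau_h)
}

#' One forward-Euler step of the IF membrane equation
#'
#' Integrates `tau_m dV/dt = -V + R_m I_syn` for one step; if the updated
#' voltage reaches `V_th` it is reset to `V_reset` and a spike is flagged.
#'
#' @param V membrane voltage
#' @param p a `neuron_params` object
#' @param dt step (s); must be positive and well below `tau_m`
#' @return list with `V` (post-step voltage) and `spiked` (logical)
#' @export
neuron_step <- function(V, p, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (dt >= p$tau_m) warning("dt >= tau_m: Euler step is unstable")
  if (V >= p$V_th) return(list(V = p$V_reset, spiked = TRUE))
  V2 <- V + dt / p$tau_m * (-V + p$R_m * p$I_syn)
  if (V2 >= p$V_th) list(V = p$V_reset, spiked = TRUE)
  else list(V = V2, spiked = FALSE)
}

# analytic IF voltage at sample times given (unthinned) spike times
if_voltage_series <- function(t, np, spike_times) {
  drive <- np$R_m * np$I_syn
  last_reset <- rep(0, length(t))
  if (length(spike_times)) {
    idx <- findInterval(t, spike_times)
    last_reset[idx > 0] <- spike_times[idx[idx > 0]]
  }
  v <- drive + (np$V_reset - drive) * exp(-(t - last_reset) / np$tau_m)
  pmin(v, np$V_th)
}

#' Simulate the reference (double-precision) model
#'
#' Runs the stimulation protocol through the continuous model. Under an IP3
#' clamp only `(Ca, h)` are integrated and the IP3 series is the clamp
#' waveform; under spike drive the full chain (IF spikes -> 2-AG -> IP3 ->
#' Ca/h) runs, with each spike adding `r_AG` to the 2-AG pool. The default
#' integrator is adaptive (`deSolve::lsoda`, restarted at clamp edges, with
#' spike impulses as events); `method = "euler"` uses fixed-step forward
#' Euler at `dt_out`, the discretization-matched oracle for the digital
#' emulator.
#'
#' @param proto an `astro_protocol`
#' @param np a `neuron_params` object
#' @param ap an `astro_params` object
#' @param dt_out output sampling step (s)
#' @param method `"adaptive"` or `"euler"`
#' @param rtol,atol adaptive-solver tolerances
#' @return an `astro_trace` data frame (see [as_trace()])
#' @export
simulate_reference <- function(proto, np = neuron_params(), ap = astro_params(),
                               dt_out = 1e-3, method = c("adaptive", "euler"),
                               rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  if (dt_out <= 0) stop("dt_out must be > 0")
  n_steps <- round(proto$T_total / dt_out)
  if (n_steps == 0) return(empty_trace(dt_out, "reference", np, ap, proto))
  t_out <- seq(0, by = dt_out, length.out = n_steps + 1)
  clamp_mode <- proto$kind == "ip3_clamp_piecewise_constant"
  spikes <- protocol_spikes(proto, np)
  spikes <- round(spikes / dt_out) * dt_out  # align impulses to the grid

  if (method == "euler") {
    init <- c(V = 0, AG = ap$AG0, IP3 = ap$IP30, Ca = ap$Ca0, h = ap$h0)
    clamp_vals <- if (clamp_mode) clamp_level_at(proto, t_out) else numeric(1)
    if (clamp_mode) init["IP3"] <- clamp_vals[1]
    flags <- integer(n_steps)
    if (length(spikes)) flags[pmin(pmax(round(spikes / dt_out), 1), n_steps)] <- 1L
    pars <- c(list(tau_m = np$tau_m, RmIsyn = np$R_m * np$I_syn,
                   V_th = np$V_th, V_reset = np$V_reset), unclass(ap))
    m <- cpp_run_euler(n_steps, 1L, if (clamp_mode) 0L else 1L, dt_out,
                       clamp_vals, flags, init, pars)
    return(matrix_to_trace(m, t_out, dt_out, "reference", np, ap, proto))
  }

  if (clamp_mode) {
    rhs <- function(t, y, parms) {
      g <- gating_steady_states(parms$ip3, y[1], ap)
      fl <- compute_fluxes(y[1], min(max(y[2], 0), 1), parms$ip3, ap)
      list(c(fl$J_chan + fl$J_leak - fl$J_pump, (g$h_inf - y[2]) / g$tau_h))
    }
    y <- c(Ca = ap$Ca0, h = ap$h0)
    edges <- c(0, cumsum(proto$segments$duration))
    rows <- vector("list", nrow(proto$segments))
    for (k in seq_len(nrow(proto$segments))) {
      tt <- t_out[t_out >= edges[k] - dt_out / 2 & t_out <= edges[k + 1] + dt_out / 2]
      sol <- deSolve::lsoda(y, tt, rhs, list(ip3 = proto$segments$level[k]),
                            rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("reference solver failed near t = %g s", tail(sol[, 1], 1)))
      y <- c(Ca = unname(sol[nrow(sol), "Ca"]), h = unname(sol[nrow(sol), "h"]))
      rows[[k]] <- if (k < nrow(proto$segments)) sol[-nrow(sol), , drop = FALSE] else sol
    }
    sol <- do.call(rbind, rows)
    ip3 <- clamp_level_at(proto, sol[, "time"])
    df <- data.frame(t = sol[, "time"], V = 0, AG = 0, IP3 = ip3,
                     Ca = sol[, "Ca"], h = sol[, "h"])
  } else {
    rhs <- function(t, y, parms) list(unname(astro_derivatives(
      list(AG = y[1], IP3 = y[2], Ca = y[3], h = y[4]), ap)))
    y <- c(AG = ap$AG0, IP3 = ap$IP30, Ca = ap$Ca0, h = ap$h0)
    ev <- NULL
    if (length(spikes))
      ev <- list(data = data.frame(var = "AG", time = spikes,
                                   value = ap$r_AG, method = "add"))
    sol <- deSolve::lsoda(y, t_out, rhs, NULL, rtol = rtol, atol = atol,
                          events = ev)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("reference solver failed near t = %g s", tail(sol[, 1], 1)))
    v_spikes <- if (proto$kind == "spike_driven")
      if_spike_times(np, proto$T_total) else spikes
    df <- data.frame(t = sol[, "time"],
                     V = if (proto$kind == "spike_driven")
                       if_voltage_series(sol[, "time"], np, v_spikes) else 0,
                     AG = sol[, "AG"], IP3 = sol[, "IP3"],
                     Ca = sol[, "Ca"], h = sol[, "h"])
  }
  finish_trace(df, dt_out, "reference", np, ap, proto)
}
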