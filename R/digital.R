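#' Build the digital approximation designs
#'
#' Produces everything the fixed-point emulator needs: piecewise-linear
#' tables for the four non-affine scalar factors of the dynamics --
#' `m_inf(IP3)`, `n_inf(Ca)`, the SERCA Hill curve `Ca^2/(k_ER^2+Ca^2)` and
#' `Q2(IP3)` -- and shift-add plans for every constant multiplication
#' (decay factors folded with the Euler step, pump/leak/CICR rates, and the
#' step itself). Cubes (`m^3`, `n^3`, `h^3`) and variable-by-variable
#' products are full fixed-point multiplies, so no PWL of the cubed
#' functions is needed; `strategy = "cubed"` linearizes `m_inf^3` /
#' `n_inf^3` directly instead. The h-gate update uses the exact algebraic
#' form `dh = dt a2 (Q2 - h (Q2 + Ca))`, which removes the two-input
#' `h_inf` from the datapath.
#'
#' @param np a `neuron_params` object
#' @param ap an `astro_params` object
#' @param dt Euler step of the digital circuit (s)
#' @param pwl_tol certified max-abs-error budget per PWL table
#' @param ip3_domain,ca_domain input ranges covered by the tables (uM)
#' @param scm_max_terms term budget per shift-add plan
#' @param cube `"after-pwl"` (default: PWL the Hill factor, cube by
#'   multiplies) or `"of-cubed"` (PWL the cubed gating functions)
#' @return an object of class `digital_designs`
#' @export
build_designs <- function(np = neuron_params(), ap = astro_params(),
                          dt = 1e-3, pwl_tol = 1e-4,
                          ip3_domain = c(0, 2), ca_domain = c(0, 1.7),
                          scm_max_terms = 12,
                          cube = c("after-pwl", "of-cubed")) {
  cube <- match.arg(cube)
  mf <- if (cube == "after-pwl") function(x) x / (x + ap$d1)
        else function(x) (x / (x + ap$d1))^3
  nf <- if (cube == "after-pwl") function(x) x / (x + ap$d5)
        else function(x) (x / (x + ap$d5))^3
  pwl <- list(
    m_inf = build_pwl_tol(mf, ip3_domain, pwl_tol,
                          name = if (cube == "after-pwl") "m_inf" else "m_inf3"),
    n_inf = build_pwl_tol(nf, ca_domain, pwl_tol,
                          name = if (cube == "after-pwl") "n_inf" else "n_inf3"),
    hill2 = build_pwl_tol(function(x) x^2 / (ap$k_ER^2 + x^2), ca_domain,
                          pwl_tol, name = "hill2"),
    q2 = build_pwl_tol(function(x) compute_q2(x, ap), ip3_domain, pwl_tol,
                       name = "q2"))
  # Rates folded with the Euler step (e.g. dt/tau_AG = 1e-4) fall so far
  # below one that the 19-bit shift cap leaves ~1% relative error; they are
  # realized as two cascaded shift-add stages, each well-conditioned under
  # the cap. The step multiplies first so the intermediate shrinks before
  # any rate constant above one (e.g. 1/tau_m = 10) can saturate it.
  cascade <- function(c1, c2) {
    p <- scm_decompose(c1, scm_max_terms)
    p$then <- scm_decompose(c2, scm_max_terms)
    p
  }
  scm <- list(
    dt_tau_m   = cascade(dt, 1 / np$tau_m),
    dt_tau_ag  = cascade(dt, 1 / ap$tau_AG),
    dt_tau_ip3 = cascade(dt, 1 / ap$tau_ip3),
    dt_rip3    = cascade(dt, ap$r_ip3),
    dt_a2      = cascade(dt, ap$a2),
    vER        = scm_decompose(ap$v_ER,   scm_max_terms),
    rC         = scm_decompose(ap$r_C,    scm_max_terms),
    rL         = scm_decompose(ap$r_L,    scm_max_terms),
    one_c1     = scm_decompose(1 + ap$c1, scm_max_terms),
    dt         = scm_decompose(dt,        scm_max_terms))
  structure(list(pwl = pwl, scm = scm, dt = dt, cube = cube,
                 pwl_tol = pwl_tol, scm_max_terms = scm_max_terms,
                 neuron = np, astro = ap),
            class = "digital_designs")
}

#' @export
print.digital_designs <- function(x, ...) {
  cat(sprintf("Digital designs (dt = %g s, PWL tol %g, cube %s):\n",
              x$dt, x$pwl_tol, x$cube))
  for (pf in x$pwl)
    cat(sprintf("  PWL %-6s %3d segments, max |err| = %.2e\n",
                pf$name, length(pf$slopes), pf$max_abs_err))
  for (nm in names(x$scm)) {
    p <- x$scm[[nm]]
    eff_target <- p$target
    eff_real <- p$realized
    nterms <- length(p$signs)
    stages <- 1L
    if (!is.null(p$then)) {
      eff_target <- p$target * p$then$target
      eff_real <- p$realized * p$then$realized
      nterms <- nterms + length(p$then$signs)
      stages <- 2L
    }
    cat(sprintf("  SCM %-10s target %-12g %2d terms/%d stage%s, |err| = %.2e\n",
                nm, eff_target, nterms, stages, if (stages > 1) "s" else "",
                abs(eff_target - eff_real)))
  }
  invisible(x)
}

pwl_raw_table <- function(pf) {
  list(bp_raw = cpp_quantize(pf$breakpoints),
       slope_raw = cpp_quantize(pf$slopes),
       intercept_raw = cpp_quantize(pf$intercepts))
}

scm_raw_plan <- function(plan) {
  out <- list(signs = as.integer(plan$signs),
              shifts = as.integer(plan$shifts),
              signs2 = integer(0), shifts2 = integer(0))
  if (!is.null(plan$then)) {
    out$signs2 <- as.integer(plan$then$signs)
    out$shifts2 <- as.integer(plan$then$shifts)
  }
  out
}

#' Run the Q4.34 digital emulator
#'
#' Bit-exact emulation of the fixed-point circuit: every state variable and
#' intermediate lives in the global Q4.34 format, constants act through
#' their shift-add plans, nonlinear factors through the PWL tables, and the
#' state advances by forward Euler in the scheduling order of the datapath
#' (IF voltage, 2-AG, IP3, h gate, gating signals and fluxes, Ca).
#' Saturation events are counted and reported, never fatal; a run in which
#' more than 1% of steps saturate triggers a prominent warning.
#'
#' @param proto an `astro_protocol`
#' @param np,ap parameter objects (must match the ones the designs were
#'   built for)
#' @param designs a `digital_designs` object; built on the fly when `NULL`
#' @param dt_out output sampling step (s), a multiple of the design step
#' @param raw if `TRUE`, return the raw-integer output matrix (for
#'   bit-exact regression) instead of a trace
#' @return an `astro_trace` with a `saturations` attribute, or the raw
#'   matrix when `raw = TRUE`
#' @export
run_digital <- function(proto, np = neuron_params(), ap = astro_params(),
                        designs = NULL, dt_out = NULL, raw = FALSE) {
  if (is.null(designs)) designs <- build_designs(np, ap)
  dt <- designs$dt
  if (is.null(dt_out)) dt_out <- dt
  out_every <- round(dt_out / dt)
  if (abs(out_every * dt - dt_out) > 1e-12 || out_every < 1)
    stop("dt_out must be a positive multiple of the design dt")
  n_steps <- round(proto$T_total / dt)
  if (n_steps == 0) {
    tr <- empty_trace(dt_out, "digital", np, ap, proto)
    attr(tr, "saturations") <- 0
    return(tr)
  }
  clamp_mode <- proto$kind == "ip3_clamp_piecewise_constant"
  t_steps <- seq(0, by = dt, length.out = n_steps + 1)
  clamp_raw <- numeric(1)
  flags <- integer(n_steps)
  if (clamp_mode) {
    clamp_raw <- cpp_quantize(clamp_level_at(proto, t_steps))
  } else {
    spikes <- protocol_spikes(proto, np)
    if (length(spikes)) flags[pmin(pmax(round(spikes / dt), 1), n_steps)] <- 1L
  }
  init <- c(V = 0, AG = ap$AG0, IP3 = ap$IP30, Ca = ap$Ca0, h = ap$h0)
  init_raw <- cpp_quantize(init)
  names(init_raw) <- names(init)
  if (clamp_mode) init_raw["IP3"] <- clamp_raw[1]
  consts_raw <- lapply(list(RmIsyn = np$R_m * np$I_syn, Vth = np$V_th,
                            Vreset = np$V_reset, rAG = ap$r_AG,
                            IP3star = ap$IP3_star, c0 = ap$c0),
                       function(v) cpp_quantize(v))
  res <- cpp_run_digital(n_steps, as.integer(out_every),
                         if (clamp_mode) 0L else 1L,
                         clamp_raw, flags, init_raw, consts_raw,
                         lapply(designs$scm, scm_raw_plan),
                         lapply(designs$pwl, pwl_raw_table),
                         if (designs$cube == "after-pwl") 1L else 0L)
  if (raw) return(res)
  m <- res$out / 2^34
  colnames(m) <- colnames(res$out)
  t_out <- seq(0, by = dt_out, length.out = nrow(m))
  tr <- matrix_to_trace(m, t_out, dt_out, "digital", np, ap, proto)
  attr(tr, "saturations") <- res$saturations
  attr(tr, "designs") <- designs
  if (res$saturations > 0.01 * n_steps)
    warning(sprintf(
      "digital run saturated %g times over %d steps (>1%%): results suspect",
      res$saturations, n_steps))
  tr
}
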