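#' Integrate-and-fire neuron parameters
#'
#' Constructs the parameter set of the leaky integrate-and-fire neuron
#' `tau_m dV/dt = -V + R_m I_syn` with threshold reset to `V_reset`.
#' Defaults are the model's published operating point.
#'
#' @param tau_m membrane time constant (s)
#' @param R_m membrane resistance (model units)
#' @param I_syn synaptic input current (model units)
#' @param V_th firing threshold (model units)
#' @param V_reset post-spike reset voltage (model units)
#' @return an object of class `neuron_params`
#' @export
#' @examples
#' np <- neuron_params()
#' if_interspike_interval(np)  # ~0.0223 s
neuron_params <- function(tau_m = 0.1, R_m = 2.5, I_syn = 2,
                          V_th = 1, V_reset = 0) {
  p <- list(tau_m = tau_m, R_m = R_m, I_syn = I_syn,
            V_th = V_th, V_reset = V_reset)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all neuron parameters must be finite scalars")
  if (tau_m <= 0) stop("tau_m must be > 0")
  if (V_th <= V_reset) stop("V_th must exceed V_reset")
  structure(p, class = "neuron_params")
}

#' Astrocyte calcium-dynamics parameters
#'
#' Constructs the full constant set of the 2-AG / IP3 / calcium model:
#' 2-AG release and decay, gatekeeper IP3 production, and Li-Rinzel-type
#' ER calcium exchange (CICR channel, leak, SERCA pump). Defaults are the
#' published values; `r_C`, which the published table omits, defaults to
#' the standard CICR rate of 6 per second.
#'
#' @param tau_AG 2-AG decay time constant (s)
#' @param r_AG 2-AG increment per presynaptic spike (uM)
#' @param IP3_star baseline IP3 concentration (uM)
#' @param tau_ip3 IP3 decay time constant (s)
#' @param r_ip3 IP3 production rate per unit 2-AG (1/s)
#' @param a2 IP3 receptor inactivation rate constant (1/(uM s))
#' @param d1,d2,d3,d5 IP3 receptor dissociation constants (uM)
#' @param c0 total free calcium concentration (uM)
#' @param c1 ER/cytosol volume ratio (dimensionless)
#' @param r_L ER leak rate (1/s)
#' @param r_C maximal CICR rate (1/s)
#' @param v_ER maximal SERCA pump rate (uM/s)
#' @param k_ER SERCA pump activation constant (uM)
#' @param Ca0,h0,IP30,AG0 initial conditions (uM, -, uM, uM)
#' @return an object of class `astro_params`
#' @export
astro_params <- function(tau_AG = 10, r_AG = 0.018, IP3_star = 0.16,
                         tau_ip3 = 7, r_ip3 = 0.5, a2 = 0.2,
                         d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.108,
                         c0 = 2, c1 = 0.185, r_L = 0.11, r_C = 6,
                         v_ER = 0.8, k_ER = 0.1,
                         Ca0 = 0.071006, h0 = 0.7791,
                         IP30 = 0.16, AG0 = 0) {
  p <- list(tau_AG = tau_AG, r_AG = r_AG, IP3_star = IP3_star,
            tau_ip3 = tau_ip3, r_ip3 = r_ip3, a2 = a2,
            d1 = d1, d2 = d2, d3 = d3, d5 = d5,
            c0 = c0, c1 = c1, r_L = r_L, r_C = r_C,
            v_ER = v_ER, k_ER = k_ER,
            Ca0 = Ca0, h0 = h0, IP30 = IP30, AG0 = AG0)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all astrocyte parameters must be finite scalars")
  pos <- c("tau_AG", "r_AG", "tau_ip3", "a2", "d1", "d2", "d3", "d5",
           "c0", "c1", "r_L", "r_C", "v_ER", "k_ER")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) stop("parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (h0 < 0 || h0 > 1) stop("h0 must lie in [0, 1]")
  if (Ca0 < 0 || IP30 < 0 || AG0 < 0)
    stop("initial concentrations must be non-negative")
  structure(p, class = "astro_params")
}

#' Named astrocyte parameter presets
#'
#' The modulation-mode presets override the leak rate `r_L` and the SERCA
#' activation constant `k_ER`: `"am"` (r_L = 0.014, k_ER = 0.1),
#' `"fm"` (r_L = 0.11, k_ER = 0.064), `"afm"` (r_L = 0.07, k_ER = 0.1);
#' `"base"` is the unmodified parameter set.
#'
#' @param name one of `"base"`, `"am"`, `"fm"`, `"afm"`
#' @param ... further overrides passed to [astro_params()]
#' @return an `astro_params` object
#' @export
astro_preset <- function(name = c("base", "am", "fm", "afm"), ...) {
  name <- match.arg(name)
  over <- switch(name,
                 base = list(),
                 am  = list(r_L = 0.014, k_ER = 0.1),
                 fm  = list(r_L = 0.11,  k_ER = 0.064),
                 afm = list(r_L = 0.07,  k_ER = 0.1))
  do.call(astro_params, modifyList(over, list(...)))
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("IF neuron parameters:\n")
  cat(sprintf("  tau_m=%g s  R_m=%g  I_syn=%g  V_th=%g  V_reset=%g\n",
              x$tau_m, x$R_m, x$I_syn, x$V_th, x$V_reset))
  invisible(x)
}

#' @export
print.astro_params <- function(x, ...) {
  cat("Astrocyte parameters (uM, s):\n")
  nm <- setdiff(names(x), c("Ca0", "h0", "IP30", "AG0"))
  cat(" ", paste(sprintf("%s=%g", nm, unlist(x[nm])), collapse = "  "), "\n")
  cat(sprintf("  init: Ca=%g h=%g IP3=%g AG=%g\n", x$Ca0, x$h0, x$IP30, x$AG0))
  invisible(x)
}

#' Closed-form inter-spike interval of the IF neuron
#'
#' For constant drive the linear membrane equation has an exact solution;
#' the interval between threshold crossings is
#' `tau_m * log(R_m I_syn / (R_m I_syn - V_th))`.
#'
#' @param np a `neuron_params` object
#' @return interval in seconds, or `Inf` when the drive never reaches
#'   threshold
#' @export
if_interspike_interval <- function(np) {
  drive <- np$R_m * np$I_syn
  if (drive <= np$V_th) return(Inf)
  np$tau_m * log((drive - np$V_reset) / (drive - np$V_th))
}
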