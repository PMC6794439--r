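#' Shift-add (single constant multiplication) decomposition
#'
#' Approximates a real constant as a signed sum of powers of two,
#' `sum(sign * 2^(-shift))`, so that multiplication by the constant becomes
#' a chain of shifts and adds. Shifts are bounded by `max_shift` right
#' shifts (the hardware datapath limit) and `-min_int_bits` left shifts for
#' constants above one. A greedy signed-digit search picks, at each step,
#' the power of two nearest the residual; with an unconstrained term budget
#' the residual falls below `2^-20`.
#'
#' @param target the real constant, `|target| < 16`
#' @param max_terms term budget
#' @param max_shift largest allowed right shift (default 19)
#' @param min_int_bits largest allowed left shift (integer headroom)
#' @return an object of class `scm_plan` with fields `target`, `signs`,
#'   `shifts`, `realized`, `abs_err`
#' @export
#' @examples
#' scm_decompose(0.75)  # shifts 1 and 2, exact
scm_decompose <- function(target, max_terms = 12, max_shift = 19,
                          min_int_bits = 4) {
  if (!is.finite(target)) stop("target must be finite")
  if (abs(target) >= 16) stop("|target| must be < 16 (Q4.34 integer range)")
  # shifts ordered largest-first so distance ties resolve toward the
  # smaller power of two (0.75 -> 2^-1 + 2^-2 rather than 2^0 - 2^-2)
  shifts_all <- seq(max_shift, -min_int_bits)
  pow <- 2^(-shifts_all)
  signs <- integer(0); shifts <- integer(0)
  r <- target
  while (length(signs) < max_terms && abs(r) > 2^-21) {
    k <- which.min(abs(abs(r) - pow))
    if (abs(r) < pow[k] / 2) break  # residual below finest useful term
    signs <- c(signs, if (r > 0) 1L else -1L)
    shifts <- c(shifts, shifts_all[k])
    r <- r - tail(signs, 1) * pow[k]
  }
  realized <- if (length(signs)) sum(signs * 2^(-shifts)) else 0
  structure(list(target = target, signs = signs, shifts = shifts,
                 realized = realized, abs_err = abs(target - realized)),
            class = "scm_plan")
}

#' @export
print.scm_plan <- function(x, ...) {
  terms <- if (length(x$signs))
    paste(sprintf("%s2^%d", ifelse(x$signs > 0, "+", "-"), -x$shifts),
          collapse = " ")
  else "0"
  cat(sprintf("SCM %g ~ %s = %.10g (|err| = %.3g, %d terms)\n",
              x$target, terms, x$realized, x$abs_err, length(x$signs)))
  invisible(x)
}

scm_to_list <- function(plan) {
  out <- list(target = plan$target,
              terms = Map(function(s, sh) list(sign = if (s > 0) "+" else "-",
                                               shift = sh),
                          plan$signs, plan$shifts),
              realized = plan$realized, abs_err = plan$abs_err)
  if (!is.null(plan$then)) out$then <- scm_to_list(plan$then)
  out
}
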