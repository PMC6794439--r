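#' Signed Q4.34 fixed-point format and values
#'
#' The digital datapath stores every signal in a single two's-complement
#' format: 1 sign bit, 4 integer bits, 34 fractional bits (39 bits total),
#' resolution `2^-34`, range `[-16, 16 - 2^-34]`. Out-of-range results
#' saturate; they never wrap. `fixed_value` objects hold the raw integers
#' (scaled by `2^34`) as doubles, which is exact.
#'
#' @return `fixed_format()` returns a descriptor list; `quantize()` a
#'   `fixed_value`; `dequantize()` a numeric vector.
#' @export
fixed_format <- function() {
  structure(list(sign_bits = 1L, int_bits = 4L, frac_bits = 34L, total = 39L,
                 resolution = 2^-34, range = c(-16, 16 - 2^-34)),
            class = "fixed_format")
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf("Q%d.%d fixed point: %d bits, resolution 2^-%d, range [%g, %g]\n",
              x$int_bits, x$frac_bits, x$total, x$frac_bits,
              x$range[1], x$range[2]))
  invisible(x)
}

new_fixed <- function(raw) structure(list(raw = raw, fmt = fixed_format()),
                                     class = "fixed_value")

#' @rdname fixed_format
#' @param x numeric vector (for `quantize`) or `fixed_value` (for
#'   `dequantize`)
#' @details Quantization rounds to nearest, ties to even; values beyond the
#'   representable range saturate to the nearest bound; `NaN` is an error.
#' @export
quantize <- function(x) {
  if (any(is.nan(x))) stop("cannot quantize NaN")
  new_fixed(cpp_quantize(as.numeric(x)))
}

#' @rdname fixed_format
#' @export
dequantize <- function(x) x$raw / 2^34

#' Saturating fixed-point arithmetic
#'
#' Exact integer operations on raw Q4.34 values with saturation at the
#' format bounds. `fx_mul` is the full 39x39-bit product with the low 34
#' bits truncated toward minus infinity (an arithmetic right shift, as a
#' hardware multiplier would). `fx_scm_mul` multiplies by a constant via
#' its shift-add plan: a signed sum of arithmetically shifted copies of the
#' operand.
#'
#' @param a,b `fixed_value` objects of equal length (or length 1)
#' @param plan an `scm_plan` from [scm_decompose()]
#' @return a `fixed_value`
#' @export
fx_add <- function(a, b) new_fixed(cpp_fx_add(a$raw, recycle_raw(b, a)))

#' @rdname fx_add
#' @export
fx_sub <- function(a, b) new_fixed(cpp_fx_sub(a$raw, recycle_raw(b, a)))

#' @rdname fx_add
#' @export
fx_mul <- function(a, b) new_fixed(cpp_fx_mul(a$raw, recycle_raw(b, a)))

#' @rdname fx_add
#' @export
fx_scm_mul <- function(a, plan) {
  if (!length(plan$signs)) return(new_fixed(rep(0, length(a$raw))))
  new_fixed(cpp_fx_scm(a$raw, as.integer(plan$signs), as.integer(plan$shifts)))
}

recycle_raw <- function(b, a) {
  if (length(b$raw) == length(a$raw)) b$raw
  else rep_len(b$raw, length(a$raw))
}

#' @export
print.fixed_value <- function(x, ...) {
  v <- dequantize(x)
  cat(sprintf("Q4.34 fixed value[%d]: %s\n", length(v),
              paste(utils::head(signif(v, 10), 8), collapse = ", ")))
  invisible(x)
}
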