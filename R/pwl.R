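#' Piecewise-linear approximation of a scalar function
#'
#' Builds a continuous piecewise-linear interpolant of `f` on `domain` with
#' `n_segments` segments and certifies its maximum absolute error on a dense
#' grid (at least 1000 points per segment). Two breakpoint strategies:
#' `"uniform"` spaces breakpoints evenly; `"minimax-greedy"` repeatedly
#' splits the currently worst segment at its point of maximum error, which
#' concentrates breakpoints where `f` curves.
#'
#' @param f vectorized scalar function, finite on `domain`
#' @param domain numeric `c(lo, hi)`, `lo < hi`
#' @param n_segments number of linear segments (>= 1)
#' @param strategy `"uniform"` or `"minimax-greedy"`
#' @param name identifier stored in the design table
#' @return an object of class `pwl_function` with fields `name`, `domain`,
#'   `breakpoints`, `values`, `slopes`, `intercepts`, `max_abs_err`
#' @export
#' @examples
#' pf <- build_pwl(function(x) x / (x + 0.13), c(0, 2), 32)
#' pf$max_abs_err
build_pwl <- function(f, domain, n_segments,
                      strategy = c("minimax-greedy", "uniform"),
                      name = deparse(substitute(f))) {
  strategy <- match.arg(strategy)
  lo <- domain[1]; hi <- domain[2]
  if (!(lo < hi)) stop("domain must satisfy lo < hi")
  if (n_segments < 1) stop("n_segments must be >= 1")
  probe <- f(seq(lo, hi, length.out = 257))
  if (!all(is.finite(probe))) stop("f must be finite on the domain")

  if (strategy == "uniform") {
    bp <- seq(lo, hi, length.out = n_segments + 1)
  } else {
    bp <- c(lo, hi)
    while (length(bp) - 1 < n_segments) {
      worst <- c(err = -1, x = NA)
      for (k in seq_len(length(bp) - 1)) {
        xs <- seq(bp[k], bp[k + 1], length.out = 128)
        fs <- f(xs)
        ls <- fs[1] + (fs[128] - fs[1]) * (xs - xs[1]) / (xs[128] - xs[1])
        e <- abs(fs - ls)
        j <- which.max(e)
        if (e[j] > worst["err"]) worst <- c(err = e[j], x = xs[j])
      }
      x_new <- worst["x"]
      if (x_new %in% bp)  # flat segment: fall back to bisecting the widest
        x_new <- mean(bp[which.max(diff(bp)) + 0:1])
      bp <- sort(c(bp, unname(x_new)))
    }
  }
  vals <- f(bp)
  slopes <- diff(vals) / diff(bp)
  intercepts <- vals[-length(vals)] - slopes * bp[-length(bp)]

  pf <- structure(list(name = name, domain = c(lo, hi), breakpoints = bp,
                       values = vals, slopes = slopes,
                       intercepts = intercepts, max_abs_err = NA_real_,
                       strategy = strategy),
                  class = "pwl_function")
  grid <- seq(lo, hi, length.out = max(1000 * n_segments, 2000))
  pf$max_abs_err <- max(abs(f(grid) - eval_pwl(pf, grid)))
  pf
}

#' Evaluate a piecewise-linear function
#'
#' Locates the segment by binary search (`findInterval`); inputs outside the
#' domain are clamped to the nearest endpoint (no extrapolation).
#'
#' @param pf a `pwl_function`
#' @param x numeric vector of inputs
#' @return approximated function values
#' @export
eval_pwl <- function(pf, x) {
  x <- pmin(pmax(x, pf$domain[1]), pf$domain[2])
  k <- findInterval(x, pf$breakpoints, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(pf$slopes))
  pf$slopes[k] * x + pf$intercepts[k]
}

#' Refine a PWL design until a certified error bound holds
#'
#' Doubles the segment count (from `n_start`) until `max_abs_err <= tol`.
#'
#' @inheritParams build_pwl
#' @param tol target maximum absolute error
#' @param n_start initial segment count
#' @param n_max refusal point (error if the bound is not reached)
#' @return a `pwl_function`
#' @export
build_pwl_tol <- function(f, domain, tol, strategy = "minimax-greedy",
                          name = "f", n_start = 8, n_max = 4096) {
  n <- n_start
  repeat {
    pf <- build_pwl(f, domain, n, strategy = strategy, name = name)
    if (pf$max_abs_err <= tol) return(pf)
    if (n >= n_max) stop(sprintf("PWL '%s': error %.3g > tol %.3g at %d segments",
                                 name, pf$max_abs_err, tol, n))
    n <- n * 2
  }
}

#' @export
print.pwl_function <- function(x, ...) {
  cat(sprintf("PWL <%s> on [%g, %g]: %d segments (%s), max |err| = %.3g\n",
              x$name, x$domain[1], x$domain[2], length(x$slopes),
              x$strategy, x$max_abs_err))
  invisible(x)
}

pwl_to_list <- function(pf) {
  list(name = pf$name, domain = pf$domain, breakpoints = pf$breakpoints,
       slopes = pf$slopes, intercepts = pf$intercepts,
       max_abs_err = pf$max_abs_err)
}
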