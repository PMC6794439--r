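# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive shift-add search: best |c - sum(sign * 2^-shift)| over all
# combinations of at most `max_terms` signed power-of-two terms with shifts
# in [-4, 19]. Small enough to enumerate outright for <= 3 terms.
scm_bruteforce_err <- function(c, max_terms, max_shift = 19, min_shift = -4) {
  pows <- c(0, 2^(-(min_shift:max_shift)), -2^(-(min_shift:max_shift)))
  vals <- 0
  for (k in seq_len(max_terms)) vals <- unique(as.vector(outer(vals, pows, "+")))
  min(abs(c - vals))
}

# Exact floor((a*b) / 2^34) for integer-valued doubles |a|,|b| < 2^39,
# via base-2^13 limb arithmetic (pure R, no 64-bit types).
mul_floor34 <- function(a, b) {
  sa <- sign(a) * sign(b)
  A <- abs(a); B <- abs(b)
  limbs <- function(x) {
    out <- numeric(4)
    for (i in 1:4) { out[i] <- x %% 2^13; x <- x %/% 2^13 }
    out
  }
  la <- limbs(A); lb <- limbs(B)
  p <- numeric(8)
  for (i in 1:4) for (j in 1:4)
    p[i + j - 1] <- p[i + j - 1] + la[i] * lb[j]
  for (i in 1:7) { carry <- p[i] %/% 2^13; p[i] <- p[i] %% 2^13; p[i + 1] <- p[i + 1] + carry }
  # p = sum p[i] * 2^(13*(i-1)); split at bit 34 = 2*13 + 8
  L <- p[1] + p[2] * 2^13 + (p[3] %% 2^8) * 2^26
  H <- p[3] %/% 2^8 + p[4] * 2^5 + p[5] * 2^18 + p[6] * 2^31 + p[7] * 2^44 +
    p[8] * 2^57
  if (sa >= 0) H else -(H + (L > 0))
}

RAW_MAX <- 2^38 - 1
RAW_MIN <- -2^38
sat_oracle <- function(v) pmin(pmax(v, RAW_MIN), RAW_MAX)
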