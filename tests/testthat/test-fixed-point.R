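test_that("quantization round-trips representable values and saturates the rest", {
  q <- quantize(0.5)
  expect_equal(q$raw, 2^33)
  expect_equal(dequantize(q), 0.5)
  expect_equal(dequantize(quantize(20)), 16 - 2^-34)
  expect_equal(dequantize(quantize(-20)), -16)
  expect_equal(dequantize(quantize(2^-35)), 0)  # below resolution, ties-to-even
  expect_error(quantize(NaN), "NaN")
  # round-trip error bounded by half an ulp for in-range values
  set.seed(7)
  x <- runif(1000, -15, 15)
  expect_true(all(abs(dequantize(quantize(x)) - x) <= 2^-35))
})

test_that("addition and subtraction are exact with saturation at the bounds", {
  a <- quantize(0.25); b <- quantize(0.125)
  expect_equal(dequantize(fx_add(a, b)), 0.375)
  expect_equal(dequantize(fx_sub(a, b)), 0.125)
  expect_equal(dequantize(fx_add(a, quantize(0))), 0.25)  # identity
  expect_equal(dequantize(fx_add(quantize(15), quantize(15))), 16 - 2^-34)
  expect_equal(dequantize(fx_sub(quantize(-15), quantize(15))), -16)
})

test_that("shift-add constant multiplies reproduce exact dyadic products", {
  expect_equal(dequantize(fx_scm_mul(quantize(1), scm_decompose(0.5))), 0.5)
  expect_equal(dequantize(fx_scm_mul(quantize(2), scm_decompose(0.75))), 1.5)
  plan <- scm_decompose(0.018, max_terms = 8)
  got <- dequantize(fx_scm_mul(quantize(1), plan))
  expect_lt(abs(got - 0.018), plan$abs_err + length(plan$signs) * 2^-34)
})

test_that("fixed ops agree with exact limb-arithmetic on random operand pairs", {
  set.seed(1234)
  n <- 10000
  ra <- floor(runif(n, -2^37, 2^37))
  rb <- floor(runif(n, -2^37, 2^37))
  a <- astromod:::new_fixed(ra); b <- astromod:::new_fixed(rb)
  expect_identical(fx_add(a, b)$raw, sat_oracle(ra + rb))
  expect_identical(fx_sub(a, b)$raw, sat_oracle(ra - rb))
  got <- fx_mul(a, b)$raw
  idx <- sample(n, 300)  # limb oracle is O(1) but slow in R; spot-check deeply
  want <- vapply(idx, function(i) sat_oracle(mul_floor34(ra[i], rb[i])), 1)
  expect_identical(got[idx], want)
  # cheap full-vector cross-check against double arithmetic within 1 ulp
  approx <- pmin(pmax(floor(ra * rb / 2^34), -2^38), 2^38 - 1)
  expect_true(all(abs(got - approx) <= 2))
})

test_that("scm application equals the sum of arithmetically shifted copies", {
  set.seed(99)
  ra <- floor(runif(200, -2^37, 2^37))
  plan <- scm_decompose(0.9434, max_terms = 6)
  got <- fx_scm_mul(astromod:::new_fixed(ra), plan)$raw
  want <- rep(0, length(ra))
  for (k in seq_along(plan$signs)) {
    s <- plan$shifts[k]
    term <- if (s >= 0) floor(ra / 2^s) else ra * 2^(-s)
    want <- sat_oracle(want + plan$signs[k] * term)
  }
  expect_identical(got, want)
})
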