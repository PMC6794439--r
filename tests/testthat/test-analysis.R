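make_sine_trace <- function(freq = 0.05, amp = 0.3, T = 400, dt = 0.1,
                            base = 0.3) {
  t <- seq(0, T, dt)
  df <- data.frame(t = t, V = 0, AG = 0, IP3 = 0.5,
                   Ca = base + amp * sin(2 * pi * freq * t), h = 0.7)
  as_trace(df, dt)
}

test_that("peak detection recovers a constructed sinusoid's peaks and period", {
  tr <- make_sine_trace()
  pk <- detect_peaks(tr, burn_in = 100, prominence = 0.05)
  expect_identical(nrow(pk), 15L)  # 0.05 Hz over (100, 400] -> 15 maxima
  expect_equal(mean(diff(pk$time)), 20, tolerance = 0.1 / 20)
  # first peak is measured against the window-start value (the mid-line),
  # later peaks against the true trough one half-cycle earlier
  expect_equal(pk$amplitude[1], 0.3, tolerance = 1e-3)
  expect_equal(pk$amplitude[-1], rep(0.6, 14), tolerance = 1e-3)
})

test_that("constant and sub-prominence series yield no peaks", {
  flat <- make_sine_trace(amp = 0)
  expect_identical(nrow(detect_peaks(flat)), 0L)
  ripple <- make_sine_trace(amp = 0.01)
  expect_identical(nrow(detect_peaks(ripple, prominence = 0.05)), 0L)
  empty <- make_sine_trace(T = 50)
  expect_identical(nrow(detect_peaks(empty, burn_in = 100)), 0L)
})

test_that("oscillation stats pool windows without bridging intervals across them", {
  tr <- make_sine_trace()
  s <- oscillation_stats(tr, list(c(100, 200), c(300, 400)))
  expect_identical(s$n_peaks, 10L)
  expect_length(s$inter_peak_intervals, 8)  # 4 per window, none across the gap
  expect_equal(s$mean_frequency, 0.05, tolerance = 0.01)
  # each window's first peak measures 0.3 from the window-start mid-line,
  # the other four the full 0.6 swing: mean (2*0.3 + 8*0.6)/10
  expect_equal(s$mean_amplitude, 0.54, tolerance = 5e-3)
})

test_that("the modulation classifier separates AM, FM, AFM and none", {
  st <- function(A, f) {
    tr <- make_sine_trace(freq = f, amp = A / 2, T = 300)
    oscillation_stats(tr, c(50, 300))
  }
  expect_identical(classify_modulation(st(0.4, 0.05), st(0.6, 0.051))$mode, "AM")
  expect_identical(classify_modulation(st(0.4, 0.05), st(0.41, 0.08))$mode, "FM")
  expect_identical(classify_modulation(st(0.4, 0.05), st(0.6, 0.08))$mode, "AFM")
  expect_identical(classify_modulation(st(0.4, 0.05), st(0.41, 0.051))$mode, "none")
  # non-oscillatory input is 'none' with a diagnostic
  mc <- classify_modulation(st(0.01, 0.05), st(0.6, 0.05))
  expect_identical(mc$mode, "none")
  expect_match(mc$diagnostic, "non-oscillatory")
})

test_that("the AFM preset is called AFM from the step protocol on the reference", {
  b <- preset_bundle("fig9_afm")
  expect_identical(b$mode$reference$mode, "AFM")
  expect_gt(b$mode$reference$amplitude_change, 0.15)
  expect_gt(b$mode$reference$frequency_change, 0.15)
  # amplitude and frequency both rise with the level
  lv <- b$mode$reference$per_level
  expect_gt(lv[["0.6"]]$mean_amplitude, lv[["0.4"]]$mean_amplitude)
  expect_gt(lv[["0.6"]]$mean_frequency, lv[["0.4"]]$mean_frequency)
})

test_that("phase-plane extraction validates its pair and collapses at a fixed point", {
  tr_osc <- clamp_trace(0.625)
  tr_steady <- clamp_trace(0.125)
  expect_error(phase_plane(tr_osc, c("Ca", "V")), "pair must be one of")
  pp_osc <- phase_plane(tr_osc, c("Ca", "h"))
  pp_st <- phase_plane(tr_steady, c("Ca", "h"))
  diag_len <- function(pp) sqrt(sum(apply(pp, 2, function(c) diff(range(c)))^2))
  expect_lt(diag_len(pp_st), 0.01 * diag_len(pp_osc))
  # oscillatory trajectory closes on itself: first and last cycles overlap
  pk <- detect_peaks(tr_osc)
  first_cycle <- tr_osc$t >= pk$time[1] & tr_osc$t <= pk$time[2]
  last_cycle <- tr_osc$t >= pk$time[nrow(pk) - 1] & tr_osc$t <= pk$time[nrow(pk)]
  hd <- hausdorff_distance(tr_osc[first_cycle, c("Ca", "h")],
                           tr_osc[last_cycle, c("Ca", "h")])
  expect_lt(hd, 0.05 * diag_len(pp_osc))
})

test_that("channel flux axis is identically zero when the h gate is forced shut", {
  tr <- clamp_trace(0.625)
  df <- as.data.frame(tr)
  df$h <- 0
  ap <- astro_params()
  tr0 <- astromod:::finish_trace(df[, c("t", "V", "AG", "IP3", "Ca", "h")],
                                 attr(tr, "dt"), "reference", NULL, ap, NULL)
  pp <- phase_plane(tr0, c("Ca", "J_chan"))
  expect_true(all(pp$J_chan == 0))
})
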