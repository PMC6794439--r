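np <- neuron_params()
ap <- astro_params()

test_that("the emulator is bit-exact deterministic", {
  proto <- protocol_clamp(0.625, 20)
  des <- build_designs(np, ap)
  r1 <- run_digital(proto, np, ap, designs = des, raw = TRUE)
  r2 <- run_digital(proto, np, ap, designs = des, raw = TRUE)
  expect_identical(r1$out, r2$out)
  expect_identical(r1$saturations, r2$saturations)
})

test_that("a zero-duration protocol yields an empty trace without error", {
  tr <- run_digital(protocol_spike_times(numeric(0), T_total = 0), np, ap,
                    designs = build_designs(np, ap))
  expect_s3_class(tr, "astro_trace")
  expect_identical(nrow(tr), 0L)
})

test_that("quiescent baseline holds: IP3 stays put within a couple of ulp", {
  # no spikes, IP3 starting at its production/decay balance point
  des <- build_designs(np, ap)
  proto <- protocol_spike_times(numeric(0), T_total = 0.05)
  raw <- run_digital(proto, np, ap, designs = des, raw = TRUE)
  ip3 <- raw$out[, "IP3"]
  expect_lte(max(abs(ip3 - ip3[1])), 2 * length(ip3))  # <=2 ulp drift per step
  ag <- raw$out[, "AG"]
  expect_true(all(ag == 0))
})

test_that("a protocol spike deposits the quantized 2-AG increment", {
  des <- build_designs(np, ap)
  proto <- protocol_spike_times(0.010, T_total = 0.05)
  tr <- run_digital(proto, np, ap, designs = des)
  expect_equal(max(tr$AG), ap$r_AG, tolerance = 1e-5)
  # decay over the following 20 ms is tiny but strictly monotone
  after <- tr$AG[tr$t > 0.011]
  expect_true(all(diff(after) <= 0))
})

test_that("the digital IF neuron fires near the closed-form rate", {
  des <- build_designs(np, ap)
  raw <- run_digital(protocol_spike_driven(2, rate_scale = 1), np, ap,
                     designs = des, raw = TRUE)
  n_spikes <- sum(raw$out[, "spike"])
  expect_equal(n_spikes, 2 / if_interspike_interval(np), tolerance = 0.05)
})

test_that("digital matches double-precision Euler at the same step (approximation error only)", {
  proto <- protocol_clamp(c(0.4, 0.6), c(75, 75))
  ap_fm <- astro_preset("fm")
  des <- build_designs(np, ap_fm)
  dig <- run_digital(proto, np, ap_fm, designs = des)
  ref <- simulate_reference(proto, np, ap_fm, dt_out = 1e-3, method = "euler")
  expect_lt(nrmse(ref$Ca, dig$Ca), 0.02)
  expect_lt(nrmse(ref$h, dig$h), 0.02)
})

test_that("halving the Euler step changes the digital calcium trace by under 2% NRMSE", {
  proto <- protocol_clamp(c(0.4, 0.6, 0.4), c(150, 200, 150))
  ap_fm <- astro_preset("fm")
  d1 <- run_digital(proto, np, ap_fm,
                    designs = build_designs(np, ap_fm, dt = 1e-3),
                    dt_out = 1e-3)
  d2 <- run_digital(proto, np, ap_fm,
                    designs = build_designs(np, ap_fm, dt = 5e-4),
                    dt_out = 1e-3)
  expect_lt(nrmse(d2$Ca, d1$Ca), 0.02)
})

test_that("saturation events are counted and a heavy-saturation run warns", {
  # a pathological parameter set drives the datapath into its rails
  ap_bad <- astro_params(r_C = 15, v_ER = 15, c0 = 14)
  des <- suppressWarnings(build_designs(np, ap_bad))
  expect_warning(run_digital(protocol_clamp(2, 5), np, ap_bad, designs = des),
                 "saturated")
})

test_that("linearizing the cubed gating curves directly is an equivalent design choice", {
  proto <- protocol_clamp(0.625, 120)
  d_after <- run_digital(proto, np, ap,
                         designs = build_designs(np, ap, cube = "after-pwl"))
  d_cubed <- run_digital(proto, np, ap,
                         designs = build_designs(np, ap, cube = "of-cubed"))
  expect_lt(nrmse(d_after$Ca, d_cubed$Ca), 0.02)
})
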