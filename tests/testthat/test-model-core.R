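ap <- astro_params()
np <- neuron_params()

test_that("Q2 matches direct evaluation of the rational form", {
  expect_equal(compute_q2(0.16, ap), 0.27570, tolerance = 1e-4 / 0.2757)
  expect_equal(compute_q2(0, ap), ap$d2 * ap$d1 / ap$d3, tolerance = 1e-12)
  expect_equal(compute_q2(0, ap), 0.14455, tolerance = 1e-4 / 0.1445)
  expect_equal(compute_q2(1e9, ap), ap$d2, tolerance = 1e-6)
  # monotone increasing in IP3 since d3 > d1
  x <- seq(0, 2, 0.01)
  expect_true(all(diff(compute_q2(x, ap)) > 0))
  expect_error(compute_q2(-0.1, ap), "non-negative")
})

test_that("gating steady states hit their half-saturation points", {
  g <- gating_steady_states(ap$d1, 0.05, ap)
  expect_equal(g$m_inf, 0.5)
  g <- gating_steady_states(0.3, ap$d5, ap)
  expect_equal(g$n_inf, 0.5)
  q2 <- compute_q2(0.3, ap)
  g <- gating_steady_states(0.3, q2, ap)
  expect_equal(g$h_inf, 0.5)
  expect_equal(g$tau_h, 1 / (ap$a2 * 2 * q2))
  # all gates bounded in [0, 1], tau_h positive
  for (ip3 in c(0, 0.2, 1, 2)) for (ca in c(0, 0.1, 1, 1.7)) {
    g <- gating_steady_states(ip3, ca, ap)
    expect_true(all(unlist(g[c("m_inf", "n_inf", "h_inf")]) >= 0))
    expect_true(all(unlist(g[c("m_inf", "n_inf", "h_inf")]) <= 1))
    expect_gt(g$tau_h, 0)
  }
  expect_error(gating_steady_states(-1, 0, ap), "non-negative")
})

test_that("fluxes follow the Hill and driving-term structure", {
  fl <- compute_fluxes(ap$k_ER, 0.5, 0.3, ap)
  expect_equal(fl$J_pump, ap$v_ER / 2)
  expect_equal(fl$J_pump, 0.4)
  # driving term vanishes at Ca = c0/(1+c1)
  ca_eq <- ap$c0 / (1 + ap$c1)
  fl <- compute_fluxes(ca_eq, 0.5, 0.3, ap)
  expect_equal(fl$J_leak, 0)
  expect_equal(fl$J_chan, 0)
  # closed h gate shuts the channel regardless of drive
  fl <- compute_fluxes(0.3, 0, 1.5, ap)
  expect_equal(fl$J_chan, 0)
  expect_lt(compute_fluxes(10 * ap$k_ER, 1, 0.3, ap)$J_pump, ap$v_ER)
})

test_that("derivatives vanish at the baseline and gate fixed points", {
  d <- astro_derivatives(list(AG = 0, IP3 = ap$IP3_star, Ca = 0.1, h = 0.8), ap)
  expect_equal(unname(d["dAG"]), 0)
  expect_equal(unname(d["dIP3"]), 0)
  g <- gating_steady_states(0.3, 0.2, ap)
  d <- astro_derivatives(list(AG = 0.01, IP3 = 0.3, Ca = 0.2, h = g$h_inf), ap)
  expect_equal(unname(d["dh"]), 0)
})

test_that("a single spike loads r_AG into the 2-AG pool which then decays exponentially", {
  proto <- protocol_spike_times(10, T_total = 60)
  tr <- simulate_reference(proto, np, ap, dt_out = 0.01)
  # the impulse lands at t = 10; the first post-event sample (10.01 s) has
  # already decayed for one step
  expect_equal(max(tr$AG), ap$r_AG * exp(-0.01 / ap$tau_AG), tolerance = 1e-6)
  after <- tr[tr$t >= 10.01, ]
  expect_equal(after$AG, ap$r_AG * exp(-(after$t - 10) / ap$tau_AG),
               tolerance = 1e-5)
  # before the spike the pool is empty and IP3 sits at baseline
  before <- tr[tr$t < 10, ]
  expect_equal(max(abs(before$AG)), 0)
  expect_equal(before$IP3, rep(ap$IP3_star, nrow(before)), tolerance = 1e-7)
})

test_that("Euler-stepped IF neuron reproduces the closed-form inter-spike interval", {
  isi_exact <- if_interspike_interval(np)
  expect_equal(isi_exact, 0.1 * log(1.25), tolerance = 1e-12)
  dt <- 1e-4
  V <- 0; spikes <- numeric(0); t <- 0
  for (i in seq_len(round(1 / dt))) {
    st <- neuron_step(V, np, dt)
    V <- st$V; t <- t + dt
    if (st$spiked) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 30)
  expect_lt(max(abs(diff(spikes) - isi_exact)), 2 * dt)
  # no drive, no spikes
  expect_false(neuron_step(0, neuron_params(I_syn = 0), dt)$spiked)
  expect_equal(neuron_step(0, neuron_params(I_syn = 0), dt)$V, 0)
  # at threshold: immediate reset
  st <- neuron_step(np$V_th, np, dt)
  expect_true(st$spiked)
  expect_equal(st$V, np$V_reset)
  expect_warning(neuron_step(0, np, np$tau_m * 2), "unstable")
})

test_that("clamp traces respect positivity and gate bounds at all levels", {
  for (level in c(0.05, 0.5, 1.0, 2.0)) {
    tr <- simulate_reference(protocol_clamp(level, 200), np, ap, dt_out = 0.01)
    expect_true(all(tr$Ca > 0), label = sprintf("Ca > 0 at clamp %g", level))
    expect_true(all(tr$Ca <= ap$c0 / (1 + ap$c1) + 1e-9),
                label = sprintf("Ca below ER ceiling at clamp %g", level))
    expect_true(all(tr$h >= 0 & tr$h <= 1),
                label = sprintf("h in [0,1] at clamp %g", level))
  }
})

test_that("baseline clamp at IP3* is a fixed point for the bypassed variables", {
  tr <- simulate_reference(protocol_clamp(ap$IP3_star, 100), np, ap,
                           dt_out = 0.01)
  expect_equal(max(abs(tr$AG)), 0)
  expect_true(all(tr$IP3 == ap$IP3_star))
})

test_that("fixed-step Euler reference self-converges on refinement", {
  proto <- protocol_clamp(0.625, 150)
  a <- simulate_reference(proto, np, ap, dt_out = 1e-3, method = "euler")
  b <- simulate_reference(proto, np, ap, dt_out = 1e-4, method = "euler")
  b_sub <- b$Ca[seq(1, nrow(b), by = 10)]
  expect_lt(nrmse(b_sub, a$Ca), 0.01)
})

test_that("oscillation frequency grows with the clamp level in the FM regime", {
  ap_fm <- astro_preset("fm")
  lo <- clamp_trace(0.55, T = 400, ap = ap_fm)
  hi <- clamp_trace(0.8, T = 400, ap = ap_fm)
  s_lo <- oscillation_stats(lo, c(100, 400))
  s_hi <- oscillation_stats(hi, c(100, 400))
  expect_gt(s_hi$mean_frequency, s_lo$mean_frequency)
})

test_that("regime examples: low clamp steady, mid oscillatory, high damped", {
  expect_identical(classify_regime(clamp_trace(0.125)), "steady")
  expect_identical(classify_regime(clamp_trace(0.625)), "oscillatory")
  expect_identical(classify_regime(clamp_trace(1.2)), "damped")
  # damped run settles at an elevated level with tiny residual ripple
  tr <- clamp_trace(1.2)
  late <- tr$Ca[tr$t >= 400]
  expect_gt(mean(late), 0.4)
  expect_lt(diff(range(late)), 0.01 * diff(range(tr$Ca)))
})
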