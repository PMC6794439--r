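test_that("unknown presets are refused with the available list", {
  expect_error(run_experiment("fig7"), "available")
})

test_that("the staircase experiment classifies its five levels as the model predicts", {
  b <- preset_bundle("fig6")
  expect_equal(b$regimes$level, c(0.125, 0.4, 0.53125, 0.625, 1.2))
  expect_identical(b$regimes$regime,
                   c("steady", "oscillatory", "oscillatory", "oscillatory",
                     "damped"))
})

test_that("the spike-driven bundle carries a complete eight-variable report", {
  b <- preset_bundle("fig8")
  expect_setequal(b$report$variable,
                  c("V", "AG", "IP3", "J_pump", "m_inf3", "n_inf3", "h", "Ca"))
  expect_true(all(is.finite(b$report$rmse)))
  # the digital trace reached the oscillatory regime like the reference
  expect_identical(classify_regime(b$reference), "oscillatory")
  expect_identical(classify_regime(b$digital), "oscillatory")
})

test_that("experiment bundles serialize to a complete run directory", {
  b <- preset_bundle("fig9_afm")
  out <- withr::local_tempdir()
  astromod:::write_bundle(b, out)
  expect_true(all(file.exists(file.path(out,
    c("reference_trace.csv", "digital_trace.csv", "comparison.csv",
      "comparison.json", "designs.json", "modulation.json", "regimes.csv")))))
  # trace CSV round-trips
  tr <- read_trace(file.path(out, "digital_trace.csv"))
  expect_equal(tr$Ca, b$digital$Ca)
  expect_equal(attr(tr, "dt"), attr(b$digital, "dt"))
  js <- jsonlite::read_json(file.path(out, "comparison.json"))
  expect_named(js$metrics,
               c("V", "AG", "IP3", "J_pump", "m_inf3", "n_inf3", "h", "Ca"))
})

test_that("spike files and config files drive the same machinery", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# spikes", "1.0", "2.5", "4.0"), f)
  proto <- protocol_spike_file(f, T_total = 10)
  expect_equal(proto$spike_times, c(1, 2.5, 4))
  cfgf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    astrocyte = list(preset = "fm", r_C = 6),
    protocol = list(kind = "ip3_clamp_piecewise_constant",
                    levels = c(0.4, 0.6), durations = c(10, 10)),
    solver = list(dt_out = 0.01)), cfgf, auto_unbox = TRUE, digits = NA)
  cfg <- read_config(cfgf)
  expect_equal(cfg$astro$k_ER, 0.064)
  expect_equal(cfg$protocol$T_total, 20)
  expect_equal(cfg$solver$dt_out, 0.01)
})

test_that("protocol invariants are enforced", {
  expect_error(protocol_clamp(c(0.4, -0.1), 100), "levels")
  expect_error(protocol_clamp(0.4, -5), "durations")
  expect_error(protocol_spike_times(c(2, 1), 10), "increasing")
  expect_error(protocol_spike_times(c(1, 12), 10), "T_total")
})
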