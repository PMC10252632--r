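test_that("the progressive weighing schedule follows its interval plan", {
  expect_identical(make_schedule(20), c(0, 5, 10, 15, 20))
  long <- make_schedule(1250)
  expect_identical(long[1L], 0)
  expect_gte(max(long), 1250)
  steps <- diff(long)
  expect_true(all(steps > 0))
  expect_true(all(diff(steps) >= 0)) # intervals widen monotonically
  expect_true(all(steps %in% drying_schedule_plan()$interval_min))
  # a custom plan's intervals appear verbatim
  plan <- data.frame(interval_min = c(2, 7), duration_min = c(10, Inf))
  expect_true(all(diff(make_schedule(60, plan)) %in% c(2, 7)))
  expect_error(make_schedule(0), "positive")
  expect_error(make_schedule(10, data.frame()), "non-empty")
  expect_error(make_schedule(10, data.frame(interval_min = 5, duration_min = 60)),
               "open-ended")
})

test_that("zero-noise simulation inverts exactly to the generating curve", {
  p <- reference_model_params("smelling", 50, "midilli")
  cfg <- synthetic_config(thinlayer_generator("midilli", p), 50,
                          wb_to_db(91.88), 6.77, noise_sd_mr = 0, seed = 9)
  run <- simulate_run(cfg)
  expect_s3_class(run, "drying_run")
  expect_equal(series_from_run(run)$mr,
               eval_drying_model("midilli", p, run$times_min), tolerance = 1e-12)
  # the run ends close to equilibrium on the moisture-ratio scale
  expect_lt(abs(series_from_run(run)$mr[length(run$times_min)]), 0.05)
})

test_that("simulation is deterministic under a seed and independent across seeds", {
  p <- reference_model_params("pout", 60, "midilli")
  mk <- function(seed) {
    simulate_run(synthetic_config(thinlayer_generator("midilli", p), 60,
                                  wb_to_db(83.30), 5.29, seed = seed))
  }
  expect_identical(serialize(mk(4), NULL), serialize(mk(4), NULL))
  expect_false(identical(mk(4)$moisture_db, mk(5)$moisture_db))
})

test_that("the configured noise level is recovered from pooled residuals", {
  fs <- fixture_suite(1, noise_sd_mr = 0.01)
  res <- unlist(lapply(names(fs), function(nm) {
    parts <- strsplit(nm, "_")[[1L]]
    p <- reference_model_params(parts[1L], as.numeric(parts[2L]), "midilli")
    series_from_run(fs[[nm]])$mr - eval_drying_model("midilli", p, fs[[nm]]$times_min)
  }))
  expect_gte(length(res), 100L)
  expect_lt(abs(sd(res) - 0.01) / 0.01, 0.2)
})

test_that("the fixture suite mirrors the reference experimental design", {
  fs <- fixture_suite(0)
  expect_length(fs, 8L)
  expect_identical(
    names(fs),
    c("smelling_50", "smelling_60", "smelling_70", "smelling_80",
      "pout_50", "pout_60", "pout_70", "pout_80")
  )
  expect_identical(unname(vapply(fs, `[[`, numeric(1L), "temperature_c")),
                   rep(c(50, 60, 70, 80), 2))
  # initial moisture equals the reported in natura water content (wet basis)
  expect_equal(db_to_wb(fs$smelling_50$initial_moisture_db), 91.88, tolerance = 1e-10)
  expect_equal(db_to_wb(fs$pout_70$initial_moisture_db), 83.30, tolerance = 1e-10)
  # equilibrium moistures come from the reference drying summary
  expect_equal(fs$smelling_80$equilibrium_moisture_db, 4.70)
  expect_equal(fs$pout_50$equilibrium_moisture_db, 6.33)
  expect_true(all(vapply(fs, `[[`, numeric(1L), "half_thickness_m") == 0.005))
  # byte-identical reproducibility; different seeds differ
  expect_identical(serialize(fixture_suite(0), NULL), serialize(fs, NULL))
  expect_false(identical(fixture_suite(2)$pout_50$moisture_db, fs$pout_50$moisture_db))
})

test_that("the generating model is identified as best on its own noise-free data", {
  fs <- fixture_suite(0, noise_sd_mr = 0)
  for (nm in names(fs)) {
    ranked <- rank_model_fits(fit_all_models(series_from_run(fs[[nm]]), seed = 1))
    expect_identical(ranked[[1L]]$model_name, "midilli", label = nm)
  }
})

test_that("under noise the generating model stays within a whisker of the top rank", {
  # R2-based ranking can prefer the 6-parameter exponential sum on noisy data
  # (it absorbs noise); the generating Midilli curve must remain essentially
  # tied with the leader and fit its own data nearly perfectly.
  fs <- fixture_suite(0)
  for (nm in names(fs)) {
    fits <- fit_all_models(series_from_run(fs[[nm]]), seed = 1)
    ranked <- rank_model_fits(fits)
    expect_gt(fits$midilli$r2, 0.995, label = nm)
    expect_lt(ranked[[1L]]$r2 - fits$midilli$r2, 1e-3, label = nm)
  }
})

test_that("a generator that cannot reach equilibrium raises a runaway error", {
  cfg <- synthetic_config(slab_generator(1e-13, 0.05), 50, 90, 5,
                          noise_sd_mr = 0, stop_delta_db = 1e-6, seed = 1)
  expect_error(simulate_run(cfg), "equilibrium not reached")
})
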