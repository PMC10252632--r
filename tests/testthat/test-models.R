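test_that("the registry exposes exactly the ten models with their arities", {
  models <- drying_models()
  expect_length(models, 10L)
  arity <- vapply(models, function(m) length(m$param_names), integer(1L))
  expect_identical(arity[["newton"]], 1L)
  expect_identical(unname(arity[c("page", "henderson_pabis", "thompson")]),
                   c(2L, 2L, 2L))
  expect_identical(unname(arity[c("logarithmic", "logistic", "verma")]),
                   c(3L, 3L, 3L))
  expect_identical(unname(arity[c("midilli", "two_term")]), c(4L, 4L))
  expect_identical(arity[["henderson_pabis_modified"]], 6L)
  # bounds contain the default inits; evaluation at init is finite at t = 0
  for (m in models) {
    expect_true(all(m$init >= m$lower & m$init <= m$upper), label = m$name)
    expect_true(is.finite(eval_drying_model(m, m$init, 0)), label = m$name)
  }
  # case-insensitive lookup round-trips
  expect_identical(drying_model("MIDILLI")$name, "midilli")
  expect_identical(drying_model("Page")$name, "page")
  expect_error(drying_model("wang_singh"), "unknown drying model")
})

test_that("model evaluation reproduces reference values", {
  # Midilli at t = 0 equals its amplitude a
  expect_equal(eval_drying_model("midilli", c(0.9895, 0.0018, 1.3451, -0.00005), 0),
               0.9895)
  # exponential half-life of the Newton model
  expect_equal(eval_drying_model("newton", 0.0148, log(2) / 0.0148), 0.5,
               tolerance = 1e-12)
  # Midilli curve at t = 100 min with the pout 80 degC parameters
  expect_equal(
    eval_drying_model("midilli", c(0.9852, 0.0033, 1.3463, -0.000007), 100),
    0.19311, tolerance = 1e-4
  )
})

test_that("models agree on shared parameter subspaces", {
  t <- c(0, 2, 7.5, 30, 120, 600, 1500)
  for (k in c(0.002, 0.01, 0.15)) {
    newton <- eval_drying_model("newton", k, t)
    expect_equal(eval_drying_model("page", c(k, 1), t), newton, tolerance = 1e-14)
    expect_equal(eval_drying_model("henderson_pabis", c(1, k), t), newton,
                 tolerance = 1e-14)
  }
})

test_that("start-of-drying values follow the closed forms", {
  expect_equal(eval_drying_model("two_term", c(0.6, 0.02, 0.45, 0.003), 0), 1.05)
  # Verma's amplitudes sum to 1 by construction
  for (a in c(-14.6, -0.5, 0.3, 2)) {
    expect_equal(eval_drying_model("verma", c(a, 0.02, 0.005), 0), 1)
  }
  # Thompson starts at 1 whenever a < 0 (sqrt(a^2) = -a)
  for (a in c(-35.11, -4282.27, -8206.3)) {
    expect_equal(eval_drying_model("thompson", c(a, 5.39), 0), 1, tolerance = 1e-12)
  }
  expect_equal(eval_drying_model("logistic", c(0.1219, 0.1251, 0.0067), 0),
               0.1219 / 1.1251)
})

test_that("exponential-decay models are monotone non-increasing for positive rates", {
  t <- seq(0, 1000, by = 10)
  cases <- list(
    newton = 0.004,
    page = c(0.002, 1.3),
    henderson_pabis = c(1.02, 0.005),
    two_term = c(0.55, 0.01, 0.45, 0.002),
    henderson_pabis_modified = c(0.4, 0.02, 0.3, 0.005, 0.3, 0.001),
    midilli = c(0.99, 0.003, 1.1, 0)
  )
  for (nm in names(cases)) {
    y <- eval_drying_model(nm, cases[[nm]], t)
    expect_true(all(diff(y) <= 1e-14), label = nm)
  }
})

test_that("analytic Jacobians agree with central finite differences", {
  cases <- recovery_cases()
  t <- c(0, 5, 20, 90, 240, 600)
  for (case in cases) {
    for (m in names(drying_models())) {
      spec <- drying_model(m)
      p <- reference_model_params(case$variety, case$temperature_c, m)
      jac <- spec$jac(p, t)
      num <- vapply(seq_along(p), function(j) {
        h <- 1e-6 * max(abs(p[j]), 1e-3)
        hi <- replace(p, j, p[j] + h)
        lo <- replace(p, j, p[j] - h)
        (spec$fun(hi, t) - spec$fun(lo, t)) / (2 * h)
      }, numeric(length(t)))
      expect_equal(unname(jac), unname(num), tolerance = 1e-4,
                   label = paste(m, case$variety))
    }
  }
})

test_that("evaluation rejects invalid inputs", {
  expect_error(eval_drying_model("newton", c(0.1, 0.2), 0), "expects 1 parameters")
  expect_error(eval_drying_model("page", 0.1, 0), "expects 2 parameters")
  expect_error(eval_drying_model("newton", 0.1, -5), "non-negative")
  expect_error(eval_drying_model("thompson", c(-1, 0), 10), "nonzero")
  # negative discriminant: a^2 + 4bt < 0 with b < 0 at large t
  expect_error(eval_drying_model("thompson", c(-1, -1), 10), "discriminant")
})
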