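test_that("goodness-of-fit statistics match hand-computed values", {
  perfect <- goodness_of_fit(c(1, 0.6, 0.2), c(1, 0.6, 0.2), 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$msd, 0)
  expect_equal(perfect$chi2, 0)

  # worked 3-point example: SSres = 0.02, SStot = 0.5
  g <- goodness_of_fit(c(1, 0.5, 0), c(0.9, 0.5, 0.1), 2)
  expect_equal(g$r2, 0.96)
  expect_equal(g$msd, sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(g$chi2, 0.02, tolerance = 1e-12)

  expect_error(goodness_of_fit(c(1, 0), c(1, 0, 0), 1), "lengths differ")
  expect_error(goodness_of_fit(c(1, 0.5), c(1, 0.4), 2), "more observations")
  expect_error(goodness_of_fit(c(1, 1, 1), c(0.9, 1, 1), 1), "zero variance")
})

test_that("the chi-square / RMSD identity holds on random inputs", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      n_params <- sample(1:4, 1)
      y <- runif(n)
      pred <- y + rnorm(n, sd = 0.05)
      g <- goodness_of_fit(y, pred, n_params)
      expect_equal(g$chi2 * (n - n_params), n * g$msd^2, tolerance = 1e-10)
      expect_gte(g$msd, 0)
      expect_gte(g$chi2, 0)
    }
  })
})

test_that("fits recover generating parameters from noiseless data", {
  ts <- make_schedule(530)
  # Page round trip at the pout 80 degC parameters
  y <- eval_drying_model("page", c(0.0039, 1.3065), ts)
  f <- fit_drying_model(mr_series(ts, y), "page", seed = 11)
  expect_lt(max(abs(f$params - c(0.0039, 1.3065)) / c(0.0039, 1.3065)), 1e-4)
  expect_gte(f$r2, 1 - 1e-10)
  expect_true(f$converged)
  expect_equal(f$n_obs, length(ts))
  expect_equal(f$n_params, 2L)

  # model nesting: Newton data fitted with Page gives n ~ 1, k ~ k_newton
  y2 <- eval_drying_model("newton", 0.0071, ts)
  f2 <- fit_drying_model(mr_series(ts, y2), "page", seed = 11)
  expect_equal(unname(f2$params[["n"]]), 1, tolerance = 1e-6)
  expect_equal(unname(f2$params[["k"]]), 0.0071, tolerance = 1e-4)
})

test_that("constant series raise an error instead of a silent fit", {
  s <- mr_series(c(0, 5, 10, 15), rep(1, 4))
  expect_error(fit_drying_model(s, "newton"), "constant")
})

test_that("fit SSE is at least as good as a dense grid-search oracle", {
  ts <- make_schedule(400)
  withr::with_seed(3, {
    for (m in c("newton", "page")) {
      spec <- drying_model(m)
      truth <- if (m == "newton") 0.006 else c(0.004, 1.2)
      y <- eval_drying_model(m, truth, ts) + rnorm(length(ts), sd = 0.01)
      f <- fit_drying_model(mr_series(ts, y), m, seed = 5)
      oracle <- grid_search_sse(spec$fun, ts, y, spec$lower, spec$upper)
      expect_lte(f$sse, oracle + 1e-9)
    }
  })
})

test_that("canonicalization orders and merges interchangeable exponential terms", {
  canon <- drykin:::canonicalize_params
  # distinct rates: sorted by descending rate
  expect_equal(unname(canon("two_term", c(0.9538, 0.0065, 0.0453, 0.1071))),
               c(0.0453, 0.1071, 0.9538, 0.0065))
  # coincident rates: amplitude split equalized, curve preserved
  got <- canon("two_term", c(0.5428, 0.0035, 0.4583, 0.0035))
  expect_equal(unname(got), c(0.50055, 0.0035, 0.50055, 0.0035))
  # a zero-amplitude term joins the dominant cluster
  got3 <- canon("henderson_pabis_modified", c(1.059, 0.0152, 0, 0.055, 0, 0.9))
  expect_equal(unname(got3), c(1.059 / 3, 0.0152, 1.059 / 3, 0.0152, 1.059 / 3, 0.0152))
  # verma: term swap is undone by rate ordering
  expect_equal(unname(canon("verma", c(-2.8776, 0.0075, 0.0089))),
               c(1 - (-2.8776), 0.0089, 0.0075))
})

test_that("every registry model is recovered from data generated at reference parameters", {
  for (case in recovery_cases()) {
    ts <- make_schedule(case$total_min)
    for (m in names(drying_models())) {
      p <- reference_model_params(case$variety, case$temperature_c, m)
      y <- eval_drying_model(m, p, ts)
      f <- fit_drying_model(mr_series(ts, y), m, seed = 42)
      p_canon <- drykin:::canonicalize_params(m, p)
      tol <- if (m == "henderson_pabis_modified") 1e-2 else 1e-3
      expect_lt(max(abs(f$params - p_canon) / pmax(abs(p_canon), 1e-12)), tol,
                label = paste(m, case$variety, case$temperature_c))
    }
  }
})

test_that("moderate noise degrades but does not destroy the fit quality", {
  # curve shapes and sampling density of the reference experiment
  for (case in recovery_cases()) {
    ts <- make_schedule(case$total_min)
    p <- reference_model_params(case$variety, case$temperature_c, "midilli")
    truth <- eval_drying_model("midilli", p, ts)
    withr::with_seed(17, {
      y <- truth + rnorm(length(ts), sd = 0.01)
    })
    f <- fit_drying_model(mr_series(ts, y), "midilli", seed = 2)
    expect_lt(f$r2, 1)
    expect_gt(f$r2, 0.98)
  }
})

test_that("model ranking uses R2 with RMSD, chi-square and parsimony tie-breaks", {
  fake_fit <- function(name, n_params, r2, msd, chi2) {
    structure(list(model_name = name, params = numeric(n_params),
                   n_obs = 30L, n_params = as.integer(n_params), r2 = r2,
                   msd = msd, chi2 = chi2, sse = 30 * msd^2,
                   converged = TRUE, residuals = numeric(30)),
              class = "drying_fit")
  }
  fits <- list(
    fake_fit("midilli", 4, 0.9995, 0.0089, 0.0001),
    fake_fit("two_term", 4, 0.9912, 0.0356, 0.00165)
  )
  expect_identical(rank_model_fits(fits)[[1L]]$model_name, "midilli")

  # identical statistics: fewer parameters first
  tie <- list(
    fake_fit("two_term", 4, 0.999, 0.01, 0.001),
    fake_fit("page", 2, 0.999, 0.01, 0.001)
  )
  expect_identical(rank_model_fits(tie)[[1L]]$model_name, "page")

  single <- list(fake_fit("newton", 1, 0.98, 0.05, 0.003))
  expect_identical(rank_model_fits(single)[[1L]]$model_name, "newton")
  expect_error(rank_model_fits(list()), "no fits")

  not_conv <- single
  not_conv[[1L]]$converged <- FALSE
  expect_error(rank_model_fits(not_conv), "no converged")
})
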