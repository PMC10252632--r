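#' Goodness-of-fit statistics for a fitted drying curve
#'
#' Computes the three statistics conventionally reported for thin-layer
#' drying fits, all on the moisture-ratio scale:
#' * `r2`: coefficient of determination, `1 - SSres/SStot`;
#' * `msd`: root-mean-square deviation, `sqrt(mean((pred - exp)^2))`;
#' * `chi2`: reduced chi-square, `SSres / (n - N)` with `N` the number of
#'   model parameters.
#'
#' The identity `chi2 * (n - N) == n * msd^2` holds by construction.
#'
#' @param mr_exp Observed moisture ratios.
#' @param mr_pred Predicted moisture ratios, same length.
#' @param n_params Number of model parameters `N`; must be below the number
#'   of observations.
#' @return A list with elements `r2`, `msd`, `chi2`.
#' @export
goodness_of_fit <- function(mr_exp, mr_pred, n_params) {
  stopifnot(is.numeric(mr_exp), is.numeric(mr_pred), is.numeric(n_params))
  n <- length(mr_exp)
  if (length(mr_pred) != n) stop("mr_exp and mr_pred lengths differ", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (n <= n_params) stop("need more observations than parameters", call. = FALSE)
  if (!all(is.finite(mr_exp)) || !all(is.finite(mr_pred))) {
    stop("moisture ratios must be finite", call. = FALSE)
  }
  res <- mr_pred - mr_exp
  ss_res <- sum(res^2)
  ss_tot <- sum((mr_exp - mean(mr_exp))^2)
  if (ss_tot == 0) {
    if (ss_res > 0) {
      stop("statistic undefined: observations have zero variance", call. = FALSE)
    }
    r2 <- 1
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  list(r2 = r2, msd = sqrt(ss_res / n), chi2 = ss_res / (n - n_params))
}

# Multi-start design: the registry default plus seeded Latin-hypercube draws
# within bounds. Rate-like parameters are mapped through log10 because their
# bounds span several decades; Thompson's negative `a` is sampled
# log-uniformly in magnitude.
fit_starts <- function(spec, n_starts, seed) {
  k <- length(spec$param_names)
  starts <- matrix(spec$init, nrow = 1L)
  if (n_starts > 1L) {
    u <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1L, k))
    draws <- matrix(NA_real_, n_starts - 1L, k)
    for (j in seq_len(k)) {
      lo <- spec$lower[j]
      hi <- spec$upper[j]
      draws[, j] <- switch(spec$role[j],
        rate = 10^(log10(lo) + u[, j] * (log10(hi) - log10(lo))),
        neg_rate = -10^(log10(-hi) + u[, j] * (log10(-lo) - log10(-hi))),
        lo + u[, j] * (hi - lo)
      )
    }
    starts <- rbind(starts, draws)
  }
  colnames(starts) <- spec$param_names
  starts
}

# Exponential-term canonicalization for the models with interchangeable
# terms. Sums of identical-form exponentials are only identifiable up to
# permutation of terms, and not at all in the amplitude split when rates
# coincide (or when an amplitude is ~0, leaving its rate meaningless). The
# canonical representative: (1) terms with negligible amplitude are
# reassigned to the rate cluster carrying the most amplitude (an
# SSE-preserving move); (2) terms whose rates agree within `tol` relative
# form one cluster sharing the amplitude-weighted mean rate with the total
# amplitude split equally; (3) clusters are ordered by descending rate.
canonicalize_exp_terms <- function(amps, rates, tol = 1e-3) {
  n <- length(amps)
  free <- abs(amps) < 1e-6 * max(sum(abs(amps)), 1e-12)
  if (all(free)) {
    ord <- order(-rates)
    return(list(amps = amps[ord], rates = rates[ord]))
  }
  ord <- order(-rates)
  core <- ord[!free[ord]]
  r <- rates[core]
  cluster_of <- cumsum(c(1, diff(r) < -tol * pmax(abs(r[-1]), abs(r[-length(r)]))))
  clusters <- lapply(unique(cluster_of), function(g) core[cluster_of == g])
  totals <- vapply(clusters, function(idx) sum(abs(amps[idx])), numeric(1L))
  heaviest <- which.max(totals)
  counts <- vapply(clusters, length, integer(1L))
  counts[heaviest] <- counts[heaviest] + sum(free)
  out_amps <- numeric(0)
  out_rates <- numeric(0)
  for (g in seq_along(clusters)) {
    idx <- clusters[[g]]
    w <- abs(amps[idx])
    rate_g <- if (sum(w) > 0) sum(w * rates[idx]) / sum(w) else mean(rates[idx])
    total_g <- sum(amps[idx]) + if (g == heaviest) sum(amps[free]) else 0
    out_amps <- c(out_amps, rep(total_g / counts[g], counts[g]))
    out_rates <- c(out_rates, rep(rate_g, counts[g]))
  }
  list(amps = out_amps, rates = out_rates)
}

canonicalize_params <- function(model_name, params) {
  if (model_name == "two_term") {
    cc <- canonicalize_exp_terms(params[c(1L, 3L)], params[c(2L, 4L)])
    params <- c(cc$amps[1L], cc$rates[1L], cc$amps[2L], cc$rates[2L])
    names(params) <- c("a", "k0", "b", "k1")
  } else if (model_name == "henderson_pabis_modified") {
    cc <- canonicalize_exp_terms(params[c(1L, 3L, 5L)], params[c(2L, 4L, 6L)])
    params <- c(cc$amps[1L], cc$rates[1L], cc$amps[2L], cc$rates[2L],
                cc$amps[3L], cc$rates[3L])
    names(params) <- c("a", "k", "b", "k0", "c", "k1")
  } else if (model_name == "verma") {
    # terms (a, k) and (1 - a, k1) are interchangeable: order by descending
    # rate; with coincident rates the split is immaterial (curve is exp(-kt))
    # and a = 1/2 is the representative.
    a <- params[1L]; k <- params[2L]; k1 <- params[3L]
    if (abs(k - k1) < 1e-3 * max(abs(k), abs(k1))) {
      km <- (k + k1) / 2
      params <- c(0.5, km, km)
    } else if (k < k1) {
      params <- c(1 - a, k1, k)
    }
    names(params) <- c("a", "k", "k1")
  }
  params
}

#' Fit a thin-layer drying model to a moisture-ratio series
#'
#' Multi-start bounded nonlinear least squares: the registry's default
#' initial guess plus seeded Latin-hypercube draws within the parameter
#' bounds, each refined by Levenberg-Marquardt ([minpack.lm::nls.lm()]); the
#' solution with the lowest sum of squared residuals is kept. Two-term and
#' modified Henderson-Pabis fits are canonicalized (exponential terms sorted
#' by descending rate; terms with indistinguishable rates share their
#' amplitude equally) so that reported parameters are comparable across runs.
#'
#' @param series An [mr_series()] (or a [drying_run()], converted via
#'   [series_from_run()]).
#' @param model Model name or specification from [drying_models()].
#' @param n_starts Number of optimizer starts (default 16).
#' @param seed Seed for the Latin-hypercube start design.
#' @param max_eval Maximum residual evaluations per start.
#' @return An object of class `drying_fit`: a list with `model_name`,
#'   named `params`, `n_obs`, `n_params`, `r2`, `msd`, `chi2`, `sse`,
#'   `converged` and `residuals` (predicted minus observed).
#' @examples
#' s <- mr_series(seq(0, 300, by = 20), exp(-0.0148 * seq(0, 300, by = 20)))
#' fit_drying_model(s, "newton")$params
#' @export
fit_drying_model <- function(series, model, n_starts = 16L, seed = 1L,
                             max_eval = 5000L) {
  if (inherits(series, "drying_run")) series <- series_from_run(series)
  stopifnot(inherits(series, "mr_series"))
  spec <- if (inherits(model, "drying_model_spec")) model else drying_model(model)
  t_min <- series$times_min
  y <- series$mr
  n <- length(y)
  k <- length(spec$param_names)
  if (n <= k) {
    stop("need more observations (", n, ") than parameters (", k, ")", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("statistic undefined: constant moisture-ratio series", call. = FALSE)
  }

  resid_fun <- function(p) {
    pred <- tryCatch(spec$fun(p, t_min), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(1e6, n))
    }
    pred - y
  }
  jac_fun <- if (is.null(spec$jac)) NULL else function(p) {
    j <- tryCatch(spec$jac(p, t_min), error = function(e) NULL)
    if (is.null(j) || any(!is.finite(j))) j <- matrix(0, n, k)
    j
  }

  starts <- fit_starts(spec, n_starts, seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    out <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fun, jac = jac_fun,
        lower = spec$lower, upper = spec$upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000L, maxfev = max_eval, ftol = 1e-15, ptol = 1e-15
        )
      )),
      error = function(e) NULL
    )
    if (is.null(out)) next
    sse <- sum(out$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = out$par, sse = sse, info = out$info)
    }
  }
  if (is.null(best) || best$sse >= n * 1e12) {
    stop("fit of '", spec$name, "' failed to converge from any of ",
         nrow(starts), " starts", call. = FALSE)
  }

  params <- canonicalize_params(spec$name, best$par)
  if (is.null(names(params))) names(params) <- spec$param_names
  pred <- spec$fun(params, t_min)
  gof <- goodness_of_fit(y, pred, k)
  structure(
    list(
      model_name = spec$name,
      params = params,
      n_obs = n,
      n_params = k,
      r2 = gof$r2,
      msd = gof$msd,
      chi2 = gof$chi2,
      sse = sum((pred - y)^2),
      # info 1-3: ftol/ptol convergence; 4: gradient orthogonal to residuals
      # (first-order optimum); an (essentially) exact fit also counts.
      converged = best$info %in% 1:4 || best$sse <= 1e-12 * max(sum(y^2), 1),
      residuals = pred - y
    ),
    class = "drying_fit"
  )
}

#' Fit every registry model to one series
#'
#' @inheritParams fit_drying_model
#' @param models Model names to fit; defaults to all ten.
#' @return A named list of `drying_fit` objects. Models whose fit fails are
#'   dropped with a warning.
#' @export
fit_all_models <- function(series, models = names(drying_models()),
                           n_starts = 16L, seed = 1L) {
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_drying_model(series, m, n_starts = n_starts, seed = seed),
                  error = function(e) {
                    warning("model '", m, "' failed: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[f$model_name]] <- f
  }
  fits
}

#' Rank fitted models by goodness of fit
#'
#' Orders fits by descending R2; ties broken by ascending RMSD, then
#' ascending reduced chi-square, then parsimony (fewer parameters first).
#' Non-converged fits are dropped.
#'
#' @param fits A list of `drying_fit` objects.
#' @return The converged fits, reordered best-first.
#' @seealso [fit_summary()] for a tabular view.
#' @export
rank_model_fits <- function(fits) {
  if (length(fits) == 0L) stop("no fits to rank", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1L), "drying_fit")))
  fits <- fits[vapply(fits, `[[`, logical(1L), "converged")]
  if (length(fits) == 0L) stop("no converged fits to rank", call. = FALSE)
  ord <- order(
    -vapply(fits, `[[`, numeric(1L), "r2"),
    vapply(fits, `[[`, numeric(1L), "msd"),
    vapply(fits, `[[`, numeric(1L), "chi2"),
    vapply(fits, `[[`, numeric(1L), "n_params")
  )
  fits[ord]
}

#' Tabulate a list of drying fits
#'
#' @param fits A list of `drying_fit` objects.
#' @return A data frame with one row per fit: model, number of parameters,
#'   R2, RMSD, reduced chi-square and convergence flag.
#' @export
fit_summary <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1L), "drying_fit")))
  data.frame(
    model = vapply(fits, `[[`, character(1L), "model_name"),
    n_params = vapply(fits, `[[`, integer(1L), "n_params"),
    r2 = vapply(fits, `[[`, numeric(1L), "r2"),
    msd = vapply(fits, `[[`, numeric(1L), "msd"),
    chi2 = vapply(fits, `[[`, numeric(1L), "chi2"),
    converged = vapply(fits, `[[`, logical(1L), "converged"),
    row.names = NULL
  )
}

#' @export
print.drying_fit <- function(x, ...) {
  cat(sprintf("<drying_fit> %s: R2 = %.4f, RMSD = %.4f, chi2 = %.5f (%s)\n",
              x$model_name, x$r2, x$msd, x$chi2,
              if (x$converged) "converged" else "not converged"))
  print(round(x$params, 6))
  invisible(x)
}
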