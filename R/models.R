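#' @name drying-models
#' @title The ten classical thin-layer drying models
#'
#' @description
#' The registry holds the ten closed-form moisture-ratio curves MR(t; theta)
#' commonly fitted to thin-layer drying data (time in minutes):
#'
#' * `two_term`: `a*exp(-k0*t) + b*exp(-k1*t)`
#' * `henderson_pabis`: `a*exp(-k*t)`
#' * `henderson_pabis_modified`: `a*exp(-k*t) + b*exp(-k0*t) + c*exp(-k1*t)`
#' * `logarithmic`: `a*exp(-k*t) + c`
#' * `logistic`: `a0 / (1 + a*exp(k*t))`
#' * `midilli`: `a*exp(-k*t^n) + b*t`
#' * `newton`: `exp(-k*t)`
#' * `page`: `exp(-k*t^n)`
#' * `thompson`: `exp((-a - sqrt(a^2 + 4*b*t)) / (2*b))` (fitted with `a < 0`,
#'   `b > 0`, for which MR(0) = 1)
#' * `verma`: `a*exp(-k*t) + (1 - a)*exp(-k1*t)`
#'
#' Each registry entry carries the ordered parameter names, box bounds, a
#' default initial guess and a parameter "role" (`amp`litude, `rate`,
#' `exp`onent, or `neg_rate` for Thompson's large negative `a`) used by the
#' multi-start sampler: rate-like parameters are drawn log-uniformly because
#' their bounds span several decades.
NULL

model_spec <- function(name, param_names, role, lower, upper, init, fun,
                       jac = NULL) {
  stopifnot(length(param_names) == length(lower),
            length(lower) == length(upper),
            length(init) == length(param_names),
            all(init >= lower & init <= upper))
  structure(
    list(name = name, param_names = param_names, role = role,
         lower = lower, upper = upper, init = init, fun = fun, jac = jac),
    class = "drying_model_spec"
  )
}

# t^n * log(t) with its t -> 0 limit (0 for n > 0).
pow_log <- function(t, n) ifelse(t == 0, 0, t^n * log(t))

# Registry in the conventional presentation order of the model family.
.model_registry <- local({
  amp <- c(-20, 20)
  rate <- c(1e-6, 10)
  expo <- c(0.1, 5)
  specs <- list(
    model_spec(
      "two_term", c("a", "k0", "b", "k1"), c("amp", "rate", "amp", "rate"),
      c(amp[1], rate[1], amp[1], rate[1]), c(amp[2], rate[2], amp[2], rate[2]),
      c(0.5, 0.02, 0.5, 0.005),
      function(p, t) p[1] * exp(-p[2] * t) + p[3] * exp(-p[4] * t),
      jac = function(p, t) {
        e1 <- exp(-p[2] * t); e2 <- exp(-p[4] * t)
        cbind(e1, -p[1] * t * e1, e2, -p[3] * t * e2)
      }
    ),
    model_spec(
      "henderson_pabis", c("a", "k"), c("amp", "rate"),
      c(amp[1], rate[1]), c(amp[2], rate[2]), c(1, 0.01),
      function(p, t) p[1] * exp(-p[2] * t),
      jac = function(p, t) {
        e <- exp(-p[2] * t)
        cbind(e, -p[1] * t * e)
      }
    ),
    model_spec(
      "henderson_pabis_modified",
      c("a", "k", "b", "k0", "c", "k1"),
      c("amp", "rate", "amp", "rate", "amp", "rate"),
      c(amp[1], rate[1], amp[1], rate[1], amp[1], rate[1]),
      c(amp[2], rate[2], amp[2], rate[2], amp[2], rate[2]),
      c(1 / 3, 0.005, 1 / 3, 0.01, 1 / 3, 0.02),
      function(p, t) p[1] * exp(-p[2] * t) + p[3] * exp(-p[4] * t) + p[5] * exp(-p[6] * t),
      jac = function(p, t) {
        e1 <- exp(-p[2] * t); e2 <- exp(-p[4] * t); e3 <- exp(-p[6] * t)
        cbind(e1, -p[1] * t * e1, e2, -p[3] * t * e2, e3, -p[5] * t * e3)
      }
    ),
    model_spec(
      "logarithmic", c("a", "k", "c"), c("amp", "rate", "amp"),
      c(amp[1], rate[1], amp[1]), c(amp[2], rate[2], amp[2]), c(1, 0.01, 0),
      function(p, t) p[1] * exp(-p[2] * t) + p[3],
      jac = function(p, t) {
        e <- exp(-p[2] * t)
        cbind(e, -p[1] * t * e, rep(1, length(t)))
      }
    ),
    model_spec(
      "logistic", c("a0", "a", "k"), c("amp", "amp", "rate"),
      c(1e-4, -0.999, rate[1]), c(20, 20, rate[2]), c(1, 1, 0.01),
      function(p, t) {
        denom <- 1 + p[2] * exp(p[3] * t)
        if (any(denom == 0)) stop("logistic model: zero denominator", call. = FALSE)
        p[1] / denom
      },
      jac = function(p, t) {
        g <- exp(p[3] * t)
        denom <- 1 + p[2] * g
        cbind(1 / denom, -p[1] * g / denom^2, -p[1] * p[2] * t * g / denom^2)
      }
    ),
    model_spec(
      "midilli", c("a", "k", "n", "b"), c("amp", "rate", "exp", "amp"),
      c(amp[1], rate[1], expo[1], -0.1), c(amp[2], rate[2], expo[2], 0.1),
      c(1, 0.01, 1, 0),
      function(p, t) p[1] * exp(-p[2] * t^p[3]) + p[4] * t,
      jac = function(p, t) {
        e <- exp(-p[2] * t^p[3])
        cbind(e, -p[1] * t^p[3] * e, -p[1] * p[2] * pow_log(t, p[3]) * e, t)
      }
    ),
    model_spec(
      "newton", "k", "rate", rate[1], rate[2], 0.01,
      function(p, t) exp(-p[1] * t),
      jac = function(p, t) cbind(-t * exp(-p[1] * t))
    ),
    model_spec(
      "page", c("k", "n"), c("rate", "exp"),
      c(rate[1], expo[1]), c(rate[2], expo[2]), c(0.01, 1),
      function(p, t) exp(-p[1] * t^p[2]),
      jac = function(p, t) {
        e <- exp(-p[1] * t^p[2])
        cbind(-t^p[2] * e, -p[1] * pow_log(t, p[2]) * e)
      }
    ),
    model_spec(
      "thompson", c("a", "b"), c("neg_rate", "rate"),
      c(-1e5, 1e-4), c(-1e-4, 100), c(-100, 1),
      function(p, t) {
        if (p[2] == 0) stop("thompson model: b must be nonzero", call. = FALSE)
        disc <- p[1]^2 + 4 * p[2] * t
        if (any(disc < 0)) stop("thompson model: negative discriminant", call. = FALSE)
        exp((-p[1] - sqrt(disc)) / (2 * p[2]))
      },
      jac = function(p, t) {
        s <- sqrt(p[1]^2 + 4 * p[2] * t)
        u <- (-p[1] - s) / (2 * p[2])
        e <- exp(u)
        du_da <- (-1 - p[1] / s) / (2 * p[2])
        du_db <- (p[1] + s) / (2 * p[2]^2) - t / (p[2] * s)
        cbind(e * du_da, e * du_db)
      }
    ),
    model_spec(
      "verma", c("a", "k", "k1"), c("amp", "rate", "rate"),
      c(amp[1], rate[1], rate[1]), c(amp[2], rate[2], rate[2]), c(0.3, 0.02, 0.005),
      function(p, t) p[1] * exp(-p[2] * t) + (1 - p[1]) * exp(-p[3] * t),
      jac = function(p, t) {
        e1 <- exp(-p[2] * t); e2 <- exp(-p[3] * t)
        cbind(e1 - e2, -p[1] * t * e1, -(1 - p[1]) * t * e2)
      }
    )
  )
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  specs
})

#' List the thin-layer drying model registry
#'
#' @return A named list of the 10 model specifications, in stable order.
#' @seealso [drying-models] for the functional forms, [drying_model()] for
#'   lookup by name, [eval_drying_model()] for evaluation.
#' @examples
#' names(drying_models())
#' @export
drying_models <- function() .model_registry

#' Look up a drying model by name
#'
#' @param name Model name (case-insensitive), one of
#'   `names(drying_models())`.
#' @return The model specification.
#' @export
drying_model <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(name)
  if (!key %in% names(.model_registry)) {
    stop("unknown drying model '", name, "'; available: ",
         paste(names(.model_registry), collapse = ", "), call. = FALSE)
  }
  .model_registry[[key]]
}

#' Evaluate a thin-layer drying model
#'
#' @param model A model name or a specification from [drying_models()].
#' @param params Numeric parameter vector in the model's parameter order
#'   (see `spec$param_names`).
#' @param times Times in minutes, non-negative.
#' @return The moisture ratio MR(t) at each time.
#' @examples
#' eval_drying_model("newton", 0.0148, c(0, 30, 60))
#' @export
eval_drying_model <- function(model, params, times) {
  spec <- if (inherits(model, "drying_model_spec")) model else drying_model(model)
  stopifnot(is.numeric(params), is.numeric(times))
  if (length(params) != length(spec$param_names)) {
    stop(spec$name, " expects ", length(spec$param_names), " parameters (",
         paste(spec$param_names, collapse = ", "), ")", call. = FALSE)
  }
  if (any(!is.finite(params))) stop("parameters must be finite", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  spec$fun(params, times)
}

#' @export
print.drying_model_spec <- function(x, ...) {
  cat(sprintf("<drying model> %s(%s)\n", x$name, paste(x$param_names, collapse = ", ")))
  invisible(x)
}
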