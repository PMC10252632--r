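#' Truncated Fick-slab series for the moisture ratio
#'
#' Analytical solution of Fick's second law for an infinite slab of
#' half-thickness `L` drying from both faces, with uniform initial moisture,
#' constant diffusivity and negligible shrinkage:
#' `MR = (8/pi^2) * sum_{n=0}^{n_terms-1} exp(-(2n+1)^2 pi^2 Fo / 4) / (2n+1)^2`
#' where `Fo = d_eff * t_s / L^2` is the Fourier number. With the default 9
#' terms the truncated sum at `t = 0` is 0.97752 rather than 1 (the
#' truncation deficit of the series identity `sum 1/(2n+1)^2 = pi^2/8`).
#'
#' @param d_eff Effective moisture diffusivity, m^2 s^-1 (positive).
#' @param half_thickness_m Slab half-thickness `L`, metres (positive).
#' @param t_s Time in seconds, non-negative; vectorized.
#' @param n_terms Number of series terms (default 9).
#' @return Moisture ratio at each time.
#' @export
slab_mr <- function(d_eff, half_thickness_m, t_s, n_terms = 9L) {
  stopifnot(is.numeric(d_eff), length(d_eff) == 1L,
            is.numeric(half_thickness_m), length(half_thickness_m) == 1L,
            is.numeric(t_s), is.numeric(n_terms), length(n_terms) == 1L)
  if (!is.finite(d_eff) || d_eff <= 0) stop("d_eff must be positive", call. = FALSE)
  if (!is.finite(half_thickness_m) || half_thickness_m <= 0) {
    stop("half_thickness_m must be positive", call. = FALSE)
  }
  if (n_terms < 1L) stop("n_terms must be at least 1", call. = FALSE)
  if (any(t_s < 0)) stop("times must be non-negative", call. = FALSE)
  fo <- d_eff * t_s / half_thickness_m^2
  m <- 2 * (seq_len(n_terms) - 1L) + 1 # odd integers 1, 3, 5, ...
  terms <- outer(fo, m, function(f, mm) exp(-mm^2 * pi^2 * f / 4) / mm^2)
  as.numeric((8 / pi^2) * rowSums(terms))
}

#' Estimate effective moisture diffusivity from a drying run
#'
#' Single-parameter least squares of the truncated Fick-slab series against
#' the observed moisture ratios: a 200-point log-uniform scan of `d_eff` over
#' 1e-13 to 1e-6 m^2 s^-1 (two decades beyond the usual foodstuff range)
#' locates the basin, which is then refined by golden-section/parabolic
#' search on log10(d_eff) to better than 1e-6 relative. Times are taken in
#' minutes from the series and converted to seconds internally. Points with
#' MR <= 0 (possible from noise near equilibrium) are excluded, since the
#' series model is positive.
#'
#' @param series An [mr_series()], or a [drying_run()] (converted internally;
#'   its `half_thickness_m` and `temperature_c` are used as defaults).
#' @param half_thickness_m Slab half-thickness, metres.
#' @param n_terms Number of series terms (default 9).
#' @param temperature_c Optional temperature tag carried into the result.
#' @return An object of class `deff_estimate`: list with `temperature_c`,
#'   `d_eff` (m^2 s^-1), `r2`, `n_terms`, `half_thickness_m`, `n_points`.
#' @export
estimate_deff <- function(series, half_thickness_m = NULL, n_terms = 9L,
                          temperature_c = NA_real_) {
  if (inherits(series, "drying_run")) {
    if (is.null(half_thickness_m)) half_thickness_m <- series$half_thickness_m
    if (is.na(temperature_c)) temperature_c <- series$temperature_c
    series <- series_from_run(series)
  }
  stopifnot(inherits(series, "mr_series"))
  if (is.null(half_thickness_m) || !is.numeric(half_thickness_m) ||
      !is.finite(half_thickness_m) || half_thickness_m <= 0) {
    stop("half_thickness_m must be a positive number", call. = FALSE)
  }
  keep <- series$mr > 0
  t_s <- series$times_min[keep] * 60
  y <- series$mr[keep]
  if (sum(y > 0 & y <= 1) < 3L) {
    stop("need at least 3 points with moisture ratio in (0, 1]", call. = FALSE)
  }

  sse <- function(log10_d) {
    pred <- slab_mr(10^log10_d, half_thickness_m, t_s, n_terms)
    sum((pred - y)^2)
  }
  grid <- seq(log10(1e-13), log10(1e-6), length.out = 200L)
  grid_sse <- vapply(grid, sse, numeric(1L))
  i <- which.min(grid_sse)
  if (i == 1L || i == length(grid)) {
    stop("diffusivity estimation failed: SSE is monotone over the search range",
         call. = FALSE)
  }
  opt <- stats::optimize(sse, lower = grid[i - 1L], upper = grid[i + 1L],
                         tol = 1e-8)
  d_eff <- 10^opt$minimum
  pred <- slab_mr(d_eff, half_thickness_m, t_s, n_terms)
  gof <- goodness_of_fit(y, pred, 1L)
  structure(
    list(
      temperature_c = temperature_c,
      d_eff = d_eff,
      r2 = gof$r2,
      n_terms = as.integer(n_terms),
      half_thickness_m = half_thickness_m,
      n_points = length(y)
    ),
    class = "deff_estimate"
  )
}

#' @export
print.deff_estimate <- function(x, ...) {
  cat(sprintf("<deff_estimate> D_eff = %.4g m^2/s (R2 = %.4f, %d terms, L = %g m%s)\n",
              x$d_eff, x$r2, x$n_terms, x$half_thickness_m,
              if (is.na(x$temperature_c)) "" else sprintf(", %g degC", x$temperature_c)))
  invisible(x)
}
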