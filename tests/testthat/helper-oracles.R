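# Independent oracles used across tests. These deliberately do not reuse the
# package's implementations.

# Dense grid-search least squares for 1- and 2-parameter models.
grid_search_sse <- function(fun, times, y, lower, upper, n_grid = 200L) {
  grids <- lapply(seq_along(lower), function(j) {
    if (lower[j] > 0 && upper[j] / lower[j] > 1e3) {
      10^seq(log10(lower[j]), log10(upper[j]), length.out = n_grid)
    } else {
      seq(lower[j], upper[j], length.out = n_grid)
    }
  })
  best <- Inf
  if (length(grids) == 1L) {
    for (p1 in grids[[1L]]) {
      sse <- sum((fun(p1, times) - y)^2)
      if (sse < best) best <- sse
    }
  } else {
    for (p1 in grids[[1L]]) {
      for (p2 in grids[[2L]]) {
        sse <- sum((fun(c(p1, p2), times) - y)^2)
        if (sse < best) best <- sse
      }
    }
  }
  best
}

# Brute-force Fick-slab series sum, written independently (plain loop).
slab_series_brute <- function(fo, n_terms = 500L) {
  total <- 0
  for (n in 0:(n_terms - 1L)) {
    m <- 2 * n + 1
    total <- total + exp(-m^2 * pi^2 * fo / 4) / m^2
  }
  8 / pi^2 * total
}

# Reference parameter sets used by recovery tests: one smelling and one pout
# condition per model.
recovery_cases <- function() {
  list(
    list(variety = "smelling", temperature_c = 50, total_min = 1250),
    list(variety = "pout", temperature_c = 80, total_min = 530)
  )
}
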