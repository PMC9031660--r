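# Shared fixtures: exact median-effect data and a brute-force fitting oracle.

# (dose, fa) points lying exactly on the law fa/fu = (D/Dm)^m
exact_points <- function(m, dm, doses) {
  list(dose = doses, fa = 1 / (1 + (dm / doses)^m))
}

# Independent oracle for the median-effect fit: grid search over (m, Dm)
# minimizing the sum of squared residuals on the linearized plot.
grid_fit_oracle <- function(dose, fa, m_range = c(0.2, 5),
                            dm_range = NULL, n_grid = 201) {
  if (is.null(dm_range)) dm_range <- range(dose) * c(0.2, 5)
  ms <- seq(m_range[1], m_range[2], length.out = n_grid)
  dms <- 10^seq(log10(dm_range[1]), log10(dm_range[2]), length.out = n_grid)
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  best <- list(sse = Inf)
  for (m in ms) {
    # residuals y - (m*x - m*log10(Dm)) over the Dm grid, vectorized
    pred0 <- m * x
    for (dm in dms) {
      sse <- sum((y - (pred0 - m * log10(dm)))^2)
      if (sse < best$sse) best <- list(m = m, dm = dm, sse = sse)
    }
  }
  best
}
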