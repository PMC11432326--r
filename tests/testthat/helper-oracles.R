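# Independent brute-force oracles. These deliberately avoid the package's
# fitting code paths: plain arithmetic and exhaustive grid search only.

# Residual sum of squares of the Michaelis-Menten hyperbola at (Km, Vmax).
mm_rss <- function(S, v, Km, Vmax) {
  sum((v - Vmax * S / (Km + S))^2)
}

# Minimum RSS over a log-spaced (Km, Vmax) grid centred on rough data scales.
mm_grid_min_rss <- function(S, v, n = 200) {
  km_grid <- exp(seq(log(min(S[S > 0]) / 4), log(max(S) * 4),
                     length.out = n))
  vmax_grid <- exp(seq(log(max(v) / 4), log(max(v) * 4), length.out = n))
  best <- Inf
  for (km in km_grid) {
    pred_unit <- S / (km + S)
    # Vmax enters linearly, but scan the grid as specified anyway
    rss <- vapply(vmax_grid,
                  function(vm) sum((v - vm * pred_unit)^2), numeric(1))
    best <- min(best, min(rss))
  }
  best
}

# Boltzmann-fraction form of the two-state melt signal:
# f_U * S_U + (1 - f_U) * S_N with f_U = K/(1+K), coded independently.
melt_signal_oracle <- function(Tk, Tm, dHvH, A_N, B_N, A_U, B_U,
                               R = 1.987e-3) {
  K <- exp(-(dHvH / R) * (1 / Tk - 1 / Tm))
  fU <- K / (1 + K)
  fU * (A_U + B_U * Tk) + (1 - fU) * (A_N + B_N * Tk)
}

# Grid search over (Tm, dHvH) with the four baseline coefficients solved by
# linear least squares at each node (the model is linear in them given the
# unfolded fraction). Returns the minimum RSS found.
melt_grid_min_rss <- function(Tk, S, n = 50, R = 1.987e-3) {
  tm_grid <- seq(min(Tk), max(Tk), length.out = n)
  dh_grid <- exp(seq(log(20), log(500), length.out = n))
  best <- Inf
  for (tm in tm_grid) {
    for (dh in dh_grid) {
      K <- exp(pmin(700, pmax(-700, -(dh / R) * (1 / Tk - 1 / tm))))
      fU <- K / (1 + K)
      X <- cbind((1 - fU), (1 - fU) * Tk, fU, fU * Tk)
      beta <- tryCatch(qr.solve(qr(X, LAPACK = TRUE), S),
                       error = function(e) NULL)
      if (is.null(beta)) next
      rss <- sum((S - X %*% beta)^2)
      if (rss < best) best <- rss
    }
  }
  best
}
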