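# Independent oracles used to cross-check the package implementations.
# They deliberately avoid the code paths they verify.

# Three-phase mass balance: solve the linear system
#   C1 = K1 C3, C3 = K2 C2, C1 V1 + C2 V2 + C3 V3 = C0 V2
# for the phase concentrations and return the mass in each phase (ng).
mass_balance_oracle <- function(v1, v2, v3, k1, k2, c0) {
  A <- rbind(
    c(1, 0, -k1),   # C1 - K1 C3 = 0
    c(0, k2, -1),   # K2 C2 - C3 = 0
    c(v1, v2, v3)   # mass balance
  )
  b <- c(0, 0, c0 * v2)
  conc <- solve(A, b)
  list(coating = conc[1] * v1 * 1000,
       liquid = conc[2] * v2 * 1000,
       headspace = conc[3] * v3 * 1000)
}

# Recursive cofactor-expansion determinant, independent of base::det.
det_cofactor <- function(m) {
  n <- nrow(m)
  if (n == 1) return(m[1, 1])
  if (n == 2) return(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  total <- 0
  for (j in seq_len(n)) {
    minor <- m[-1, -j, drop = FALSE]
    total <- total + (-1)^(1 + j) * m[1, j] * det_cofactor(minor)
  }
  total
}

# Closed-form simple linear regression via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       sd_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# The 3 x 2 coded candidate grid used throughout (fiber thickness x
# sampling temperature).
default_grid <- function() {
  build_candidates(list(
    factor_spec("x1", c(-1, 0, 1), c("7 um", "30 um", "100 um")),
    factor_spec("x2", c(-1, 1), c("60 C", "10 C"))
  ))
}
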