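# Independent bisection oracle on the mass-action residual, used to check
# every closed-form root. Works directly on concentrations (no quadratic),
# so it shares no code path with the package's solvers.
#
# residual(c) = (c*N0 - h) * (c*N0) - K * (N0 - c*N0) * (P0 - c*N0 + h)
# The admissible conversion is the root of this in (max(0, h/N0),
# min(1, (P0+h)/N0)): negative at the lower end (no products), positive at
# the upper end (a reactant exhausted).
oracle_conversion <- function(N0, P0, K, h = 0, tol = 1e-13) {
  f <- function(c) (c * N0 - h) * (c * N0) - K * (N0 - c * N0) * (P0 - c * N0 + h)
  lo <- max(0, h / N0)
  hi <- min(1, (P0 + h) / N0)
  uniroot(f, c(lo, hi), tol = tol)$root
}

# mass-action residual of a state implied by (c, h); 0 at equilibrium
mass_action_residual <- function(system, c, h = 0) {
  B <- c * system$N0
  N <- system$N0 - B
  P <- system$P0 - B + h
  P1P <- B - h
  P1P * B / (N * P) - system$K
}

# write a small spectra CSV and return its path
write_spectra_csv <- function(wl, cols, path = tempfile(fileext = ".csv")) {
  df <- data.frame(wavelength_nm = wl, cols, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}

uridine_system <- function() reaction_system(N0 = 2, P0 = 8, K = 0.15)
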