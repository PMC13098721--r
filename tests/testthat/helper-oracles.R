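# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing binary is stored.

PAR <- physical_params()   # k_D = 0.25/ns, k_A = 0.5/ns, R0 = 5 nm

# brute-force quadrature of the path efficiency on a fine grid, independent
# of the package's trapezoid/interpolation code path
oracle_efficiency_path <- function(k_fun, T, k_D, n = 1e5) {
  tt <- seq(0, T, length.out = n + 1)
  kk <- k_fun(tt)
  Lam <- sum((kk[-1] + kk[-length(kk)]) / 2 * diff(tt))
  Lam / (Lam + k_D * T)
}

# independent Ogata-thinning sampler (per-draw loop, written from the
# textbook algorithm, no shared code with sample_transfer_time)
oracle_thinning <- function(t_grid, k_grid, n) {
  M <- max(k_grid)
  tmax <- max(t_grid)
  out <- numeric(n)
  for (i in seq_len(n)) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, M)
      if (t > tmax) { t <- Inf; break }
      lam <- stats::approx(t_grid, k_grid, xout = t)$y
      if (stats::runif(1) < lam / M) break
    }
    out[i] <- t
  }
  out
}

# CDF of the norm of a centered isotropic 3-D Gaussian with per-axis sd s
# (the "Rayleigh distributed" interdye distance of the centered spring
# configuration)
pnorm3d <- function(x, s) stats::pchisq((x / s)^2, df = 3)

# small, fast burst configuration for engine tests (caller args win)
fast_config <- function(...) {
  args <- list(n_excitations = 300, det_eff_D = 1, det_eff_A = 1,
               min_photons = 10)
  user <- list(...)
  args[names(user)] <- user
  do.call(burst_config, args)
}
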