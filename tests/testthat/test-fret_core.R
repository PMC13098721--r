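# Closed-form FRET layer: orientation factor, rates, efficiencies,
# lifetime estimators.

test_that("kappa_squared reproduces the canonical geometries", {
  # collinear: (1 - 3)^2 = 4
  expect_equal(kappa_squared(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), 4)
  # mutually orthogonal: no transfer possible
  expect_equal(kappa_squared(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 0)
  # parallel dipoles perpendicular to the displacement: (1 - 0)^2 = 1
  expect_equal(kappa_squared(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)), 1)
  # magnitude of r_vec is irrelevant, only direction enters
  expect_equal(kappa_squared(c(0, 0, 1), c(0, 0, 1), c(0, 0, 7.3)), 4)
  # dipole_frame input route agrees with the raw-vector route
  f <- dipole_frame(c(0, 1, 0), c(0, 0, 1), c(3, 4, 0))
  expect_equal(kappa_squared(f),
               kappa_squared(c(0, 1, 0), c(0, 0, 1), c(3, 4, 0)))
})

test_that("kappa_squared validates unit norms and stays in [0, 4]", {
  expect_error(kappa_squared(c(0, 0, 2), c(0, 0, 1), c(0, 0, 1)), "unit")
  expect_error(dipole_frame(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0)), "positive")
  set.seed(42)
  k2 <- kappa_squared(sample_uniform_sphere(5000),
                      sample_uniform_sphere(5000),
                      sample_uniform_sphere(5000))
  expect_true(all(k2 >= 0 & k2 <= 4))
})

test_that("uniform-orientation ensemble average of kappa_squared is 2/3", {
  set.seed(7)
  n <- 3e5
  k2 <- kappa_squared(sample_uniform_sphere(n),
                      sample_uniform_sphere(n),
                      sample_uniform_sphere(n))
  se <- sd(k2) / sqrt(n)
  expect_lt(abs(mean(k2) - 2 / 3), 3 * se)
})

test_that("forster_rate identities at the Forster radius hold", {
  p <- PAR
  expect_equal(forster_rate(p$R0_iso, 2 / 3, p), p$k_D)
  expect_equal(forster_rate(p$R0_iso / 2, 2 / 3, p), 64 * p$k_D)
  expect_equal(forster_rate(3.1, 0, p), 0)
  expect_error(forster_rate(-1, 2 / 3, p), "> 0")
})

test_that("efficiency_static matches the closed form", {
  p <- PAR
  expect_equal(efficiency_static(p$R0_iso, p), 0.5)
  expect_equal(efficiency_static(0, p), 1)
  expect_equal(efficiency_static(2 * p$R0_iso, p), 1 / 65)
  # consistency with efficiency_path under a constant matched hazard
  r <- 6.2
  kc <- p$k_D * (p$R0_iso / r)^6
  path <- rate_path(seq(0, 20, by = 0.1), k_ET = rep(kc, 201))
  expect_equal(efficiency_path(path, 17.3, p), efficiency_static(r, p),
               tolerance = 1e-12)
})

test_that("efficiency_path handles constant, zero and piecewise hazards", {
  p <- PAR
  tg <- seq(0, 10, by = 0.01)
  const <- rate_path(tg, k_ET = rep(p$k_D, length(tg)))
  expect_equal(efficiency_path(const, 10, p), 0.5)
  expect_equal(efficiency_path(const, 3.21, p), 0.5)   # off-grid T
  zero <- rate_path(tg, k_ET = rep(0, length(tg)))
  expect_equal(efficiency_path(zero, 5, p), 0)
  # hazard k_D on [0, T/2], 0 afterwards: independent fine-grid oracle (1/3)
  Tt <- 8
  kfun <- function(t) ifelse(t <= Tt / 2, p$k_D, 0)
  piece <- rate_path(seq(0, Tt, by = 1e-3),
                     k_ET = kfun(seq(0, Tt, by = 1e-3)))
  expected <- oracle_efficiency_path(kfun, Tt, p$k_D)
  # the sampled staircase smooths the jump over one grid interval: O(dt)
  expect_equal(efficiency_path(piece, Tt, p), expected, tolerance = 1e-4)
  expect_equal(expected, 1 / 3, tolerance = 1e-4)
  expect_error(efficiency_path(piece, Tt + 1, p), "grid")
})

test_that("efficiency_path is monotone in pointwise hazard increases", {
  p <- PAR
  tg <- seq(0, 10, by = 0.05)
  set.seed(11)
  for (i in 1:20) {
    k1 <- runif(length(tg), 0, 0.5)
    bump <- runif(length(tg), 0, 0.2)
    e1 <- efficiency_path(rate_path(tg, k_ET = k1), 10, p)
    e2 <- efficiency_path(rate_path(tg, k_ET = k1 + bump), 10, p)
    expect_gte(e2, e1)
  }
})

test_that("efficiency_intensity is the count ratio with an empty-burst guard", {
  expect_equal(efficiency_intensity(50, 50), 0.5)
  expect_equal(efficiency_intensity(0, 10), 0)
  expect_error(efficiency_intensity(0, 0), "empty burst")
  expect_error(efficiency_intensity(1.5, 2), "integer")
  set.seed(3)
  n <- 1e4
  IA <- rbinom(1, n, 0.3)
  expect_lt(abs(efficiency_intensity(IA, n - IA) - 0.3),
            3 * sqrt(0.3 * 0.7 / n))
})

test_that("efficiency_lifetime is linear and unclipped", {
  expect_equal(efficiency_lifetime(4, 4), 0)
  expect_equal(efficiency_lifetime(2, 4), 0.5)
  expect_equal(efficiency_lifetime(0, 4), 1)
  expect_lt(efficiency_lifetime(5, 4), 0)  # noisy estimates stay negative
  expect_error(efficiency_lifetime(1, 0), "positive")
})

test_that("jensen_lifetimes obeys the convexity bound", {
  expect_equal(jensen_lifetimes(2), list(tau_bar = 0.5, tau_under = 0.5))
  jl <- jensen_lifetimes(c(1, 3), c(0.5, 0.5))
  expect_equal(jl$tau_bar, 2 / 3)
  expect_equal(jl$tau_under, 0.5)
  expect_error(jensen_lifetimes(c(1, 2), c(0.7, 0.7)), "sum to 1")
  set.seed(5)
  for (i in 1:100) {
    m <- sample(2:6, 1)
    rates <- rexp(m, 0.3) + 1e-3
    w <- runif(m); w <- w / sum(w)
    jl <- jensen_lifetimes(rates, w)
    expect_lte(jl$tau_under, jl$tau_bar + 1e-12)
  }
})
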