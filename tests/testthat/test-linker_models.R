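# Linker chemistry, OU spring and elastic pendulum dynamics.

test_that("linker_from_chemistry applies springs-in-series and the bond geometry", {
  lk1 <- linker_from_chemistry(1, k_bond = 5)
  expect_equal(lk1$k_eff, 5)
  lk10 <- linker_from_chemistry(10, k_bond = 5)
  expect_equal(lk10$k_eff, 0.5)
  # law-of-cosines per-link length at l = 1.54 A, theta = 109.5 deg
  l <- 0.154; th <- 109.5 * pi / 180
  expect_equal(lk10$L_link, sqrt(2 * l^2 - 2 * l^2 * cos(th)) / 2)
  expect_equal(lk10$L_link * 10, 1.2576, tolerance = 1e-4)  # Angstrom
  expect_equal(lk10$contour_length, 10 * lk10$L_link)
  expect_error(linker_from_chemistry(0), "N_links")
})

test_that("noise-free spring relaxes exponentially to x_eq", {
  sp <- spring_spec(k_rate = 0.5, sigma = 0, x_eq = c(1, -2, 3))
  tg <- seq(0, 20, by = 0.1)
  path <- simulate_spring(sp, tg, x0 = c(5, 0, 0))
  # Heun for dx = -k(x - xeq) is 2nd order: matches exp decay closely
  expect_equal(path[, 1], 1 + 4 * exp(-0.5 * tg), tolerance = 1e-3)
  expect_equal(path[nrow(path), ], c(x = 1, y = -2, z = 3), tolerance = 1e-3)
})

test_that("OU stationary variance matches sigma^2 / (2k) and both noise conventions agree", {
  sp <- spring_spec(k_rate = 1, sigma = sqrt(2))   # variance 1 per axis
  tg <- seq(0, 10000, by = 0.05)
  path <- simulate_spring(sp, tg, seed = 101)
  v <- apply(path, 2, var)
  expect_true(all(abs(v - 1) < 0.05))
  # sigma_paper convention: variance = sigma_paper / k
  sp2 <- spring_spec(k_rate = 1, sigma = NULL, sigma_paper = 1)
  expect_equal(sp2$sigma, sqrt(2))
  expect_equal(unname(sp2$stationary_sd), rep(1, 3))
})

test_that("spring simulation is reproducible and guards the step size", {
  sp <- spring_spec()
  tg <- seq(0, 50, by = 0.1)
  p1 <- simulate_spring(sp, tg, seed = 9)
  p2 <- simulate_spring(sp, tg, seed = 9)
  expect_identical(p1, p2)
  expect_error(simulate_spring(spring_spec(k_rate = 10), seq(0, 10, 0.5)),
               "unstable")
  expect_warning(simulate_spring(spring_spec(k_rate = 10), seq(0, 10, 0.5),
                                 seed = 1, override_stability = TRUE),
                 "inaccurate")
})

test_that("centered isotropic spring pair gives the 3-D Gaussian norm distance law", {
  # both dyes at the same attachment: displacement is centered Gaussian,
  # distance follows the chi(3) law ("Rayleigh distributed" configuration)
  sp <- spring_spec(k_rate = 1, sigma = sqrt(2))   # per-axis sd 1
  tg <- seq(0, 4000, by = 0.05)
  d <- simulate_spring(sp, tg, seed = 31)
  a <- simulate_spring(sp, tg, seed = 32)
  r <- interdye_distance(d, a)
  idx <- seq(1, length(r), by = 100)   # ~5 relaxation times apart: ~iid
  ks <- stats::ks.test(r[idx], function(x) pnorm3d(x, sqrt(2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free pendulum shows pure radial relaxation", {
  ps <- pendulum_spec(k_r = 0.5, r_eq = 2, k_theta = 0.1,
                      sigma_r = 0, sigma_theta = 0, sigma_phi = 0)
  tg <- seq(0, 30, by = 0.05)
  path <- simulate_pendulum(ps, tg, state0 = c(3, 0, 0))
  expect_equal(path$r, 2 + 1 * exp(-0.5 * tg), tolerance = 1e-3)
  expect_equal(path$theta, rep(0, length(tg)))
})

test_that("free angular pendulum diffusion has uniform cos(theta) stationary law", {
  # k_theta = 0 and a frozen radius: angular part is Brownian motion on the
  # sphere, whose stationary cos(theta) marginal is uniform on [-1, 1]
  ps <- pendulum_spec(k_r = 1, r_eq = 2, k_theta = 0,
                      sigma_r = 0, sigma_theta = 0.4, sigma_phi = 0.4)
  tg <- seq(0, 6000, by = 0.05)
  path <- simulate_pendulum(ps, tg, seed = 77, state0 = c(2, pi / 2, 0))
  # angular diffusion sigma^2/(2 r^2) = 0.02 -> relax ~ 25 ns; subsample
  ct <- cos(path$theta[seq(2000, length(tg), by = 2500)])
  ks <- stats::ks.test(ct, "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)
  expect_true(all(path$r > 0))
})

test_that("pendulum paths are reproducible and interdye_distance matches a direct norm", {
  ps <- pendulum_spec()
  tg <- seq(0, 100, by = 0.05)
  p1 <- simulate_pendulum(ps, tg, seed = 5)
  p2 <- simulate_pendulum(ps, tg, seed = 5)
  expect_identical(p1, p2)

  expect_equal(interdye_distance(matrix(0, 5, 3),
                                 matrix(rep(c(0, 0, 5), each = 5), 5, 3)),
               rep(5, 5))
  expect_equal(interdye_distance(matrix(0, 4, 3),
                                 matrix(rep(c(3, 4, 0), each = 4), 4, 3)),
               rep(5, 4))
  set.seed(8)
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(60) + 4, 20, 3)
  manual <- vapply(1:20, function(i) sqrt(sum((B[i, ] - A[i, ])^2)),
                   numeric(1))
  expect_equal(interdye_distance(A, B), manual)
  expect_error(interdye_distance(A, B[1:10, ]), "share")
})

test_that("dye_trajectory validates inputs and round-trips through text export", {
  tg <- seq(0, 1, by = 0.1)
  pos <- matrix(seq_len(33) / 10, 11, 3)
  tr <- dye_trajectory(tg, pos, pos + 2)
  expect_equal(interdye_distance(tr), rep(sqrt(12), 11))
  expect_error(dye_trajectory(tg, pos[1:5, ], pos), "match")
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$xD, pos[, 1])
  expect_equal(back$zA, pos[, 3] + 2)
})
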