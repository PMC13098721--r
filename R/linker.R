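# Translational dye dynamics: linker chemistry, OU springs (isotropic and
# anisotropic) and the stochastic elastic pendulum.

#' Package physical constants
#'
#' Reads the versioned constants file shipped under `inst/extdata`
#' (C-C bond length, tetrahedral bond angle, the printed single-bond spring
#' constant, and default thermodynamic values). Kept in a data file rather
#' than in code so printed literature values are versioned in one place.
#'
#' @return Named list of constants.
#' @export
fret_constants <- function() {
  path <- system.file("extdata", "constants.json", package = "smfretsim")
  if (!nzchar(path)) stop("constants.json not found in installed package")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Effective linker spring from C-C chain chemistry
#'
#' Treats a chain of `N_links` C-C bonds as springs in series,
#' `k_eff = k_bond / N_links`, and derives the effective per-link length
#' from the law of cosines on a C-C-C unit,
#' `L_link = sqrt(2 l^2 (1 - cos(theta))) / 2`, with bond length
#' `l = 1.54 A` and tetrahedral angle `theta = 109.5` degrees by default.
#'
#' Note the default `k_bond` is the printed literature value whose
#' magnitude/units are ambiguous (see the methods vignette); it is carried
#' as metadata and is not used by the simulation engine, whose spring
#' constants are friction-scaled rates.
#'
#' @param N_links integer number of C-C links, `>= 1`.
#' @param k_bond single C-C bond spring constant (configurable; default from
#'   [fret_constants()]).
#' @param l_bond C-C bond length (nm).
#' @param theta_bond C-C-C bond angle (degrees).
#' @return Object of class `linker_chemistry` with `k_eff`, `L_link` (nm)
#'   and `contour_length = N_links * L_link` (nm).
#' @examples
#' lk <- linker_from_chemistry(15)
#' lk$L_link * 10   # per-link length in Angstrom, ~1.2576
#' @export
linker_from_chemistry <- function(N_links, k_bond = NULL,
                                  l_bond = NULL, theta_bond = NULL) {
  cst <- fret_constants()
  if (is.null(k_bond)) k_bond <- cst$k_bond_printed
  if (is.null(l_bond)) l_bond <- cst$l_bond_nm
  if (is.null(theta_bond)) theta_bond <- cst$theta_bond_deg
  if (length(N_links) != 1L || N_links < 1 || N_links != round(N_links))
    stop("N_links must be an integer >= 1")
  if (k_bond <= 0) stop("k_bond must be > 0")
  th <- theta_bond * pi / 180
  L_link <- sqrt(2 * l_bond^2 * (1 - cos(th))) / 2
  structure(list(N_links = as.integer(N_links), k_bond = k_bond,
                 l_bond = l_bond, theta_bond = theta_bond,
                 k_eff = k_bond / N_links, L_link = L_link,
                 contour_length = N_links * L_link),
            class = "linker_chemistry")
}

#' @export
print.linker_chemistry <- function(x, ...) {
  cat(sprintf("C-C linker: %d links, l = %.4g nm, theta = %.4g deg\n",
              x$N_links, x$l_bond, x$theta_bond))
  cat(sprintf("  k_eff = k_bond/N = %.4g, L_link = %.5g nm, contour = %.4g nm\n",
              x$k_eff, x$L_link, x$contour_length))
  invisible(x)
}

#' OU spring model specification
#'
#' Overdamped noisy spring `dX = -K (X - X_eq) dt + sigma dB` with diagonal
#' spring matrix `K` in rate units (1/ns; the friction coefficient is
#' already absorbed, see the vignette). Isotropic when `anisotropy_p = 1`;
#' otherwise the two `soft_axes` entries are scaled by `p in [0, 1]`.
#' The stationary per-axis variance is `sigma^2 / (2 k_axis)` (nm^2).
#'
#' Two noise parameterizations are accepted: `sigma` is the SDE amplitude
#' (nm/sqrt(ns)); alternatively `sigma_paper` is the stationary-variance
#' numerator in the `variance = sigma_paper / k` convention, related by
#' `sigma^2 = 2 * sigma_paper`.
#'
#' @param k_rate base spring constant in rate units (1/ns).
#' @param sigma noise amplitude (nm/sqrt(ns)).
#' @param sigma_paper alternative noise parameter (nm^2/ns); exactly one of
#'   `sigma`/`sigma_paper` is used, `sigma` wins if both given.
#' @param anisotropy_p scaling of the two soft axes, in \[0, 1\]; 1 means
#'   isotropic.
#' @param soft_axes indices (two of 1:3) scaled by `anisotropy_p`.
#' @param x_eq equilibrium position (nm).
#' @return Object of class `spring_spec` with the diagonal `k` (length-3),
#'   `sigma`, `x_eq`, `anisotropy_p` and `stationary_sd` per axis.
#' @export
spring_spec <- function(k_rate = 0.005, sigma = 0.05, sigma_paper = NULL,
                        anisotropy_p = 1, soft_axes = c(1L, 2L),
                        x_eq = c(0, 0, 0)) {
  if (is.null(sigma)) {
    if (is.null(sigma_paper)) stop("supply sigma or sigma_paper")
    sigma <- sqrt(2 * sigma_paper)
  }
  if (k_rate <= 0) stop("k_rate must be > 0 (1/ns)")
  if (sigma < 0) stop("sigma must be >= 0")
  if (anisotropy_p < 0 || anisotropy_p > 1)
    stop("anisotropy_p must lie in [0, 1]")
  if (length(soft_axes) != 2L || !all(soft_axes %in% 1:3))
    stop("soft_axes must be two indices in 1:3")
  k <- rep(k_rate, 3)
  k[soft_axes] <- k[soft_axes] * anisotropy_p
  if (any(k <= 0)) stop("all diagonal spring entries must be > 0 (p > 0)")
  structure(list(k = k, sigma = sigma, x_eq = as.numeric(x_eq),
                 anisotropy_p = anisotropy_p,
                 stationary_sd = if (sigma > 0) sigma / sqrt(2 * k)
                                 else rep(0, 3)),
            class = "spring_spec")
}

#' Elastic pendulum model specification
#'
#' Spherical-coordinate Langevin system for a dye on a flexible tether:
#' radial spring `dr = (-k_r (r - r_eq) + sigma_r^2 / r) dt + sigma_r o dB`,
#' polar pendulum `dtheta = (-k_theta sin(theta) +
#' sigma_theta^2 / (2 r^2 tan(theta))) dt + (sigma_theta / r) o dB`, and
#' free azimuthal diffusion
#' `dphi = (sigma_phi / (r sin(theta))) o dB`. With `k_theta = 0` the
#' angular part reduces to Brownian motion on the sphere of radius `r`
#' (uniform stationary law) -- the criterion used to resolve the drift
#' grouping, see the vignette.
#'
#' @param k_r radial spring constant (1/ns).
#' @param r_eq equilibrium tether length (nm); default is the contour
#'   length of a 15-link C-C chain from [linker_from_chemistry()].
#' @param k_theta polar restoring constant (1/ns).
#' @param sigma_r,sigma_theta,sigma_phi component noise amplitudes
#'   (nm/sqrt(ns)); must be `>= 0`.
#' @return Object of class `pendulum_spec`.
#' @export
pendulum_spec <- function(k_r = 0.0025, r_eq = NULL, k_theta = 0.002,
                          sigma_r = 0.021, sigma_theta = 0.09,
                          sigma_phi = 0.09) {
  if (is.null(r_eq)) r_eq <- linker_from_chemistry(15)$contour_length
  if (k_r <= 0 || r_eq <= 0) stop("k_r and r_eq must be > 0")
  if (k_theta < 0) stop("k_theta must be >= 0")
  if (sigma_r < 0 || sigma_theta < 0 || sigma_phi < 0)
    stop("noise amplitudes must be >= 0")
  structure(list(k_r = k_r, r_eq = r_eq, k_theta = k_theta,
                 sigma_r = sigma_r, sigma_theta = sigma_theta,
                 sigma_phi = sigma_phi),
            class = "pendulum_spec")
}

.check_grid <- function(t_grid) {
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with >= 2 points")
  t_grid
}

#' Simulate an OU spring dye path
#'
#' Euler-Heun integration (for this additive-noise system identical to
#' Euler-Maruyama, and Ito/Stratonovich coincide). The step must satisfy
#' `max(dt) * max(k) < 0.1` unless `override_stability = TRUE`.
#'
#' @param spec a [spring_spec()].
#' @param t_grid strictly increasing times (ns).
#' @param seed optional integer seed (uses the R RNG).
#' @param x0 initial position; default is a draw from the stationary
#'   Gaussian law.
#' @param override_stability allow too-large steps (with a warning).
#' @return `length(t_grid) x 3` matrix of positions (nm).
#' @export
simulate_spring <- function(spec, t_grid, seed = NULL, x0 = NULL,
                            override_stability = FALSE) {
  if (!inherits(spec, "spring_spec")) stop("`spec` must be a spring_spec")
  t_grid <- .check_grid(t_grid)
  bad <- max(diff(t_grid)) * max(spec$k)
  if (bad >= 0.1) {
    if (!override_stability)
      stop(sprintf("unstable step: max(dt)*max(k) = %.3g >= 0.1 (set override_stability = TRUE to force)", bad))
    warning("integrating with max(dt)*max(k) >= 0.1; results may be inaccurate")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- spec$x_eq + rnorm(3) * spec$stationary_sd
  out <- cpp_ou_path(as.numeric(x0), spec$k, spec$x_eq, spec$sigma, t_grid)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Simulate an elastic pendulum dye path
#'
#' Stratonovich-consistent Euler-Heun integration of the three-component
#' Langevin system of [pendulum_spec()]. Steps that would cross the pole
#' (`|sin(theta)| < 1e-6`) or drive `r` to zero are rejected and retried at
#' half the step size (recursively, up to 25 halvings).
#'
#' @param spec a [pendulum_spec()].
#' @param t_grid strictly increasing times (ns).
#' @param seed optional integer seed.
#' @param state0 initial `(r, theta, phi)`; default `r = r_eq`, `theta`
#'   drawn with the sphere area weight (uniform `cos(theta)`), `phi`
#'   uniform.
#' @param attach attachment point (nm) added to the returned Cartesian
#'   coordinates.
#' @return `data.frame` with columns `t, r, theta, phi, x, y, z`.
#' @export
simulate_pendulum <- function(spec, t_grid, seed = NULL, state0 = NULL,
                              attach = c(0, 0, 0)) {
  if (!inherits(spec, "pendulum_spec")) stop("`spec` must be a pendulum_spec")
  t_grid <- .check_grid(t_grid)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state0)) {
    state0 <- c(spec$r_eq, acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
  }
  if (state0[1] <= 0) stop("initial r must be > 0")
  if (state0[2] < 0 || state0[2] > pi) stop("initial theta must lie in [0, pi]")
  pars <- c(spec$k_r, spec$r_eq, spec$k_theta,
            spec$sigma_r, spec$sigma_theta, spec$sigma_phi)
  m <- cpp_pendulum_path(as.numeric(state0), pars, t_grid)
  st <- sin(m[, 2])
  data.frame(t = t_grid, r = m[, 1], theta = m[, 2], phi = m[, 3],
             x = attach[1] + m[, 1] * st * cos(m[, 3]),
             y = attach[2] + m[, 1] * st * sin(m[, 3]),
             z = attach[3] + m[, 1] * cos(m[, 2]))
}

#' Paired dye trajectory container
#'
#' @param t_grid shared time grid (ns).
#' @param pos_D,pos_A `n x 3` matrices of dye positions (nm).
#' @param attach_D,attach_A fixed attachment points (nm).
#' @return Object of class `dye_trajectory`.
#' @export
dye_trajectory <- function(t_grid, pos_D, pos_A,
                           attach_D = c(0, 0, 0), attach_A = c(0, 0, 0)) {
  t_grid <- .check_grid(t_grid)
  pos_D <- as.matrix(pos_D); pos_A <- as.matrix(pos_A)
  if (nrow(pos_D) != length(t_grid) || nrow(pos_A) != length(t_grid))
    stop("position paths must match t_grid in length")
  if (ncol(pos_D) != 3L || ncol(pos_A) != 3L)
    stop("position paths must have 3 columns")
  if (any(!is.finite(pos_D)) || any(!is.finite(pos_A)))
    stop("positions must be finite")
  structure(list(t_grid = t_grid, pos_D = pos_D, pos_A = pos_A,
                 attach_D = as.numeric(attach_D),
                 attach_A = as.numeric(attach_A)),
            class = "dye_trajectory")
}

#' Interdye distance path
#'
#' Elementwise Euclidean norm of `pos_A - pos_D` along a shared grid.
#'
#' @param traj a [dye_trajectory()], or an `n x 3` donor position matrix
#'   (then `pos_A` must be given).
#' @param pos_A acceptor positions when `traj` is a matrix.
#' @return Numeric vector of distances (nm).
#' @export
interdye_distance <- function(traj, pos_A = NULL) {
  if (inherits(traj, "dye_trajectory")) {
    d <- traj$pos_A - traj$pos_D
  } else {
    pos_D <- as.matrix(traj); pos_A <- as.matrix(pos_A)
    if (!identical(dim(pos_D), dim(pos_A)))
      stop("donor and acceptor paths must share the same grid/dimensions")
    d <- pos_A - pos_D
  }
  r <- sqrt(rowSums(d^2))
  if (any(r <= 0)) stop("coincident dye positions: distance must be > 0")
  r
}

#' Write a paired trajectory as delimited text
#'
#' Columns `time, xD, yD, zD, xA, yA, zA`, tab-separated with a header row.
#'
#' @param traj a [dye_trajectory()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dye_trajectory"))
  df <- data.frame(time = traj$t_grid,
                   xD = traj$pos_D[, 1], yD = traj$pos_D[, 2],
                   zD = traj$pos_D[, 3],
                   xA = traj$pos_A[, 1], yA = traj$pos_A[, 2],
                   zA = traj$pos_A[, 3])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
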