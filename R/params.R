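# Domain containers for the closed-form FRET layer.
# Unit conventions (fixed throughout the package): time ns, length nm,
# rates 1/ns.  Conversions happen at config parsing only.

#' Physical FRET parameters
#'
#' Bundles the donor/acceptor radiative rates and the isotropic-average
#' Forster radius. The orientational coupling constant is fixed to
#' `C = (3/2) * R0_iso^6` so that the time-dependent Forster radius
#' `R0(t)^6 = C * kappa2(t)` reduces to the user-supplied `R0_iso` at the
#' isotropic average `kappa2 = 2/3`.
#'
#' @param k_D donor radiative decay rate (1/ns).
#' @param k_A acceptor radiative decay rate (1/ns).
#' @param R0_iso Forster radius under the `kappa2 = 2/3` convention (nm).
#' @return An object of class `fret_params` with fields `k_D`, `k_A`,
#'   `R0_iso`, `C` (nm^6) and `tau_D0 = 1/k_D` (ns).
#' @examples
#' p <- physical_params(k_D = 0.25, k_A = 0.5, R0_iso = 5)
#' p$tau_D0            # 4 ns donor-only lifetime
#' @export
physical_params <- function(k_D = 0.25, k_A = 0.5, R0_iso = 5) {
  stopifnot(is.numeric(k_D), length(k_D) == 1L, is.finite(k_D),
            is.numeric(k_A), length(k_A) == 1L, is.finite(k_A),
            is.numeric(R0_iso), length(R0_iso) == 1L, is.finite(R0_iso))
  if (k_D <= 0) stop("k_D must be > 0 (1/ns)")
  if (k_A <= 0) stop("k_A must be > 0 (1/ns)")
  if (R0_iso <= 0) stop("R0_iso must be > 0 (nm)")
  structure(
    list(k_D = k_D, k_A = k_A, R0_iso = R0_iso,
         C = 1.5 * R0_iso^6, tau_D0 = 1 / k_D),
    class = "fret_params")
}

#' @export
print.fret_params <- function(x, ...) {
  cat("FRET physical parameters\n")
  cat(sprintf("  k_D    = %.4g 1/ns  (tau_D0 = %.4g ns)\n", x$k_D, x$tau_D0))
  cat(sprintf("  k_A    = %.4g 1/ns\n", x$k_A))
  cat(sprintf("  R0_iso = %.4g nm    (C = %.4g nm^6)\n", x$R0_iso, x$C))
  invisible(x)
}

.assert_params <- function(params) {
  if (!inherits(params, "fret_params"))
    stop("`params` must be created with physical_params()")
  params
}

#' Instantaneous dipole/displacement geometry
#'
#' Validated snapshot of the two transition dipole orientations and the
#' interdye displacement, as consumed by [kappa_squared()].
#'
#' @param mu_D donor transition-dipole unit 3-vector.
#' @param mu_A acceptor transition-dipole unit 3-vector.
#' @param r_vec interdye displacement 3-vector (nm), acceptor minus donor.
#' @param tol unit-norm tolerance.
#' @return Object of class `dipole_frame` with fields `mu_D`, `mu_A`,
#'   `r_vec`, `r` and `r_hat`.
#' @export
dipole_frame <- function(mu_D, mu_A, r_vec, tol = 1e-9) {
  mu_D <- as.numeric(mu_D); mu_A <- as.numeric(mu_A); r_vec <- as.numeric(r_vec)
  if (length(mu_D) != 3L || length(mu_A) != 3L || length(r_vec) != 3L)
    stop("mu_D, mu_A and r_vec must be 3-vectors")
  nd <- sqrt(sum(mu_D^2)); na <- sqrt(sum(mu_A^2))
  if (abs(nd - 1) > tol) stop("mu_D is not a unit vector (|norm - 1| > tol)")
  if (abs(na - 1) > tol) stop("mu_A is not a unit vector (|norm - 1| > tol)")
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("r_vec must have positive magnitude")
  structure(list(mu_D = mu_D, mu_A = mu_A, r_vec = r_vec,
                 r = r, r_hat = r_vec / r),
            class = "dipole_frame")
}

# cumulative trapezoid integral, Lambda[1] = 0
.cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(t)))
}

#' Transfer-hazard path for one excitation event
#'
#' Stores the time grid, the orientation-factor path `kappa2(t)`, the
#' transfer hazard `k_ET(t)` and its cumulative trapezoid integral
#' `Lambda(t)`.  The hazard may be supplied directly via `k_ET`, or computed
#' from `kappa2` and a distance path `r` as
#' `k_ET(t) = k_D * C * kappa2(t) / r(t)^6`.
#'
#' @param t_grid strictly increasing times (ns), starting at 0.
#' @param kappa2 orientation-factor values on the grid, each in \[0, 4\].
#' @param r interdye distance path on the grid (nm), required when `k_ET`
#'   is not given.
#' @param k_ET transfer hazard on the grid (1/ns); overrides `kappa2`/`r`.
#' @param params [physical_params()] object (needed unless `k_ET` given).
#' @return Object of class `rate_path` with fields `t_grid`, `kappa2`,
#'   `k_ET`, `Lambda`.
#' @examples
#' p <- physical_params()
#' rp <- rate_path(seq(0, 40, by = 0.1), kappa2 = rep(2/3, 401),
#'                 r = rep(5, 401), params = p)
#' max(rp$Lambda)  # = k_D * 40 at r = R0, kappa2 = 2/3
#' @export
rate_path <- function(t_grid, kappa2 = NULL, r = NULL, k_ET = NULL,
                      params = NULL) {
  t_grid <- as.numeric(t_grid)
  n <- length(t_grid)
  if (n < 2L) stop("t_grid needs at least two points")
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (is.null(k_ET)) {
    if (is.null(kappa2) || is.null(r))
      stop("supply either k_ET or both kappa2 and r")
    .assert_params(params)
    kappa2 <- as.numeric(kappa2); r <- as.numeric(r)
    if (length(kappa2) != n || length(r) != n)
      stop("kappa2 and r must match t_grid in length")
    if (any(!is.finite(kappa2)) || any(kappa2 < 0 | kappa2 > 4))
      stop("kappa2 values must lie in [0, 4]")
    if (any(r <= 0)) stop("distance path r must be strictly positive")
    k_ET <- params$k_D * params$C * kappa2 / r^6
  } else {
    k_ET <- as.numeric(k_ET)
    if (length(k_ET) != n) stop("k_ET must match t_grid in length")
    if (any(!is.finite(k_ET)) || any(k_ET < 0))
      stop("k_ET must be finite and nonnegative")
    if (!is.null(kappa2)) {
      kappa2 <- as.numeric(kappa2)
      if (length(kappa2) != n) stop("kappa2 must match t_grid in length")
      if (any(kappa2 < 0 | kappa2 > 4)) stop("kappa2 values must lie in [0, 4]")
    }
  }
  structure(list(t_grid = t_grid, kappa2 = kappa2, k_ET = k_ET,
                 Lambda = .cumtrapz(t_grid, k_ET)),
            class = "rate_path")
}

# Lambda(T) with linear interpolation of the integrand inside the bracketing
# interval (so Lambda is piecewise quadratic, consistent with the trapezoid
# rule on the stored grid).
.lambda_at <- function(path, T) {
  t <- path$t_grid; k <- path$k_ET; L <- path$Lambda
  if (T < t[1] || T > t[length(t)]) stop("T outside the stored time grid")
  i <- findInterval(T, t)
  if (i == length(t)) return(L[i])
  s <- T - t[i]; d <- t[i + 1] - t[i]
  ki <- k[i]; slope <- (k[i + 1] - ki) / d
  L[i] + ki * s + 0.5 * slope * s^2
}
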