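# Closed-form FRET mathematics: orientation factor, transfer rates, static
# and path-dependent efficiencies, intensity/lifetime estimators and the
# Jensen's-inequality lifetime relations.

#' Dipole orientation factor kappa^2
#'
#' `kappa2 = (mu_D . mu_A - 3 (r_hat . mu_D)(r_hat . mu_A))^2`, the
#' dimensionless factor in \[0, 4\] coupling the two transition-dipole
#' directions and the interdye displacement direction. Its average over
#' independent uniform orientations is 2/3 (the dynamic averaging
#' convention).
#'
#' @param mu_D donor dipole unit 3-vector, an `n x 3` matrix of unit rows,
#'   or a [dipole_frame()] (in which case the other arguments are ignored).
#' @param mu_A acceptor dipole unit 3-vector or `n x 3` matrix.
#' @param r_vec interdye displacement 3-vector or `n x 3` matrix (any
#'   positive magnitude; only its direction enters).
#' @param tol unit-norm validation tolerance.
#' @return Numeric vector of kappa^2 values in \[0, 4\].
#' @examples
#' kappa_squared(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))   # collinear: 4
#' kappa_squared(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))   # orthogonal: 0
#' @export
kappa_squared <- function(mu_D, mu_A = NULL, r_vec = NULL, tol = 1e-9) {
  if (inherits(mu_D, "dipole_frame")) {
    f <- mu_D
    mu_D <- f$mu_D; mu_A <- f$mu_A; r_vec <- f$r_vec
  }
  as_mat <- function(x, nm) {
    if (is.null(dim(x))) {
      if (length(x) != 3L) stop(nm, " must be a 3-vector or n x 3 matrix")
      matrix(as.numeric(x), 1L, 3L)
    } else {
      x <- as.matrix(x)
      if (ncol(x) != 3L) stop(nm, " must have 3 columns")
      x
    }
  }
  mu_D <- as_mat(mu_D, "mu_D"); mu_A <- as_mat(mu_A, "mu_A")
  r_vec <- as_mat(r_vec, "r_vec")
  n <- max(nrow(mu_D), nrow(mu_A), nrow(r_vec))
  rep_mat <- function(x) if (nrow(x) == n) x else x[rep(1L, n), , drop = FALSE]
  mu_D <- rep_mat(mu_D); mu_A <- rep_mat(mu_A); r_vec <- rep_mat(r_vec)
  nd <- sqrt(rowSums(mu_D^2)); na <- sqrt(rowSums(mu_A^2))
  if (any(abs(nd - 1) > tol) || any(abs(na - 1) > tol))
    stop("dipole vectors must be unit length (|norm - 1| <= tol)")
  rn <- sqrt(rowSums(r_vec^2))
  if (any(rn <= 0)) stop("r_vec rows must have positive magnitude")
  r_hat <- r_vec / rn
  cc <- rowSums(mu_D * mu_A) -
    3 * rowSums(r_hat * mu_D) * rowSums(r_hat * mu_A)
  k2 <- cc^2
  pmin(pmax(k2, 0), 4)
}

#' Forster transfer rate
#'
#' `k_ET = k_D * C * kappa2 / r^6` with `C = (3/2) R0_iso^6`, so at
#' `kappa2 = 2/3` and `r = R0_iso` the transfer rate equals `k_D`.
#'
#' @param r interdye distance (nm), vectorized.
#' @param kappa2 orientation factor, vectorized (recycled against `r`).
#' @param params [physical_params()].
#' @return Transfer rate(s) in 1/ns.
#' @export
forster_rate <- function(r, kappa2, params) {
  .assert_params(params)
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be > 0 (nm)")
  if (any(kappa2 < 0 | kappa2 > 4)) stop("kappa2 must lie in [0, 4]")
  params$k_D * params$C * kappa2 / r^6
}

#' Static (time-homogeneous) FRET efficiency
#'
#' `E = 1 / ((r/R0_iso)^6 + 1)` under the isotropic `kappa2 = 2/3`
#' convention; equals 0.5 at `r = R0_iso` by definition of the Forster
#' radius.
#'
#' @param r interdye distance (nm), `r >= 0`, vectorized.
#' @param params [physical_params()].
#' @return Efficiency in (0, 1\] (`r = 0` gives 1).
#' @export
efficiency_static <- function(r, params) {
  .assert_params(params)
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be >= 0 (nm)")
  1 / ((r / params$R0_iso)^6 + 1)
}

#' Path-dependent FRET efficiency
#'
#' For a time-varying hazard the transfer probability depends on the whole
#' history: `E(T) = Lambda(T) / (Lambda(T) + k_D * T)` where
#' `Lambda(T) = integral_0^T k_ET(s) ds` is evaluated by trapezoid
#' quadrature on the stored grid with linear interpolation of the hazard
#' for off-grid `T`.
#'
#' @param path a [rate_path()].
#' @param T evaluation time (ns), in `(0, max(t_grid)]`, vectorized.
#' @param params [physical_params()].
#' @return Efficiency value(s) in \[0, 1).
#' @export
efficiency_path <- function(path, T, params) {
  if (!inherits(path, "rate_path")) stop("`path` must be a rate_path object")
  .assert_params(params)
  if (any(T <= 0)) stop("T must be > 0")
  vapply(T, function(Ti) {
    L <- .lambda_at(path, Ti)
    L / (L + params$k_D * Ti)
  }, numeric(1))
}

#' Intensity-based FRET efficiency estimator
#'
#' `E_I = I_A / (I_A + I_D)` from detected photon counts.
#'
#' @param I_A acceptor-channel counts (nonnegative integers), vectorized.
#' @param I_D donor-channel counts (nonnegative integers), vectorized.
#' @return Efficiency estimate(s) in \[0, 1\].
#' @export
efficiency_intensity <- function(I_A, I_D) {
  if (any(I_A < 0) || any(I_D < 0)) stop("counts must be nonnegative")
  if (any(abs(I_A - round(I_A)) > 1e-8) || any(abs(I_D - round(I_D)) > 1e-8))
    stop("counts must be integers")
  tot <- I_A + I_D
  if (any(tot < 1)) stop("empty burst: I_A + I_D must be >= 1 (filter upstream)")
  I_A / tot
}

#' Lifetime-based FRET efficiency estimator
#'
#' `E = 1 - tau_DA / tau_D0`, where `tau_DA` is the donor lifetime in the
#' presence of the acceptor. Deliberately not clipped to \[0, 1\]: noisy
#' estimates may be negative, and clipping would distort shot-noise
#' structure downstream.
#'
#' @param tau_DA donor lifetime with acceptor present (ns), vectorized.
#' @param tau_D0 donor-only lifetime (ns).
#' @return Efficiency value(s) in `(-Inf, 1]`.
#' @export
efficiency_lifetime <- function(tau_DA, tau_D0) {
  if (length(tau_D0) != 1L || !is.finite(tau_D0) || tau_D0 <= 0)
    stop("tau_D0 must be a positive scalar (ns)")
  if (any(tau_DA < 0)) stop("tau_DA must be >= 0")
  1 - tau_DA / tau_D0
}

#' Mixture lifetimes and the Jensen's-inequality bound
#'
#' For a mixture of decay rates `k_i` with weights `w_i`, the average
#' lifetime is `tau_bar = sum(w_i / k_i)` while the lifetime of the average
#' rate is `tau_under = 1 / sum(w_i * k_i)`. Convexity of `1/x` guarantees
#' `tau_under <= tau_bar`; the gap is the lifetime signature of state
#' mixing (the dynamic shift).
#'
#' @param rates positive decay rates (1/ns).
#' @param weights probability weights summing to 1 (default uniform).
#' @return List with `tau_bar` and `tau_under` (ns).
#' @examples
#' jensen_lifetimes(c(1, 3))   # tau_bar = 2/3, tau_under = 1/2
#' @export
jensen_lifetimes <- function(rates, weights = NULL) {
  rates <- as.numeric(rates)
  if (length(rates) < 1L || any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be positive and finite")
  if (is.null(weights)) weights <- rep(1 / length(rates), length(rates))
  weights <- as.numeric(weights)
  if (length(weights) != length(rates))
    stop("weights must match rates in length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  tau_bar <- sum(weights / rates)
  tau_under <- 1 / sum(weights * rates)
  list(tau_bar = tau_bar, tau_under = tau_under)
}
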