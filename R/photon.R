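# Photon engine: transfer-time sampling along hazard paths, per-excitation
# competing risks, burst assembly with detection losses, and full
# experiment orchestration.

#' Burst simulation configuration
#'
#' @param n_excitations excitation events per burst (fixed count; diffusion
#'   through the confocal volume is not modeled).
#' @param det_eff_D,det_eff_A per-channel detection efficiencies in
#'   \[0, 1\] (independent Bernoulli thinning per photon). Defaults are
#'   equal so that photon loss adds shot noise without an uncorrected
#'   spectral bias (see the vignette).
#' @param min_photons bursts with fewer detected photons are flagged
#'   excluded.
#' @param dt_factor fine-grid step is `tau_D0 / dt_factor`.
#' @param horizon_factor censoring horizon is `horizon_factor * tau_D0`.
#' @param freeze_translation if TRUE the dyes are pinned at their
#'   equilibrium positions (shot-noise-only reference regime).
#' @param burn_in_ns,burn_dt_ns pendulum stationary-draw burn-in length and
#'   step (ns).
#' @return Object of class `burst_config`.
#' @export
burst_config <- function(n_excitations = 1000, det_eff_D = 0.375,
                         det_eff_A = 0.375, min_photons = 30,
                         dt_factor = 200, horizon_factor = 10,
                         freeze_translation = FALSE,
                         burn_in_ns = 1000, burn_dt_ns = 0.05) {
  if (n_excitations < 1) stop("n_excitations must be >= 1")
  if (det_eff_D < 0 || det_eff_D > 1 || det_eff_A < 0 || det_eff_A > 1)
    stop("detection efficiencies must lie in [0, 1]")
  if (min_photons < 0) stop("min_photons must be >= 0")
  if (dt_factor < 10) stop("dt_factor must be >= 10")
  if (horizon_factor <= 0) stop("horizon_factor must be > 0")
  structure(list(n_excitations = as.integer(n_excitations),
                 det_eff_D = det_eff_D, det_eff_A = det_eff_A,
                 min_photons = as.integer(min_photons),
                 dt_factor = dt_factor, horizon_factor = horizon_factor,
                 freeze_translation = isTRUE(freeze_translation),
                 burn_in_ns = burn_in_ns, burn_dt_ns = burn_dt_ns),
            class = "burst_config")
}

#' Derive a deterministic substream seed
#'
#' Maps (master seed, stream id, index) to a 32-bit seed; used for
#' per-burst substreams so any burst is reproducible in isolation. All
#' intermediate terms stay far below 2^53, so the arithmetic is exact in
#' doubles.
#'
#' @param master master integer seed.
#' @param stream small integer stream identifier.
#' @param i index within the stream (e.g. burst number).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, stream, i = 0L) {
  master <- as.numeric(master) %% 2147483647
  s <- (master * 69069 + as.numeric(stream) * 1013904223 +
          as.numeric(i) * 97003) %% 2147483563
  as.integer(s + 1)
}

#' Sample a transfer time along an inhomogeneous hazard path
#'
#' First-event times of the inhomogeneous transfer process: with
#' `u ~ Exp(1)`, the event time solves `Lambda(t*) = u`, found by monotone
#' inversion of the cumulative trapezoid integral (piecewise-quadratic in
#' each grid interval). Draws with `u > Lambda(t_max)` are censored and
#' returned as `Inf`. `method = "thinning"` instead uses Ogata thinning
#' with bound `max(k_ET)`; the two samplers agree in distribution and
#' cross-validate each other.
#'
#' @param path a [rate_path()].
#' @param n number of independent draws.
#' @param seed optional integer seed.
#' @param method `"inversion"` (default) or `"thinning"`.
#' @return Numeric vector of event times (ns), `Inf` when censored at the
#'   end of the grid.
#' @export
sample_transfer_time <- function(path, n = 1, seed = NULL,
                                 method = c("inversion", "thinning")) {
  if (!inherits(path, "rate_path")) stop("`path` must be a rate_path")
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  tg <- path$t_grid; k <- path$k_ET; L <- path$Lambda
  m <- length(tg)
  if (method == "inversion") {
    u <- rexp(n)
    out <- rep(Inf, n)
    idx <- which(u <= L[m])
    if (length(idx)) {
      iv <- findInterval(u[idx], L, rightmost.closed = TRUE)
      iv[iv >= m] <- m - 1L
      d <- tg[iv + 1L] - tg[iv]
      a <- (k[iv + 1L] - k[iv]) / (2 * d)
      b <- k[iv]
      cc <- L[iv] - u[idx]
      s <- ifelse(abs(a) < 1e-14 * (abs(b) + 1),
                  ifelse(b > 0, -cc / b, d),
                  (-b + sqrt(pmax(b^2 - 4 * a * cc, 0))) / (2 * a))
      out[idx] <- tg[iv] + pmin(pmax(s, 0), d)
    }
    out
  } else {
    M <- max(k)
    tmax <- tg[m]
    kfun <- stats::approxfun(tg, k, rule = 2)
    out <- numeric(n)
    for (i in seq_len(n)) {
      t <- 0
      repeat {
        if (M <= 0) { t <- Inf; break }
        t <- t + rexp(1, M)
        if (t > tmax) { t <- Inf; break }
        if (runif(1) < kfun(t) / M) break
      }
      out[i] <- t
    }
    out
  }
}

#' Simulate excitation events along given dynamics paths
#'
#' Competing-risks resolution of one (or `n` independent) excitation
#' event(s) along a supplied orientation/distance history: homogeneous
#' donor decay at rate `k_D` versus the inhomogeneous transfer hazard
#' `k_ET(t) = k_D C kappa2(t) / r(t)^6`. If transfer wins, the acceptor
#' emits after an additional `Exp(k_A)` residence. Under
#' `kappa2_mode = "static"` the orientation factor is frozen at 2/3 for
#' the whole event.
#'
#' @param t_grid time grid covering at least the censoring horizon (ns).
#' @param r interdye distance path on the grid (nm).
#' @param kappa2 orientation-factor path (required for `"dynamic"`).
#' @param params [physical_params()].
#' @param kappa2_mode `"dynamic"` or `"static"`.
#' @param horizon censoring horizon (ns), default `10 * tau_D0`.
#' @param n number of independent events sharing the same paths.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `outcome`
#'   (`"donor"`/`"acceptor"`/`"censored"`), `delay` (ns, NA when censored)
#'   and `transfer_time` (ns, NA unless transfer occurred).
#' @export
simulate_excitation <- function(t_grid, r, kappa2 = NULL, params,
                                kappa2_mode = c("dynamic", "static"),
                                horizon = NULL, n = 1, seed = NULL) {
  .assert_params(params)
  kappa2_mode <- match.arg(kappa2_mode)
  if (is.null(horizon)) horizon <- 10 * params$tau_D0
  t_grid <- .check_grid(t_grid)
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (max(t_grid) < horizon)
    stop("paths must cover the censoring horizon")
  if (kappa2_mode == "static") {
    kappa2 <- rep(2 / 3, length(t_grid))
  } else if (is.null(kappa2)) {
    stop("kappa2 path required in dynamic mode")
  }
  path <- rate_path(t_grid, kappa2 = kappa2, r = r, params = params)
  if (!is.null(seed)) set.seed(seed)
  T_D <- rexp(n, params$k_D)
  t_et <- sample_transfer_time(path, n = n)
  outcome <- rep("censored", n)
  delay <- rep(NA_real_, n)
  ttr <- rep(NA_real_, n)
  don <- T_D <= horizon & T_D <= t_et
  acc <- t_et < T_D & t_et <= horizon
  outcome[don] <- "donor"; delay[don] <- T_D[don]
  outcome[acc] <- "acceptor"
  ttr[acc] <- t_et[acc]
  delay[acc] <- t_et[acc] + rexp(sum(acc), params$k_A)
  data.frame(outcome = outcome, delay = delay, transfer_time = ttr)
}

# -- internal: assemble kernel arguments for one model ----------------------

.zero_pend <- c(1, 1, 0, 0, 0, 0)

.model_setup <- function(model, params, config,
                         spring_D = NULL, spring_A = NULL,
                         pendulum_D = NULL, pendulum_A = NULL,
                         rotation_D = NULL, rotation_A = NULL,
                         attach_sep = NULL, anisotropy_p = 0.5) {
  # default geometry: mean interdye distance ~ R0_iso. The pendulum wobble
  # inflates the mean distance by ~0.5 nm over the attachment separation,
  # so its attachments sit closer.
  if (is.null(attach_sep))
    attach_sep <- if (model == "pendulum") params$R0_iso - 0.5 else params$R0_iso
  attach_D <- c(0, 0, 0)
  attach_A <- c(0, 0, attach_sep)
  if (model %in% c("iso_spring", "aniso_spring", "frozen")) {
    if (is.null(spring_D)) {
      spring_D <- switch(model,
        iso_spring = spring_spec(x_eq = attach_D),
        aniso_spring = spring_spec(anisotropy_p = anisotropy_p,
                                   soft_axes = c(1L, 2L), x_eq = attach_D),
        frozen = spring_spec(sigma = 0, x_eq = attach_D))
    }
    if (is.null(spring_A)) {
      spring_A <- switch(model,
        iso_spring = spring_spec(x_eq = attach_A),
        # soft planes of the two stationary ellipsoids mutually orthogonal
        aniso_spring = spring_spec(anisotropy_p = anisotropy_p,
                                   soft_axes = c(2L, 3L), x_eq = attach_A),
        frozen = spring_spec(sigma = 0, x_eq = attach_A))
    }
    if (config$freeze_translation) {
      spring_D$sigma <- 0; spring_A$sigma <- 0
      spring_D$stationary_sd <- rep(0, 3); spring_A$stationary_sd <- rep(0, 3)
    }
    list(model_code = 0L, attach_D = attach_D, attach_A = attach_A,
         spring_D = spring_D, spring_A = spring_A,
         pend_D = .zero_pend, pend_A = .zero_pend,
         rotation_D = rotation_D %||% rotational_spec(),
         rotation_A = rotation_A %||% rotational_spec())
  } else if (model == "pendulum") {
    if (is.null(pendulum_D)) pendulum_D <- pendulum_spec()
    if (is.null(pendulum_A)) pendulum_A <- pendulum_spec()
    if (config$freeze_translation) {
      for (nm in c("sigma_r", "sigma_theta", "sigma_phi")) {
        pendulum_D[[nm]] <- 0; pendulum_A[[nm]] <- 0
      }
    }
    list(model_code = 1L, attach_D = attach_D, attach_A = attach_A,
         pendulum_D = pendulum_D, pendulum_A = pendulum_A,
         pend_D = with(pendulum_D, c(k_r, r_eq, k_theta, sigma_r,
                                     sigma_theta, sigma_phi)),
         pend_A = with(pendulum_A, c(k_r, r_eq, k_theta, sigma_r,
                                     sigma_theta, sigma_phi)),
         rotation_D = rotation_D %||% rotational_spec(),
         rotation_A = rotation_A %||% rotational_spec())
  } else stop("unknown model: ", model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stationary (or burn-in) initial translational state for one dye
.init_state <- function(setup, which = c("D", "A"), config) {
  which <- match.arg(which)
  if (setup$model_code == 0L) {
    sp <- if (which == "D") setup$spring_D else setup$spring_A
    if (sp$sigma == 0) sp$x_eq else sp$x_eq + rnorm(3) * sp$stationary_sd
  } else {
    ps <- if (which == "D") setup$pendulum_D else setup$pendulum_A
    s0 <- c(ps$r_eq, acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    if (ps$sigma_r == 0 && ps$sigma_theta == 0 && ps$sigma_phi == 0)
      return(c(ps$r_eq, 1e-5, 0))
    nb <- max(2L, ceiling(config$burn_in_ns / config$burn_dt_ns))
    grid <- seq(0, config$burn_in_ns, length.out = nb + 1L)
    pars <- c(ps$k_r, ps$r_eq, ps$k_theta,
              ps$sigma_r, ps$sigma_theta, ps$sigma_phi)
    m <- cpp_pendulum_path(s0, pars, grid)
    m[nrow(m), ]
  }
}

#' Simulate a single burst
#'
#' One burst of `n_excitations` donor excitation cycles: a fresh
#' translational state is drawn from the model's stationary law (springs:
#' exact Gaussian; pendulum: burn-in), dipoles are resampled uniformly per
#' excitation in dynamic mode, each excitation is resolved by the
#' competing-risks engine on a fine grid (`dt = tau_D0 / dt_factor`), and
#' detection losses are applied by Bernoulli thinning. Summary statistics
#' use detected photons only; the lifetime estimator uses detected donor
#' photons only.
#'
#' @param model one of `"iso_spring"`, `"aniso_spring"`, `"pendulum"`.
#' @param kappa2_mode `"static"` (kappa2 frozen at 2/3) or `"dynamic"`.
#' @param params [physical_params()].
#' @param config [burst_config()].
#' @param seed integer seed for this burst.
#' @param burst_id identifier recorded in the outputs.
#' @param ... model specification overrides passed to the internal setup:
#'   `spring_D`, `spring_A`, `pendulum_D`, `pendulum_A`, `rotation_D`,
#'   `rotation_A`, `attach_sep`, `anisotropy_p`.
#' @return List with `summary` (one-row data.frame: `burst_id, I_D, I_A,
#'   E_I, tau_norm, mean_kappa2, n_excitations, n_censored, excluded`) and
#'   `photons` (per-photon data.frame: `burst_id, channel, delay_ns,
#'   detected`).
#' @export
simulate_burst <- function(model = c("iso_spring", "aniso_spring", "pendulum"),
                           kappa2_mode = c("static", "dynamic"),
                           params = physical_params(),
                           config = burst_config(), seed = NULL,
                           burst_id = 1L, ...) {
  model <- match.arg(model)
  kappa2_mode <- match.arg(kappa2_mode)
  .assert_params(params)
  if (!inherits(config, "burst_config")) stop("`config` must be a burst_config")
  if (!is.null(seed)) set.seed(seed)
  setup <- .model_setup(model, params, config, ...)
  s0D <- .init_state(setup, "D", config)
  s0A <- .init_state(setup, "A", config)
  res <- .run_burst_kernel(setup, s0D, s0A, kappa2_mode, params, config)
  list(summary = .summarize_burst(res, burst_id, params, config),
       photons = .photon_records(res, burst_id))
}

.run_burst_kernel <- function(setup, s0D, s0A, kappa2_mode, params, config) {
  dynamic <- identical(kappa2_mode, "dynamic")
  if (setup$model_code == 0L) {
    spD <- setup$spring_D; spA <- setup$spring_A
    kD3 <- spD$k; kA3 <- spA$k
    xeD <- spD$x_eq; xeA <- spA$x_eq
    sgD <- spD$sigma; sgA <- spA$sigma
  } else {
    kD3 <- kA3 <- c(1, 1, 1); xeD <- xeA <- c(0, 0, 0); sgD <- sgA <- 0
  }
  cpp_simulate_burst(setup$model_code, dynamic,
                     as.numeric(s0D), as.numeric(s0A),
                     setup$attach_D, setup$attach_A,
                     kD3, kA3, xeD, xeA, sgD, sgA,
                     setup$pend_D, setup$pend_A,
                     setup$rotation_D$D_rot, setup$rotation_A$D_rot,
                     params$k_D, params$k_A, params$C, 2 / 3,
                     config$n_excitations,
                     params$tau_D0 / config$dt_factor,
                     config$horizon_factor * params$tau_D0,
                     config$det_eff_D, config$det_eff_A)
}

.summarize_burst <- function(res, burst_id, params, config) {
  don <- res$outcome == 0L & res$detected
  acc <- res$outcome == 1L & res$detected
  I_D <- sum(don); I_A <- sum(acc)
  E_I <- if (I_D + I_A >= 1) I_A / (I_A + I_D) else NA_real_
  tau_norm <- if (I_D >= 1) mean(res$delay[don]) / params$tau_D0 else NA_real_
  data.frame(burst_id = burst_id, I_D = I_D, I_A = I_A, E_I = E_I,
             tau_norm = tau_norm, mean_kappa2 = mean(res$kbar),
             n_excitations = length(res$outcome),
             n_censored = sum(res$outcome == 2L),
             excluded = (I_D + I_A) < config$min_photons || I_D < 1)
}

.photon_records <- function(res, burst_id) {
  emit <- res$outcome != 2L
  data.frame(burst_id = burst_id,
             channel = c("donor", "acceptor")[res$outcome[emit] + 1L],
             delay_ns = res$delay[emit],
             detected = res$detected[emit])
}

#' Run a simulated smFRET experiment
#'
#' Simulates `n_bursts` independent bursts for one dye model and
#' orientation-factor mode, with deterministic per-burst seed substreams
#' derived from the master seed (any burst is reproducible in isolation
#' via `derive_seed`).
#'
#' @inheritParams simulate_burst
#' @param n_bursts number of bursts.
#' @param seed master integer seed.
#' @param record_photons keep the per-photon stream (as attribute
#'   `"photons"` of the result).
#' @return A `data.frame` of class `burst_table`, one row per burst with
#'   columns `burst_id, I_D, I_A, E_I, tau_norm, mean_kappa2,
#'   n_excitations, n_censored, excluded`; attributes `model`,
#'   `kappa2_mode`, `params`, `seed` (and `photons` if requested).
#' @examples
#' \donttest{
#' tab <- run_experiment("iso_spring", "static", n_bursts = 20, seed = 7,
#'                       config = burst_config(n_excitations = 200))
#' shift_distribution(tab)
#' }
#' @export
run_experiment <- function(model = c("iso_spring", "aniso_spring", "pendulum"),
                           kappa2_mode = c("static", "dynamic"),
                           n_bursts = 1000, params = physical_params(),
                           config = burst_config(), seed = 1L,
                           record_photons = FALSE, ...) {
  model <- match.arg(model)
  kappa2_mode <- match.arg(kappa2_mode)
  .assert_params(params)
  if (n_bursts < 1) stop("n_bursts must be >= 1")
  setup <- .model_setup(model, params, config, ...)
  rows <- vector("list", n_bursts)
  phot <- if (record_photons) vector("list", n_bursts) else NULL
  for (b in seq_len(n_bursts)) {
    set.seed(derive_seed(seed, 1L, b))
    s0D <- .init_state(setup, "D", config)
    s0A <- .init_state(setup, "A", config)
    res <- .run_burst_kernel(setup, s0D, s0A, kappa2_mode, params, config)
    rows[[b]] <- .summarize_burst(res, b, params, config)
    if (record_photons) phot[[b]] <- .photon_records(res, b)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("burst_table", "data.frame")
  attr(out, "model") <- model
  attr(out, "kappa2_mode") <- kappa2_mode
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  if (record_photons) attr(out, "photons") <- do.call(rbind, phot)
  out
}
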