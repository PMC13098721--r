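# Experiment configuration: schema-validated JSON with explicit defaults,
# presets for the documented parameter sets, and lossless round-tripping.

.default_config <- function() {
  list(
    model = "iso_spring",
    kappa2_mode = "static",
    n_bursts = 1000L,
    seed = 1L,
    physical = list(k_D = 0.25, k_A = 0.5, R0_iso = 5),
    linker = list(N_links = 15L),
    spring = list(k_rate = 0.005, sigma = 0.05, anisotropy_p = 0.5),
    pendulum = list(k_r = 0.0025, r_eq = NULL, k_theta = 0.002,
                    sigma_r = 0.021, sigma_theta = 0.09, sigma_phi = 0.09),
    rotation = list(D_rot_D = 0.001, D_rot_A = 0.001,
                    nu_mPas = 0.89, R_h_nm = 0.8, T_K = 298,
                    paper_units_D = NULL, paper_units_A = NULL,
                    paper_unit_scale = 1e-3),
    burst = list(n_excitations = 1000L, det_eff_D = 0.375,
                 det_eff_A = 0.375, min_photons = 30L, dt_factor = 200,
                 horizon_factor = 10, freeze_translation = FALSE),
    attach_sep = NULL
  )
}

.config_field_checks <- list(
  model = function(v) v %in% c("iso_spring", "aniso_spring", "pendulum"),
  kappa2_mode = function(v) v %in% c("static", "dynamic"),
  n_bursts = function(v) is.numeric(v) && v >= 1,
  seed = function(v) is.numeric(v) && v == round(v)
)

.check_positive <- function(cfg, path, allow_zero = FALSE, allow_null = FALSE) {
  v <- cfg
  for (p in path) v <- v[[p]]
  nm <- paste(path, collapse = ".")
  if (is.null(v)) {
    if (allow_null) return(invisible(TRUE))
    stop("config field `", nm, "` is missing")
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("config field `", nm, "` must be a finite number")
  if (v < 0 || (!allow_zero && v == 0))
    stop("config field `", nm, "` must be ",
         if (allow_zero) ">= 0" else "> 0", " (got ", v, ")")
  invisible(TRUE)
}

# recursive merge of user values over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(prefix, nm, "."))
    } else {
      defaults[nm] <- list(user[[nm]])   # list() form: JSON null clears a field
    }
  }
  defaults
}

#' Validate an experiment configuration
#'
#' Checks enumerations, positivity and range constraints; error messages
#' name the offending field.
#'
#' @param cfg configuration list (all defaults materialized).
#' @return The validated config, invisibly classed `experiment_config`.
#' @export
validate_config <- function(cfg) {
  for (nm in names(.config_field_checks)) {
    if (!.config_field_checks[[nm]](cfg[[nm]]))
      stop("config field `", nm, "` is invalid (got ",
           deparse(cfg[[nm]]), ")")
  }
  .check_positive(cfg, c("physical", "k_D"))
  .check_positive(cfg, c("physical", "k_A"))
  .check_positive(cfg, c("physical", "R0_iso"))
  .check_positive(cfg, c("linker", "N_links"))
  .check_positive(cfg, c("spring", "k_rate"))
  .check_positive(cfg, c("spring", "sigma"), allow_zero = TRUE)
  p <- cfg$spring$anisotropy_p
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("config field `spring.anisotropy_p` must lie in [0, 1]")
  .check_positive(cfg, c("pendulum", "k_r"))
  .check_positive(cfg, c("pendulum", "r_eq"), allow_null = TRUE)
  .check_positive(cfg, c("pendulum", "k_theta"), allow_zero = TRUE)
  for (nm in c("sigma_r", "sigma_theta", "sigma_phi"))
    .check_positive(cfg, c("pendulum", nm), allow_zero = TRUE)
  .check_positive(cfg, c("rotation", "D_rot_D"), allow_zero = TRUE,
                  allow_null = TRUE)
  .check_positive(cfg, c("rotation", "D_rot_A"), allow_zero = TRUE,
                  allow_null = TRUE)
  .check_positive(cfg, c("rotation", "nu_mPas"))
  .check_positive(cfg, c("rotation", "R_h_nm"))
  .check_positive(cfg, c("rotation", "T_K"))
  .check_positive(cfg, c("burst", "n_excitations"))
  for (nm in c("det_eff_D", "det_eff_A")) {
    v <- cfg$burst[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config field `burst.", nm, "` must lie in [0, 1]")
  }
  .check_positive(cfg, c("burst", "min_photons"), allow_zero = TRUE)
  .check_positive(cfg, c("burst", "dt_factor"))
  .check_positive(cfg, c("burst", "horizon_factor"))
  .check_positive(cfg, c("attach_sep"), allow_null = TRUE)
  structure(cfg, class = "experiment_config")
}

#' Load an experiment configuration from JSON
#'
#' Reads a JSON config file, fills every unspecified field with its
#' documented default, rejects unknown keys, and validates ranges. A
#' minimal file like `{"model": "pendulum"}` is valid.
#'
#' @param path JSON file path.
#' @return Validated config of class `experiment_config` with all defaults
#'   materialized.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(.merge_config(.default_config(), user))
}

#' Load a named preset configuration
#'
#' Presets live as versioned JSON files under the package's
#' `extdata/presets` directory: the three dye-model panels
#' (`iso_spring`, `aniso_spring`, `pendulum`, `pendulum_dynamic`) and the
#' printed rotational-diffusion parameter sets (`fig7a`, `fig7b`,
#' `fig7c`, exposed verbatim in the source's units via
#' `rotation.paper_units_*`).
#'
#' @param name preset name.
#' @return Validated `experiment_config`.
#' @export
preset_config <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "smfretsim")
  if (!nzchar(path)) {
    avail <- sub("\\.json$", "",
                 list.files(system.file("extdata", "presets",
                                        package = "smfretsim")))
    stop("unknown preset `", name, "`; available: ",
         paste(avail, collapse = ", "))
  }
  load_config(path)
}

#' Serialize a configuration to JSON
#'
#' Every default is explicit in the serialized form, so configs round-trip
#' losslessly through [load_config()].
#'
#' @param cfg an `experiment_config`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# 32-bit FNV-1a over the canonical JSON serialization, with exact modular
# arithmetic in doubles (split multiply keeps products below 2^53)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536; hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))    # xor touches low byte only
    h <- hi * 65536 + lo
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# materialize R objects from a validated config
.config_objects <- function(cfg) {
  params <- physical_params(cfg$physical$k_D, cfg$physical$k_A,
                            cfg$physical$R0_iso)
  linker <- linker_from_chemistry(cfg$linker$N_links)
  r_eq <- cfg$pendulum$r_eq %||% linker$contour_length
  scale <- cfg$rotation$paper_unit_scale
  D_D <- cfg$rotation$D_rot_D %||%
    (if (!is.null(cfg$rotation$paper_units_D))
       cfg$rotation$paper_units_D * scale
     else rotational_diffusion_from_hydro(cfg$rotation$nu_mPas,
                                          cfg$rotation$R_h_nm,
                                          T_K = cfg$rotation$T_K))
  D_A <- cfg$rotation$D_rot_A %||%
    (if (!is.null(cfg$rotation$paper_units_A))
       cfg$rotation$paper_units_A * scale
     else rotational_diffusion_from_hydro(cfg$rotation$nu_mPas,
                                          cfg$rotation$R_h_nm,
                                          T_K = cfg$rotation$T_K))
  list(
    params = params,
    linker = linker,
    config = burst_config(cfg$burst$n_excitations, cfg$burst$det_eff_D,
                          cfg$burst$det_eff_A, cfg$burst$min_photons,
                          cfg$burst$dt_factor, cfg$burst$horizon_factor,
                          cfg$burst$freeze_translation),
    pendulum = pendulum_spec(cfg$pendulum$k_r, r_eq, cfg$pendulum$k_theta,
                             cfg$pendulum$sigma_r, cfg$pendulum$sigma_theta,
                             cfg$pendulum$sigma_phi),
    rotation_D = rotational_spec(D_rot = D_D),
    rotation_A = rotational_spec(D_rot = D_A),
    spring = cfg$spring,
    attach_sep = cfg$attach_sep
  )
}

#' Run the experiment described by a configuration
#'
#' @param cfg an `experiment_config` (from [load_config()] /
#'   [preset_config()]), or a path to a JSON config file.
#' @param n_bursts,seed optional overrides of the config values.
#' @param record_photons keep the photon-level stream.
#' @return A `burst_table`, as from [run_experiment()].
#' @export
run_config <- function(cfg, n_bursts = NULL, seed = NULL,
                       record_photons = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  if (!inherits(cfg, "experiment_config"))
    stop("`cfg` must be an experiment_config or a file path")
  ob <- .config_objects(cfg)
  sp <- cfg$spring
  sep <- cfg$attach_sep %||% ob$params$R0_iso
  spring_D <- switch(cfg$model,
    iso_spring = spring_spec(sp$k_rate, sp$sigma, x_eq = c(0, 0, 0)),
    aniso_spring = spring_spec(sp$k_rate, sp$sigma,
                               anisotropy_p = sp$anisotropy_p,
                               soft_axes = c(1L, 2L), x_eq = c(0, 0, 0)),
    NULL)
  spring_A <- switch(cfg$model,
    iso_spring = spring_spec(sp$k_rate, sp$sigma, x_eq = c(0, 0, sep)),
    aniso_spring = spring_spec(sp$k_rate, sp$sigma,
                               anisotropy_p = sp$anisotropy_p,
                               soft_axes = c(2L, 3L), x_eq = c(0, 0, sep)),
    NULL)
  run_experiment(
    model = cfg$model, kappa2_mode = cfg$kappa2_mode,
    n_bursts = n_bursts %||% cfg$n_bursts,
    params = ob$params, config = ob$config,
    seed = seed %||% cfg$seed,
    record_photons = record_photons,
    spring_D = spring_D, spring_A = spring_A,
    pendulum_D = ob$pendulum, pendulum_A = ob$pendulum,
    rotation_D = ob$rotation_D, rotation_A = ob$rotation_A,
    attach_sep = sep)
}
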