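# Delimited-text IO for burst tables and shift results, with provenance
# headers ('#'-prefixed comment lines: package version, config hash, seed).

.provenance_lines <- function(cfg = NULL, seed = NULL) {
  lines <- sprintf("# smfretsim %s", as.character(packageVersion("smfretsim")))
  if (!is.null(cfg)) lines <- c(lines, sprintf("# config_hash: %s",
                                               config_hash(cfg)))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d",
                                                as.integer(seed)))
  lines
}

#' Write a burst table as tab-separated text
#'
#' Header columns: `burst_id, I_D, I_A, E_I, tau_norm, mean_kappa2,
#' n_excitations, n_censored, excluded`, preceded by '#' provenance lines.
#' Output bytes are a pure function of the table and provenance inputs
#' (no timestamps), so reruns are byte-identical.
#'
#' @param tab a `burst_table` (or compatible data.frame).
#' @param path output path.
#' @param cfg optional `experiment_config` recorded as a hash.
#' @param seed optional seed recorded in the header.
#' @return Invisibly, the path.
#' @export
write_burst_table <- function(tab, path, cfg = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(cfg, seed %||% attr(tab, "seed")), con)
  write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a burst table written by [write_burst_table()]
#'
#' @param path input path.
#' @return A `burst_table` data.frame.
#' @export
read_burst_table <- function(path) {
  if (!file.exists(path)) stop("burst table not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("burst_id", "I_D", "I_A", "E_I", "tau_norm")
  if (!all(need %in% names(tab)))
    stop("not a burst table; missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  class(tab) <- c("burst_table", "data.frame")
  tab
}

#' Write a photon-level stream as tab-separated text
#'
#' Columns `burst_id, channel, delay_ns, detected`.
#'
#' @param photons photon data.frame (e.g. the `"photons"` attribute of a
#'   [run_experiment()] result).
#' @param path output path.
#' @param cfg,seed optional provenance.
#' @return Invisibly, the path.
#' @export
write_photon_stream <- function(photons, path, cfg = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(cfg, seed), con)
  write.table(photons, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write dynamic-shift results as tab-separated text
#'
#' Per-burst `delta` values followed by a '#'-prefixed summary line
#' `# summary: mu=<mu> sigma=<sigma> n=<n>`.
#'
#' @param shift a `shift_result` from [shift_distribution()].
#' @param path output path.
#' @param cfg,seed optional provenance.
#' @return Invisibly, the path.
#' @export
write_shift_result <- function(shift, path, cfg = NULL, seed = NULL) {
  stopifnot(inherits(shift, "shift_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(cfg, seed), con)
  writeLines(sprintf("# summary: mu=%.10g sigma=%.10g n=%d",
                     shift$mu_delta, shift$sigma_delta, shift$n), con)
  write.table(data.frame(delta = shift$delta), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate the deterministic toy fixtures used by the test suite
#'
#' Emits three small artifacts, byte-identical across runs with the same
#' seed: a 50-burst table from a shot-noise-only (frozen, static)
#' experiment, a short orientation-factor path sampled from paired dipole
#' diffusion, and a two-state reference table.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- physical_params()
  cfgb <- burst_config(n_excitations = 200, det_eff_D = 1, det_eff_A = 1,
                       min_photons = 10, freeze_translation = TRUE)
  tab <- run_experiment("iso_spring", "static", n_bursts = 50,
                        params = params, config = cfgb,
                        seed = derive_seed(seed, 10L))
  f1 <- file.path(dir, "bursts_50.tsv")
  write_burst_table(tab, f1, seed = derive_seed(seed, 10L))

  tg <- seq(0, 10, by = 0.05)
  set.seed(derive_seed(seed, 11L))
  muD <- simulate_dipole(0.3, c(0, 0, 1), tg)
  muA <- simulate_dipole(0.3, c(1, 0, 0), tg)
  k2 <- kappa_squared(muD, muA, matrix(rep(c(0, 0, 5), each = length(tg)),
                                       ncol = 3))
  f2 <- file.path(dir, "kappa2_path.tsv")
  con <- file(f2, "w")
  writeLines(.provenance_lines(seed = derive_seed(seed, 11L)), con)
  write.table(data.frame(time_ns = tg, kappa2 = k2), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  close(con)

  ts <- two_state_reference(two_state_spec(0.3, 0.7, 0.05), n_bursts = 50,
                            params = params,
                            config = burst_config(n_excitations = 200,
                                                  det_eff_D = 1,
                                                  det_eff_A = 1,
                                                  min_photons = 10),
                            seed = derive_seed(seed, 12L))
  f3 <- file.path(dir, "twostate_bursts.tsv")
  write_burst_table(ts, f3, seed = derive_seed(seed, 12L))
  c(bursts = f1, kappa2_path = f2, twostate = f3)
}
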