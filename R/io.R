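.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Read a long-form plate-reader CSV
#'
#' Expects columns `time_h`, `well`, `od`; times in hours, OD dimensionless.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("time_h", "well", "od"), paste0("plate CSV '", path, "'"))
  bad <- which(!is.finite(df$time_h) | df$time_h < 0)
  if (length(bad))
    stop("plate CSV '", path, "': negative or non-finite time_h at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$od))
  if (length(bad))
    stop("plate CSV '", path, "': non-finite od at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  df
}

#' Read a plate-map CSV
#'
#' Expects columns `well`, `strain_id`, `media_id`, `replicate`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_plate_map_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("well", "strain_id", "media_id", "replicate"),
                   paste0("plate map '", path, "'"))
  df
}

#' Write / read trajectory CSV
#'
#' Trajectory tables have columns `time_h`, `N_E`, `N_Y`, `N_B`, `cycle`
#' (hours and cells/mL).
#'
#' @param traj an `lv_trajectory` or trajectory data frame.
#' @param path CSV path.
#' @return `write_trajectory_csv`: the path, invisibly;
#'   `read_trajectory_csv`: an `lv_trajectory` data frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)[, c("time_h", "N_E", "N_Y", "N_B", "cycle")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("time_h", "N_E", "N_Y", "N_B", "cycle"),
                   paste0("trajectory CSV '", path, "'"))
  if (any(df$time_h < 0)) stop("trajectory CSV '", path, "': negative time_h")
  if (any(df[, c("N_E", "N_Y", "N_B")] < 0))
    stop("trajectory CSV '", path, "': negative populations")
  structure(df, class = c("lv_trajectory", "data.frame"))
}

#' Read a YAML run configuration
#'
#' Configuration schema (all blocks optional; defaults fill in): `species`
#' (per-role `r`, `K`, `N0`), `alphas` (six coefficients), `protocol`
#' (`cycle_hours`, `dilution_factor`, `n_cycles`, `equilibration_cycles`,
#' `invader_N0`), `model`, `integrator` (`rtol`, `atol`), `threshold`,
#' `seed`.
#'
#' @param path YAML path.
#' @return a validated configuration list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  default_config(raw)
}

#' Default run configuration
#'
#' @param override named list of settings layered over the defaults.
#' @return a `run_config` list.
#' @export
default_config <- function(override = list()) {
  cfg <- list(
    model = "freqdep",
    species = list(E = list(r = 0.7, K = 1e9, N0 = 1e7),
                   Y = list(r = 0.35, K = 1e8, N0 = 1e7),
                   B = list(r = 0.6, K = 1e9, N0 = 1e7)),
    alphas = as.list(setNames(rep(0.01, 6), .alpha_names)),
    protocol = list(cycle_hours = 24, dilution_factor = 2^-10, n_cycles = 7,
                    equilibration_cycles = 3, invader_N0 = 1e7),
    integrator = list(rtol = 1e-8, atol = 1e-3),
    threshold = 1e4,
    seed = 1L)
  cfg <- utils::modifyList(cfg, override)
  if (!cfg$model %in% c("freqdep", "classic"))
    stop("config: model must be 'freqdep' or 'classic'")
  for (role in c("E", "Y", "B")) {
    s <- cfg$species[[role]]
    if (is.null(s) || !all(c("r", "K", "N0") %in% names(s)))
      stop("config: species '", role, "' must define r, K, N0")
  }
  missing <- setdiff(.alpha_names, names(cfg$alphas))
  if (length(missing))
    stop("config: missing alpha(s): ", paste(missing, collapse = ", "))
  with(cfg$protocol, stopifnot(cycle_hours > 0, dilution_factor > 0,
                               dilution_factor <= 1, n_cycles >= 1))
  structure(cfg, class = "run_config")
}

#' Build a community model from a run configuration
#'
#' @param config a `run_config` (see [read_config()]).
#' @return an [lv_community()].
#' @export
config_community <- function(config) {
  num <- function(x) as.numeric(x)  # tolerate YAML scalars like "2.0e9"
  lv_community(
    E = species_params("E", num(config$species$E$r), num(config$species$E$K),
                       num(config$species$E$N0)),
    Y = species_params("Y", num(config$species$Y$r), num(config$species$Y$K),
                       num(config$species$Y$N0)),
    B = species_params("B", num(config$species$B$r), num(config$species$B$K),
                       num(config$species$B$N0)),
    alphas = do.call(interaction_matrix,
                     lapply(config$alphas[.alpha_names], num)),
    model = config$model)
}

#' Write a reproducibility manifest
#'
#' Records, next to every pipeline output, everything needed to reproduce
#' it: the command, input paths, the full configuration, the seed, and
#' package/R versions, plus an md5 of the configuration.
#'
#' @param path manifest path (JSON).
#' @param command subcommand or function name.
#' @param inputs named list/vector of input paths.
#' @param config configuration list.
#' @param seed RNG seed used.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, command, inputs = list(), config = list(),
                           seed = NA_integer_) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    command = command,
    inputs = inputs,
    config = config,
    config_md5 = unname(tools::md5sum(tf)),
    seed = seed,
    versions = list(lvtrio = as.character(packageVersion("lvtrio")),
                    R = R.version.string),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tf)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
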