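#' Load a model configuration from YAML
#'
#' The configuration file has up to five sections: `soil` (fields of
#' [soil_profile_params()]), `root` (`r0_cm`, `Em_mV`, `v0_cm3_s`),
#' `solutes` (path to a solute CSV, relative to the config file),
#' `numerics` (fields of [sim_settings()]), and `outputs` (`dir`).
#' Omitted numerics take the documented defaults; unknown keys raise an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path YAML (or JSON) configuration file.
#' @return A list of class `rhizo_config` with elements `soil`, `root`,
#'   `solutes`, `settings`, `outputs`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("soil", "root", "solutes", "numerics", "outputs")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config section(s): ",
                        paste(unknown, collapse = ", ")))
  }
  check_keys <- function(section, allowed) {
    bad <- setdiff(names(cfg[[section]]), allowed)
    if (length(bad) > 0) {
      rlang::abort(sprintf("unknown key(s) in section '%s': %s", section,
                           paste(bad, collapse = ", ")))
    }
  }
  check_keys("soil", names(formals(soil_profile_params)))
  soil <- do.call(soil_profile_params, cfg$soil %||% list())

  check_keys("root", c("r0_cm", "Em_mV", "v0_cm3_s"))
  rt <- cfg$root %||% list()
  root <- root_params(r0 = rt$r0_cm %||% 0.0641885,
                      Em = (rt$Em_mV %||% -120) / 1000,
                      v0 = rt$v0_cm3_s %||% 0)

  # numerics keys are suffixed with their units (and avoid the bare
  # YAML-boolean key "n")
  numerics_map <- c(n_annuli = "n", dr_cm = "dr", dt_s = "dt",
                    eq_rel_tol = "eq_rel_tol",
                    max_sim_time_s = "max_sim_time",
                    threshold_nmol = "threshold_nmol",
                    sorption = "sorption", retardation = "retardation",
                    secant = "secant", advection = "advection")
  check_keys("numerics", names(numerics_map))
  num <- cfg$numerics %||% list()
  names(num) <- numerics_map[names(num)]
  settings <- do.call(sim_settings, num)

  solutes <- NULL
  if (!is.null(cfg$solutes)) {
    sol_path <- cfg$solutes
    if (!file.exists(sol_path)) {
      sol_path <- file.path(dirname(path), cfg$solutes)
    }
    solutes <- read_solute_table(sol_path)
  }
  structure(list(soil = soil, root = root, solutes = solutes,
                 settings = settings,
                 outputs = cfg$outputs %||% list(dir = ".")),
            class = "rhizo_config")
}

#' Write simulation results to disk
#'
#' Serialises one or more equilibrium runs: a per-run radial profile CSV
#' (`r_cm`, concentration, sorbed and mineralized pools), a combined
#' summary table CSV with the quantities usually plotted against depth
#' (rhizoplane concentration, extent, efflux, influx, net exudation,
#' recapture), a summary JSON, and a manifest echoing the configuration.
#' All numbers are written at full precision.
#'
#' @param runs A list of `rhizo_sim` objects (or a single one).
#' @param dir Output directory (created if needed; must be writable —
#'   checked before anything is written).
#' @param stem File-name stem.
#' @return Invisibly, a character vector of the files written.
#' @export
write_results <- function(runs, dir = ".", stem = "rhizosim") {
  if (inherits(runs, "rhizo_sim")) runs <- list(runs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) {
    rlang::abort(sprintf("output directory '%s' is not writable", dir))
  }
  if (length(runs) == 0) {
    rlang::warn("empty result set; writing manifest only")
  }
  files <- character(0)
  summaries <- list()
  for (run in runs) {
    sm <- run$summary
    tag <- sprintf("%s_%s_d%03d", stem, sm$solute, round(sm$depth))
    prof_file <- file.path(dir, paste0(tag, "_profile.csv"))
    readr::write_csv(run$profile, prof_file)
    files <- c(files, prof_file)
    summaries <- c(summaries, list(sm))
  }
  if (length(summaries) > 0) {
    sweep_file <- file.path(dir, paste0(stem, "_summary.csv"))
    json_file <- file.path(dir, paste0(stem, "_summary.json"))
    all_sm <- dplyr::bind_rows(summaries)
    readr::write_csv(all_sm, sweep_file)
    jsonlite::write_json(all_sm, json_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, sweep_file, json_file)
  }
  manifest <- list(
    package = "rhizosim",
    version = as.character(utils::packageVersion("rhizosim")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = basename(files),
    runs = lapply(runs, function(run) {
      list(solute = as.list(run$solute), depth = run$depth,
           root = run$root[c("r0", "Em", "v0")],
           soil = unclass(run$soil), settings = unclass(run$settings),
           converged = run$summary$converged)
    })
  )
  man_file <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, man_file, auto_unbox = TRUE, digits = NA)
  files <- c(files, man_file)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
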