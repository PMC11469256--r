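#' Run a scenario end-to-end from a configuration file
#'
#' Reads a YAML config (see [write_config()]), builds the scenario, runs the
#' amplitude sweep, extracts features, and writes all artifacts to
#' `output_dir`: ensemble serialization, sweep CSV, features JSON, a run
#' manifest, and (optionally) a log-log sweep plot. Config plus seed fully
#' determine every numeric output.
#'
#' @param config_path path to the YAML configuration.
#' @param output_dir output directory (created if needed).
#' @param plot write `sweep.png` (convenience only; never an input to any
#'   computation).
#' @param quiet suppress progress messages.
#' @return the run manifest (named list), invisibly.
#' @export
run_scenario <- function(config_path, output_dir, plot = FALSE,
                         quiet = FALSE) {
  cfg <- read_config(config_path)
  spec <- config_to_spec(cfg)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  amplitudes <- if (!is.null(cfg$amplitudes)) as.numeric(cfg$amplitudes)
                else default_amplitudes()
  protocol <- shear_protocol(
    omega = cfg$omega %||% 0.05,
    n_cycles_total = cfg$n_cycles_total %||% 6,
    n_cycles_discard = cfg$n_cycles_discard %||% 2,
    dt = cfg$dt %||% 0.05)

  if (!quiet) message("building scenario '", spec$kind, "' (seed ", spec$seed, ")")
  ens <- build_scenario(spec)
  ens_prefix <- file.path(output_dir, "ensemble")
  write_ensemble(ens, ens_prefix)

  if (!quiet) message("running amplitude sweep (", length(amplitudes), " amplitudes)")
  warnings_log <- character(0)
  curve <- withCallingHandlers(
    amplitude_sweep(ens, amplitudes, protocol, label = spec$kind),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sweep_path <- file.path(output_dir, "sweep.csv")
  write_sweep(curve, sweep_path)

  feats <- extract_features(curve)
  undefined <- names(feats)[vapply(feats, function(v)
    length(v) == 1 && is.na(v), TRUE)]
  feats_path <- file.path(output_dir, "features.json")
  jsonlite::write_json(unclass(feats), feats_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")

  outputs <- c(ensemble_meta = paste0(ens_prefix, "_meta.json"),
               ensemble_elements = paste0(ens_prefix, "_elements.csv"),
               ensemble_bonds = paste0(ens_prefix, "_bonds.csv"),
               sweep = sweep_path, features = feats_path)
  if (plot) {
    png_path <- file.path(output_dir, "sweep.png")
    grDevices::png(png_path, width = 900, height = 700, res = 120)
    plot(curve, main = spec$kind)
    grDevices::dev.off()
    outputs <- c(outputs, plot = png_path)
  }
  manifest <- list(
    config = cfg,
    seed = spec$seed,
    version = as.character(utils::packageVersion("rheodem")),
    scenario_hash = scenario_hash(spec),
    outputs = as.list(outputs),
    stability_warnings = warnings_log,
    undefined_features = undefined,
    wall_time_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (!quiet) {
    for (w in warnings_log) message("stability warning: ", w)
    for (u in undefined) message("undefined feature: ", u)
  }
  invisible(manifest)
}

scenario_hash <- function(spec) {
  s <- paste(vapply(unclass(spec), function(v) paste(format(v, digits = 17),
                                                     collapse = ","), ""),
             collapse = "|")
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(substr(tools::md5sum(tf), 1, 12))
}

#' Compare amplitude sweeps against injectability targets
#'
#' Extracts the rheological feature set from each curve and flags it against
#' configurable design thresholds: relative yield stress at most
#' `max_relative_yield_stress` (injectability at acceptable stiffness) and
#' yield strain at least `min_yield_strain` (resilience to physiological
#' deformation). Curves sharing a scenario label are additionally summarized
#' as mean and standard deviation over replicates. Curves with undefined
#' features keep their row, with `NA` flags.
#'
#' @param curves list of `rheology_curve` objects, or paths to sweep CSVs.
#' @param max_relative_yield_stress threshold on `tau_y / G0'`.
#' @param min_yield_strain threshold on the yield strain.
#' @return list with `table` (one row per curve, features + pass/fail flags)
#'   and `summary` (per-scenario mean and SD of the numeric features).
#' @export
compare_scenarios <- function(curves, max_relative_yield_stress = 0.12,
                              min_yield_strain = 0.50) {
  if (inherits(curves, "rheology_curve")) curves <- list(curves)
  curves <- lapply(curves, function(cv)
    if (is.character(cv)) read_sweep(cv) else cv)
  if (length(curves) < 2)
    warning("fewer than 2 curves; comparison table is degenerate")
  rows <- lapply(curves, function(cv) {
    f <- extract_features(cv)
    data.frame(scenario = f$scenario, seed = f$seed, G0p = f$G0p,
               softening_onset_strain = f$softening_onset_strain,
               softening_depth = f$softening_depth,
               soft_plateau_stress = f$soft_plateau_stress,
               yield_strain = f$yield_strain, yield_stress = f$yield_stress,
               relative_yield_stress = f$relative_yield_stress)
  })
  tab <- do.call(rbind, rows)
  tab$pass_relative_yield_stress <-
    tab$relative_yield_stress <= max_relative_yield_stress
  tab$pass_yield_strain <- tab$yield_strain >= min_yield_strain
  num <- c("G0p", "softening_onset_strain", "softening_depth",
           "soft_plateau_stress", "yield_strain", "yield_stress",
           "relative_yield_stress")
  agg <- lapply(split(tab[num], tab$scenario), function(g) {
    row <- list(n = nrow(g))
    for (nm in num) {
      row[[paste0(nm, "_mean")]] <- mean(g[[nm]])
      row[[paste0(nm, "_sd")]] <- stats::sd(g[[nm]])
    }
    as.data.frame(row)
  })
  summary <- do.call(rbind, agg)
  summary <- cbind(scenario = names(agg), summary)
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}
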