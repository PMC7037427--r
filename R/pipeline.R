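#' Pipeline configuration
#'
#' Collects the assay constants and analysis settings shared by all stages.
#' Defaults are the published assay conditions: dopachrome molar
#' absorptivity 3700 M^-1 cm^-1, 0.3 cm path, an eight-minute
#' initial-velocity window, four assay temperatures, the doubling L-DOPA
#' series, and a 6 Angstrom copper-proximity cutoff for pose filtering.
#' The gas constant is fixed at 8.314 J/(K mol) and is not configurable.
#'
#' @param epsilon_M_cm molar absorptivity (M^-1 cm^-1).
#' @param path_cm optical path (cm).
#' @param window_s initial-velocity analysis window (s).
#' @param temperatures_C assay temperatures (degrees Celsius, distinct).
#' @param substrate_series_mM substrate dilution series (mM).
#' @param enzyme_conc_M enzyme concentration for the association
#'   normalization (M).
#' @param pose_cutoff_A copper-proximity cutoff (Angstrom).
#' @param baseline subtract the blank traces before analysis.
#' @param seed integer seed recorded in provenance.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(epsilon_M_cm = 3700,
                            path_cm = 0.3,
                            window_s = 480,
                            temperatures_C = c(25, 31, 37, 43),
                            substrate_series_mM = c(0.09375, 0.1875, 0.375,
                                                    0.75, 1.5, 3, 6),
                            enzyme_conc_M = 1e-6,
                            pose_cutoff_A = 6,
                            baseline = TRUE,
                            seed = 1L) {
  for (nm in c("epsilon_M_cm", "path_cm", "window_s", "enzyme_conc_M")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      abort(sprintf("Config key `%s` must be a single positive number.", nm),
            class = "dopatherm_config_error")
    }
  }
  if (pose_cutoff_A < 0) {
    abort("Config key `pose_cutoff_A` must be non-negative.",
          class = "dopatherm_config_error")
  }
  if (anyDuplicated(temperatures_C)) {
    abort("Config key `temperatures_C` must hold distinct values.",
          class = "dopatherm_config_error")
  }
  if (any(substrate_series_mM <= 0)) {
    abort("Config key `substrate_series_mM` must be strictly positive.",
          class = "dopatherm_config_error")
  }
  structure(list(
    epsilon_M_cm = epsilon_M_cm, path_cm = path_cm, window_s = window_s,
    temperatures_C = temperatures_C,
    substrate_series_mM = substrate_series_mM,
    enzyme_conc_M = enzyme_conc_M, pose_cutoff_A = pose_cutoff_A,
    baseline = isTRUE(baseline), seed = as.integer(seed),
    gas_constant = GAS_CONSTANT
  ), class = "pipeline_config")
}

#' Load / save a pipeline configuration (YAML)
#'
#' Missing keys take their defaults; unknown keys are rejected with a
#' message naming them; invalid values raise a validation error naming the
#' key. An empty file yields the all-defaults configuration.
#'
#' @param path path to a YAML file.
#' @return A `"pipeline_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "dopatherm_config_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(vals), c(known, "gas_constant"))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "dopatherm_config_error")
  }
  if (!is.null(vals$gas_constant) && vals$gas_constant != GAS_CONSTANT) {
    abort("Config key `gas_constant` is fixed at 8.314 J/(K mol).",
          class = "dopatherm_config_error")
  }
  vals$gas_constant <- NULL
  do.call(pipeline_config, vals)
}

#' @param config a `"pipeline_config"` object.
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$gas_constant <- NULL  # fixed, not a free key
  yaml::write_yaml(out, path)
  invisible(path)
}

write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Run the full temperature-dependent analysis pipeline
#'
#' Executes plate kinetics (baseline subtraction, initial velocities,
#' per-replicate Michaelis-Menten fits, replicate aggregation), the
#' kinetics van 't Hoff fit, the docking branch (pose filtering when
#' geometry is available, best-pose selection, Boltzmann affinities,
#' docking van 't Hoff fit) and the dopachrome-offset fit. Results are
#' written as JSON plus a human-readable summary and a provenance record.
#' The run is fully deterministic given the inputs and configuration.
#'
#' @param plate_csv path to a plate CSV (see [read_plate_csv()]).
#' @param docking_tsv optional path to a docking TSV; when `NULL` the
#'   docking and dopachrome-offset stages are skipped (and logged as such).
#' @param receptor_pdb optional path to a receptor/pose PDB used for
#'   geometric pose filtering; when `NULL` and the docking table carries an
#'   `offset_A` column that column is used, otherwise filtering requires it.
#' @param config a [pipeline_config()].
#' @param out_dir directory for `fits.json`, `thermo.json`,
#'   `dcshift.json`, `summary.txt`, `provenance.json`; created if needed.
#'   `NULL` skips writing.
#' @return Invisibly, a list with elements `rates`, `fits`, `km_summary`,
#'   `kinetics_signature`, `docking` (or `NULL`), `dc` (or `NULL`),
#'   `stages_run`.
#' @export
run_pipeline <- function(plate_csv, docking_tsv = NULL, receptor_pdb = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "dopatherm_stage_failure")
    })
  }
  stages <- character()

  traces <- stage("read_plate", read_plate_csv(plate_csv))
  if (config$baseline && any(traces$is_blank)) {
    traces <- stage("baseline", subtract_baseline(traces))
  } else {
    traces <- dplyr::filter(traces, !.data$is_blank)
  }
  rates <- stage("initial_velocities", initial_velocities(
    traces, window_s = config$window_s,
    epsilon_M_cm = config$epsilon_M_cm, path_cm = config$path_cm))
  fits <- stage("mm_fits", fit_michaelis_menten_by(rates))
  km_summary <- stage("aggregate", aggregate_replicates(fits))
  kin_points <- stage("vant_hoff_points",
                      build_vant_hoff_points(km_summary, config$enzyme_conc_M))
  kin_sig <- stage("vant_hoff_fit", fit_vant_hoff(kin_points))
  stages <- c(stages, "kinetics", "vant_hoff")

  docking <- NULL
  dc <- NULL
  if (!is.null(docking_tsv)) {
    runs <- stage("read_docking", read_docking_table(docking_tsv))
    pose_d <- NULL
    if (!is.null(receptor_pdb)) {
      pose_d <- stage("pose_distances", measure_pose_distances(receptor_pdb))
    }
    filt <- stage("pose_filter",
                  filter_correct_poses(runs, pose_d, config$pose_cutoff_A))
    best <- stage("best_poses", best_pose_per_temperature(filt$kept))
    aff <- stage("affinities", docking_affinities(best))
    dock_points <- stage("docking_points", docking_vant_hoff_points(best))
    dock_sig <- stage("docking_fit", fit_vant_hoff(dock_points))
    docking <- list(counts = filt$counts, best = best, affinities = aff,
                    signature = dock_sig)
    dc <- stage("dc_offset", fit_dc_offset(kin_points, dock_sig))
    stages <- c(stages, "docking", "dc_shift")
  } else {
    message("No docking table supplied; docking and dopachrome-offset stages skipped.")
  }

  result <- list(rates = rates, fits = fits, km_summary = km_summary,
                 kinetics_points = kin_points, kinetics_signature = kin_sig,
                 docking = docking, dc = dc, stages_run = stages,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_json(list(
      per_replicate = fits, per_temperature = km_summary),
      file.path(out_dir, "fits.json"))
    thermo <- list(
      kinetics = glance(kin_sig),
      per_T_dG_kJ_mol = gibbs_energy(
        kin_sig, celsius_to_kelvin(km_summary$temperature_C)),
      normalization = "ln([E]/Km), association-oriented; only dS depends on [E]")
    if (!is.null(docking)) thermo$docking <- glance(docking$signature)
    write_result_json(thermo, file.path(out_dir, "thermo.json"))
    if (!is.null(dc)) {
      write_result_json(list(summary = glance(dc), per_T = tidy(dc),
                             plot_table = vant_hoff_plot_table(dc)),
                        file.path(out_dir, "dcshift.json"))
    }
    write_result_json(list(
      seed = config$seed,
      config = unclass(config),
      package_version = as.character(utils::packageVersion("dopatherm")),
      r_version = R.version.string,
      stages_run = stages,
      complete = is.null(docking_tsv) ||
        all(c("docking", "dc_shift") %in% stages)),
      file.path(out_dir, "provenance.json"))
    writeLines(pipeline_summary_text(result), file.path(out_dir, "summary.txt"))
  }
  invisible(result)
}

# human-readable tables mirroring the per-temperature and signature results
pipeline_summary_text <- function(result) {
  km <- result$km_summary
  lines <- c("Temperature-dependent diphenol-oxidase analysis", "",
             "Per-temperature Michaelis-Menten parameters (mean +/- SEM):")
  lines <- c(lines, sprintf(
    "  %5.1f degC  Km = %.3g +/- %.2g mM   Vmax = %.3g +/- %.2g mM/min (n = %d)",
    km$temperature_C, km$km_mM, km$sem_km, km$vmax_mM_min, km$sem_vmax,
    km$n_fits))
  sig <- result$kinetics_signature
  lines <- c(lines, "", sprintf(
    "Kinetics van 't Hoff: dH = %.4g +/- %.2g kJ/mol, dS = %.4g +/- %.2g kJ/(K mol), r = %.3f, adj R2 = %.3f",
    sig$dH_kJ_mol, sig$se_dH, sig$dS_kJ_K_mol, sig$se_dS,
    sig$pearson_r, sig$adj_r2))
  if (!is.null(result$docking)) {
    d <- result$docking
    lines <- c(lines, "", "Docking branch (best pose per temperature):")
    lines <- c(lines, sprintf(
      "  %5.1f degC  E = %.4g kJ/mol   Kd = %.3g mM",
      d$best$temperature_C, d$best$binding_energy_kJ_mol, d$affinities$kd_mM))
    lines <- c(lines, sprintf(
      "Docking van 't Hoff: dH = %.4g kJ/mol, dS = %.4g kJ/(K mol)",
      d$signature$dH_kJ_mol, d$signature$dS_kJ_K_mol))
  }
  if (!is.null(result$dc)) {
    lines <- c(lines, "", sprintf(
      "Dopachrome offset DC = %.4g +/- %.2g (dG_dc at 298.15 K = %.4g kJ/mol)",
      result$dc$dc, result$dc$se_dc, dopachrome_free_energy(result$dc, 298.15)))
  }
  lines
}
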