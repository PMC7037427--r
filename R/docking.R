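#' Read a docking-run table
#'
#' Reads a tab-separated table of docking runs with required columns
#' `temperature_C`, `run_id`, `binding_energy_kJ_mol` (and any optional
#' extras such as `pose_id`, `in_site_truth`). Rows whose numeric fields do
#' not parse are reported with their line numbers.
#'
#' @param path path to a TSV file.
#' @return A tibble of docking runs (possibly empty, with a warning).
#' @export
read_docking_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("temperature_C", "run_id", "binding_energy_kJ_mol")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Docking table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dopatherm_schema_error")
  }
  if (nrow(raw) == 0) {
    warn("Docking table is empty.")
    return(tibble::tibble(temperature_C = numeric(), run_id = character(),
                          binding_energy_kJ_mol = numeric()))
  }
  for (col in c("temperature_C", "binding_energy_kJ_mol")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric `%s` value(s) at line(s): %s",
                    col, paste(bad + 1L, collapse = ", ")),  # +1 for header
            class = "dopatherm_schema_error")
    }
    raw[[col]] <- parsed
  }
  if (any(raw$binding_energy_kJ_mol < 0)) {
    abort("Binding energies must be stored as non-negative magnitudes.",
          class = "dopatherm_schema_error")
  }
  if ("pose_id" %in% names(raw)) raw$pose_id <- as.integer(raw$pose_id)
  if ("in_site_truth" %in% names(raw)) {
    raw$in_site_truth <- as.logical(raw$in_site_truth)
  }
  if ("offset_A" %in% names(raw)) {
    raw$offset_A <- suppressWarnings(as.numeric(raw$offset_A))
  }
  dup <- raw |>
    dplyr::count(.data$temperature_C, .data$run_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Run ids must be unique within each temperature.",
          class = "dopatherm_schema_error")
  }
  raw
}

#' Locate the two catalytic coppers in a receptor PDB
#'
#' Parses a PDB file and extracts the coordinates of the two copper atoms
#' that define the tyrosinase active site.
#'
#' @param pdb path to a PDB file, or a `bio3d` pdb object.
#' @return A list of class `"active_site"` with `cu_a` and `cu_b`
#'   (3-vectors, Angstrom).
#' @export
read_active_site <- function(pdb) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- pdb$atom
  is_cu <- toupper(trimws(at$elesy)) == "CU" |
    toupper(trimws(at$elety)) == "CU"
  cu <- at[is_cu, , drop = FALSE]
  if (nrow(cu) != 2) {
    abort(sprintf("Expected exactly 2 copper atoms in the receptor; found %d.",
                  nrow(cu)),
          class = "dopatherm_invalid_site")
  }
  structure(list(cu_a = as.numeric(cu[1, c("x", "y", "z")]),
                 cu_b = as.numeric(cu[2, c("x", "y", "z")])),
            class = "active_site")
}

#' Measure ligand-oxygen to copper distances per pose
#'
#' For every ligand pose (a non-copper HETATM residue) in a PDB file,
#' computes the minimum distance from any of its oxygen atoms to the nearer
#' of the two catalytic coppers.
#'
#' @param pdb path to a PDB file, or a `bio3d` pdb object.
#' @param site optional [read_active_site()] result; located from `pdb`
#'   when omitted.
#' @return A tibble with columns `pose_id` (ligand residue number) and
#'   `min_o_cu_A`.
#' @export
measure_pose_distances <- function(pdb, site = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  if (is.null(site)) site <- read_active_site(pdb)
  at <- pdb$atom
  is_cu <- toupper(trimws(at$elesy)) == "CU" |
    toupper(trimws(at$elety)) == "CU"
  lig <- at[!is_cu, , drop = FALSE]
  if (nrow(lig) == 0) {
    return(tibble::tibble(pose_id = integer(), min_o_cu_A = numeric()))
  }
  is_o <- toupper(trimws(lig$elesy)) == "O" |
    startsWith(toupper(trimws(lig$elety)), "O")
  cu <- rbind(site$cu_a, site$cu_b)
  lig |>
    dplyr::mutate(.is_o = is_o) |>
    dplyr::group_by(pose_id = .data$resno) |>
    dplyr::group_modify(function(d, key) {
      ox <- d[d$.is_o, c("x", "y", "z"), drop = FALSE]
      if (nrow(ox) == 0) {
        abort(sprintf("Pose %d carries no oxygen atoms; cannot apply the copper-proximity criterion.",
                      key$pose_id),
              class = "dopatherm_not_classifiable")
      }
      dmat <- outer(seq_len(nrow(ox)), 1:2, Vectorize(function(i, j) {
        sqrt(sum((as.numeric(ox[i, ]) - cu[j, ])^2))
      }))
      tibble::tibble(min_o_cu_A = min(dmat))
    }) |>
    dplyr::ungroup()
}

#' Keep correctly docked poses by copper proximity
#'
#' A docking run is "correctly docked" when the minimum distance from any
#' of its ligand oxygen atoms to either active-site copper does not exceed
#' `cutoff_A`. Distances come either from a `pose_distances` table (see
#' [measure_pose_distances()]) joined on `pose_id`, or -- for tables that
#' already carry a measured `offset_A` column -- from that column. Runs for
#' which no distance is available raise an error rather than being silently
#' kept or dropped.
#'
#' @param runs a docking-run tibble (see [read_docking_table()]).
#' @param pose_distances optional tibble with `pose_id`, `min_o_cu_A`.
#' @param cutoff_A proximity cutoff in Angstrom (default 6, the scale of
#'   the first coordination shell).
#' @return A list with `kept` (the retained runs, with `min_o_cu_A`) and
#'   `counts` (per-temperature tibble: `n_total`, `n_kept`).
#' @export
filter_correct_poses <- function(runs, pose_distances = NULL, cutoff_A = 6) {
  if (cutoff_A < 0) {
    abort("`cutoff_A` must be non-negative.", class = "dopatherm_invalid_value")
  }
  if (!is.null(pose_distances)) {
    if (!"pose_id" %in% names(runs)) {
      abort("`runs` lacks a `pose_id` column to join pose distances on.",
            class = "dopatherm_not_classifiable")
    }
    runs <- dplyr::left_join(
      runs, pose_distances[, c("pose_id", "min_o_cu_A")], by = "pose_id")
  } else if ("offset_A" %in% names(runs)) {
    runs$min_o_cu_A <- runs$offset_A
  } else {
    abort("Runs carry no ligand geometry (no pose distances, no `offset_A`); poses are not classifiable.",
          class = "dopatherm_not_classifiable")
  }
  if (any(is.na(runs$min_o_cu_A))) {
    abort(sprintf("%d run(s) have no measurable ligand geometry; poses are not classifiable.",
                  sum(is.na(runs$min_o_cu_A))),
          class = "dopatherm_not_classifiable")
  }
  kept <- dplyr::filter(runs, .data$min_o_cu_A <= cutoff_A)
  counts <- runs |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_kept = sum(.data$min_o_cu_A <= .env$cutoff_A),
                     .groups = "drop")
  list(kept = kept, counts = counts)
}

#' Select the best docking pose per temperature
#'
#' The best pose at a temperature is the one with the largest binding
#' energy magnitude (strongest binding); ties are broken by the
#' lexicographically smallest `run_id`. Alternatively the per-temperature
#' arithmetic mean of the energies can be taken.
#'
#' @param runs a tibble of (kept) docking runs.
#' @param temperatures temperatures that must be represented; defaults to
#'   those present. Requested temperatures with no kept pose are reported
#'   via a warning and a `missing_temperatures` attribute, never fabricated.
#' @param average if `TRUE`, return the mean energy per temperature instead
#'   of the single best pose.
#' @return A tibble with one row per available temperature.
#' @export
best_pose_per_temperature <- function(runs, temperatures = NULL,
                                      average = FALSE) {
  if (is.null(temperatures)) temperatures <- sort(unique(runs$temperature_C))
  missing <- setdiff(temperatures, unique(runs$temperature_C))
  if (length(missing) > 0) {
    warn(sprintf("No kept pose at temperature(s): %s",
                 paste(missing, collapse = ", ")))
  }
  out <- if (average) {
    runs |>
      dplyr::filter(.data$temperature_C %in% temperatures) |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::summarise(
        binding_energy_kJ_mol = mean(.data$binding_energy_kJ_mol),
        run_id = paste(sort(.data$run_id), collapse = "+"),
        n_poses = dplyr::n(), .groups = "drop")
  } else {
    runs |>
      dplyr::filter(.data$temperature_C %in% temperatures) |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::arrange(dplyr::desc(.data$binding_energy_kJ_mol), .data$run_id,
                     .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
  }
  attr(out, "missing_temperatures") <- missing
  out
}

#' Boltzmann conversion between binding energy and dissociation constant
#'
#' Converts a binding free-energy magnitude (kJ/mol) into a dissociation
#' constant relative to the 1 M reference state:
#' Kd = exp(-E * 1000 / (R T)) mol/L, reported in mM. The inverse,
#' [kd_to_binding_energy()], satisfies the round-trip identity.
#'
#' @param energy_kJ_mol binding energy magnitude(s), >= 0 (kJ/mol).
#' @param temperature_K temperature(s) in Kelvin, > 0.
#' @return Dissociation constant(s) in mM.
#' @export
binding_energy_to_kd <- function(energy_kJ_mol, temperature_K) {
  if (any(energy_kJ_mol < 0)) {
    abort("Binding energy magnitudes must be non-negative.",
          class = "dopatherm_invalid_value")
  }
  if (any(temperature_K <= 0)) {
    abort("Temperatures must be positive Kelvin.",
          class = "dopatherm_invalid_value")
  }
  exp(-energy_kJ_mol * 1000 / (GAS_CONSTANT * temperature_K)) * 1000
}

#' @param kd_mM dissociation constant(s) in mM.
#' @rdname binding_energy_to_kd
#' @export
kd_to_binding_energy <- function(kd_mM, temperature_K) {
  if (any(kd_mM <= 0)) {
    abort("`kd_mM` must be positive.", class = "dopatherm_invalid_value")
  }
  -GAS_CONSTANT * temperature_K * log(kd_mM / 1000) / 1000
}

#' Per-temperature affinity estimates from best poses
#'
#' @param best_poses output of [best_pose_per_temperature()].
#' @return A tibble with `temperature_C`, `kd_mM`, `source_energy_kJ_mol`.
#' @export
docking_affinities <- function(best_poses) {
  T_K <- celsius_to_kelvin(best_poses$temperature_C)
  tibble::tibble(
    temperature_C = best_poses$temperature_C,
    kd_mM = binding_energy_to_kd(best_poses$binding_energy_kJ_mol, T_K),
    source_energy_kJ_mol = best_poses$binding_energy_kJ_mol
  )
}

#' van 't Hoff points from docking binding energies
#'
#' The log molar association constant implied by a binding energy magnitude
#' is ln K = E * 1000 / (R T); one point per temperature feeds the docking
#' branch of the van 't Hoff analysis.
#'
#' @param best_poses output of [best_pose_per_temperature()] covering at
#'   least two temperatures.
#' @return A tibble of van 't Hoff points (`temperature_K`, `inv_T`,
#'   `ln_k_norm`, `sigma_ln_k = 0`, `source = "docking"`).
#' @export
docking_vant_hoff_points <- function(best_poses) {
  if (length(unique(best_poses$temperature_C)) < 2) {
    abort("Need at least 2 temperatures for a docking van 't Hoff analysis.",
          class = "dopatherm_insufficient_data")
  }
  T_K <- celsius_to_kelvin(best_poses$temperature_C)
  tibble::tibble(
    temperature_K = T_K,
    inv_T = 1 / T_K,
    ln_k_norm = best_poses$binding_energy_kJ_mol * 1000 / (GAS_CONSTANT * T_K),
    sigma_ln_k = 0,
    source = "docking"
  )
}
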