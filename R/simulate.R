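#' Simulation parameters for synthetic dopachrome assays
#'
#' Bundles and validates the ground-truth parameters used by
#' [simulate_progress_curves()]. Defaults reproduce the study conditions of
#' the temperature-dependent diphenol-oxidase assay: four assay temperatures,
#' a doubling L-DOPA dilution series, per-temperature Michaelis constants and
#' maximal velocities at the published point estimates, dopachrome molar
#' absorptivity 3700 M^-1 cm^-1 over a 0.3 cm path, and additive Gaussian
#' plate-reader noise.
#'
#' @param temperatures_C assay temperatures in degrees Celsius (distinct).
#' @param substrate_series_mM initial L-DOPA concentrations (mM).
#' @param km_by_T_mM ground-truth Michaelis constants, one per temperature (mM).
#' @param vmax_by_T_mM_min ground-truth maximal velocities, one per
#'   temperature (mM/min).
#' @param epsilon_M_cm molar absorptivity of dopachrome (M^-1 cm^-1).
#' @param path_cm optical path length (cm).
#' @param duration_s simulated reaction time (s).
#' @param step_s sampling (and integration) interval (s).
#' @param noise_sigma_mOD SD of additive Gaussian absorbance noise (mOD).
#' @param n_replicates number of replicate traces per condition.
#' @param seed integer RNG seed; the same seed gives bit-identical output.
#'
#' @return A validated list of class `"sim_params"`.
#' @seealso [km_from_signature()] to derive `km_by_T_mM` from a
#'   thermodynamic signature.
#' @export
#' @examples
#' p <- sim_params(noise_sigma_mOD = 0, n_replicates = 1)
#' curves <- simulate_progress_curves(p)
sim_params <- function(temperatures_C = c(25, 31, 37, 43),
                       substrate_series_mM = c(0.09375, 0.1875, 0.375,
                                               0.75, 1.5, 3, 6),
                       km_by_T_mM = c(0.41, 0.52, 0.70, 0.62),
                       vmax_by_T_mM_min = c(0.029, 0.032, 0.038, 0.057),
                       epsilon_M_cm = 3700,
                       path_cm = 0.3,
                       duration_s = 600,
                       step_s = 5,
                       noise_sigma_mOD = 2,
                       n_replicates = 3,
                       seed = 1L) {
  if (anyDuplicated(temperatures_C)) {
    abort("`temperatures_C` must be distinct.", class = "dopatherm_invalid_value")
  }
  nT <- length(temperatures_C)
  km_by_T_mM <- rep_len(km_by_T_mM, nT)
  vmax_by_T_mM_min <- rep_len(vmax_by_T_mM_min, nT)
  for (nm in c("epsilon_M_cm", "path_cm", "duration_s", "step_s")) {
    check_positive(get(nm), nm)
  }
  if (any(substrate_series_mM <= 0) || any(km_by_T_mM <= 0) ||
      any(vmax_by_T_mM_min <= 0)) {
    abort("Substrate, Km and Vmax values must be strictly positive.",
          class = "dopatherm_invalid_value")
  }
  if (step_s >= duration_s) {
    abort("`step_s` must be smaller than `duration_s`.",
          class = "dopatherm_invalid_grid")
  }
  if (noise_sigma_mOD < 0) {
    abort("`noise_sigma_mOD` must be non-negative.",
          class = "dopatherm_invalid_value")
  }
  if (n_replicates < 1) {
    abort("`n_replicates` must be >= 1.", class = "dopatherm_invalid_value")
  }
  structure(list(
    temperatures_C = temperatures_C,
    substrate_series_mM = substrate_series_mM,
    km_by_T_mM = km_by_T_mM,
    vmax_by_T_mM_min = vmax_by_T_mM_min,
    epsilon_M_cm = epsilon_M_cm,
    path_cm = path_cm,
    duration_s = duration_s,
    step_s = step_s,
    noise_sigma_mOD = noise_sigma_mOD,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Michaelis constants implied by a van 't Hoff signature
#'
#' Inverts the van 't Hoff line ln([E]/Km) = -dH/(R T) + dS/R to obtain
#' per-temperature Michaelis constants from an apparent enthalpy/entropy
#' pair and an enzyme concentration. Used to build self-consistent synthetic
#' data sets whose downstream van 't Hoff fit has a known truth.
#'
#' @param dH_kJ_mol apparent enthalpy change (kJ/mol).
#' @param dS_kJ_K_mol apparent entropy change (kJ/(K mol)).
#' @param enzyme_conc_M enzyme concentration used for normalization (M).
#' @param temperatures_C assay temperatures (degrees Celsius).
#' @return A tibble with columns `temperature_C` and `km_mM`.
#' @export
km_from_signature <- function(dH_kJ_mol, dS_kJ_K_mol, enzyme_conc_M,
                              temperatures_C) {
  check_positive(enzyme_conc_M, "enzyme_conc_M")
  T_K <- celsius_to_kelvin(temperatures_C)
  ln_k <- -dH_kJ_mol * 1000 / (GAS_CONSTANT * T_K) + dS_kJ_K_mol * 1000 / GAS_CONSTANT
  km_M <- enzyme_conc_M / exp(ln_k)
  tibble::tibble(temperature_C = temperatures_C, km_mM = km_M * 1000)
}

#' Deterministic Michaelis-Menten progress curve
#'
#' Integrates substrate depletion dS/dt = -Vmax S/(Km + S) (product
#' formation is the mirror image, 1:1 stoichiometry) with a fixed-step
#' classical 4th-order Runge-Kutta scheme. Vectorised over the initial
#' substrate concentrations so a whole dilution series is integrated in one
#' pass.
#'
#' @param s0_mM initial substrate concentration(s) (mM).
#' @param km_mM Michaelis constant (mM).
#' @param vmax_mM_min maximal velocity (mM/min).
#' @param duration_s,step_s time horizon and fixed step (s).
#' @return A tibble with columns `time_s`, `substrate_mM0` (the series
#'   label), `substrate_mM` (current), `product_mM`.
#' @export
mm_progress <- function(s0_mM, km_mM, vmax_mM_min, duration_s, step_s) {
  check_positive(km_mM, "km_mM")
  check_positive(vmax_mM_min, "vmax_mM_min")
  if (step_s >= duration_s) {
    abort("`step_s` must be smaller than `duration_s`.",
          class = "dopatherm_invalid_grid")
  }
  vmax_s <- vmax_mM_min / 60
  times <- seq(0, duration_s, by = step_s)
  n <- length(times)
  rate <- function(s) -vmax_s * s / (km_mM + s)
  S <- matrix(NA_real_, nrow = n, ncol = length(s0_mM))
  S[1, ] <- s0_mM
  h <- step_s
  for (i in seq_len(n - 1L)) {
    s <- S[i, ]
    k1 <- rate(s)
    k2 <- rate(s + h / 2 * k1)
    k3 <- rate(s + h / 2 * k2)
    k4 <- rate(s + h * k3)
    S[i + 1L, ] <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  tibble::tibble(
    time_s = rep(times, times = length(s0_mM)),
    substrate_mM0 = rep(s0_mM, each = n),
    substrate_mM = as.vector(S),
    product_mM = rep(s0_mM, each = n) - as.vector(S)
  )
}

#' Simulate dopachrome absorbance progress curves
#'
#' Generates one absorbance trace per (temperature, substrate, replicate)
#' plus a substrate-free blank per temperature. Product concentration is
#' converted to absorbance via the Beer-Lambert law
#' (A_mOD = epsilon * L * P_mM) and corrupted with i.i.d. Gaussian noise.
#' Output is bit-reproducible for a fixed `seed`.
#'
#' @param params a [sim_params()] object.
#' @return A tibble with columns `time_s`, `temperature_C`, `substrate_mM`,
#'   `replicate`, `absorbance_mOD`, `is_blank`.
#' @export
simulate_progress_curves <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  per_T <- purrr::map2(seq_along(p$temperatures_C), p$temperatures_C,
    function(i, temp) {
      prog <- mm_progress(p$substrate_series_mM, p$km_by_T_mM[i],
                          p$vmax_by_T_mM_min[i], p$duration_s, p$step_s)
      reps <- tidyr::crossing(replicate = seq_len(p$n_replicates), prog)
      curves <- tibble::tibble(
        time_s = reps$time_s,
        temperature_C = temp,
        substrate_mM = reps$substrate_mM0,
        replicate = reps$replicate,
        absorbance_mOD = p$epsilon_M_cm * p$path_cm * reps$product_mM,
        is_blank = FALSE
      )
      blank_t <- seq(0, p$duration_s, by = p$step_s)
      blank <- tibble::tibble(
        time_s = blank_t, temperature_C = temp, substrate_mM = 0,
        replicate = 1L, absorbance_mOD = 0, is_blank = TRUE
      )
      dplyr::bind_rows(curves, blank)
    })
  out <- dplyr::bind_rows(per_T)
  if (p$noise_sigma_mOD > 0) {
    out$absorbance_mOD <- out$absorbance_mOD +
      withr::with_seed(p$seed, rnorm(nrow(out), 0, p$noise_sigma_mOD))
  }
  out
}

#' Simulate a docking-run energy table
#'
#' Emulates the tabulated output of repeated rigid-receptor docking runs at
#' several temperatures. In-site ("correctly docked") poses carry binding
#' energy magnitudes scattered about |dH - T dS| and a ligand-oxygen to
#' copper distance inside the first coordination shell; decoy poses sit far
#' from the coppers and bind more weakly (half the in-site mean energy).
#' Whether a run is a decoy is an independent Bernoulli draw per run.
#'
#' @param dH_dock_kJ_mol,dS_dock_kJ_K_mol ground-truth association
#'   signature of the docking model (kJ/mol; kJ/(K mol)).
#' @param temperatures_C docking temperatures (degrees Celsius).
#' @param n_runs docking runs per temperature.
#' @param decoy_fraction probability that a run is a decoy, in [0, 1).
#' @param energy_noise_kJ SD of Gaussian scatter on binding energies (kJ/mol).
#' @param seed integer RNG seed.
#' @return A tibble with columns `pose_id` (matches the ligand residue
#'   number in a fixture written with [simulate_pose_pdb()] from this
#'   table's `offset_A` column), `temperature_C`, `run_id`,
#'   `binding_energy_kJ_mol`, `in_site_truth`, `offset_A` (ground-truth
#'   nearest ligand-oxygen to copper distance).
#' @export
simulate_docking_table <- function(dH_dock_kJ_mol, dS_dock_kJ_K_mol,
                                   temperatures_C = c(25, 31, 37, 43),
                                   n_runs = 200,
                                   decoy_fraction = 0,
                                   energy_noise_kJ = 0,
                                   seed = 1L) {
  if (n_runs < 1) abort("`n_runs` must be >= 1.", class = "dopatherm_invalid_value")
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    abort("`decoy_fraction` must be in [0, 1).", class = "dopatherm_invalid_value")
  }
  if (energy_noise_kJ < 0) {
    abort("`energy_noise_kJ` must be non-negative.",
          class = "dopatherm_invalid_value")
  }
  T_K <- celsius_to_kelvin(temperatures_C)
  e_true <- abs(dH_dock_kJ_mol - T_K * dS_dock_kJ_K_mol)
  grid <- tidyr::crossing(ti = seq_along(temperatures_C), run = seq_len(n_runs))
  withr::with_seed(seed, {
    n <- nrow(grid)
    in_site <- runif(n) >= decoy_fraction
    base_e <- e_true[grid$ti] * ifelse(in_site, 1, 0.5)
    energy <- base_e + if (energy_noise_kJ > 0) rnorm(n, 0, energy_noise_kJ) else 0
    offset <- ifelse(in_site, runif(n, 2.5, 4.5), runif(n, 10, 20))
    tibble::tibble(
      pose_id = seq_len(n),
      temperature_C = temperatures_C[grid$ti],
      run_id = sprintf("T%s_run%03d", temperatures_C[grid$ti], grid$run),
      binding_energy_kJ_mol = pmax(energy, 0),
      in_site_truth = in_site,
      offset_A = offset
    )
  })
}

# fixed-width HETATM record (columns per the PDB v3 standard)
pdb_hetatm <- function(serial, name, resname, chain, resno, xyz, elem) {
  sprintf("HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, xyz[1], xyz[2], xyz[3],
          1, 0, elem)
}

#' Write a synthetic receptor/pose PDB fixture
#'
#' Emits a minimal PDB: two copper HETATM records standing in for the CuA
#' and CuB of the tyrosinase active site, plus one catechol-like ligand
#' residue per requested pose. Each pose is constructed so that the
#' distance from its nearest oxygen atom to the nearer copper equals the
#' requested offset to within 0.01 Angstrom; all other pose atoms are
#' strictly farther from both coppers.
#'
#' @param cu_positions a 2 x 3 numeric matrix of copper coordinates (Angstrom).
#' @param pose_offsets_A nearest-oxygen-to-copper distances, one per pose
#'   (Angstrom, non-negative). May be empty (receptor-only file).
#' @param seed integer RNG seed (pose directions are randomised).
#' @param path optional file path; when given the PDB text is written there.
#' @return Invisibly, the character vector of PDB lines.
#' @export
simulate_pose_pdb <- function(cu_positions, pose_offsets_A = numeric(),
                              seed = 1L, path = NULL) {
  cu_positions <- as.matrix(cu_positions)
  if (!is.numeric(cu_positions) || !all(dim(cu_positions) == c(2L, 3L))) {
    abort("`cu_positions` must be a 2 x 3 numeric matrix.",
          class = "dopatherm_invalid_value")
  }
  if (all(cu_positions[1, ] == cu_positions[2, ])) {
    abort("The two copper positions must be distinct.",
          class = "dopatherm_invalid_value")
  }
  if (any(pose_offsets_A < 0)) {
    abort("Pose offsets must be non-negative.", class = "dopatherm_invalid_value")
  }
  cu_a <- cu_positions[1, ]
  cu_b <- cu_positions[2, ]
  ab <- cu_a - cu_b
  ab_hat <- ab / sqrt(sum(ab^2))
  lines <- c("REMARK synthetic receptor/pose fixture",
             pdb_hetatm(1L, "CU", "CUA", "A", 1L, cu_a, "Cu"),
             pdb_hetatm(2L, "CU", "CUB", "A", 2L, cu_b, "Cu"))
  serial <- 2L
  if (length(pose_offsets_A) > 0) {
    dirs <- withr::with_seed(seed, {
      w <- matrix(rnorm(3 * length(pose_offsets_A)), ncol = 3)
      w <- w / sqrt(rowSums(w^2))
      u <- sweep(0.5 * w, 2, ab_hat, "+")  # biased away from CuB
      u / sqrt(rowSums(u^2))
    })
    for (i in seq_along(pose_offsets_A)) {
      d <- pose_offsets_A[i]
      u <- dirs[i, ]
      side <- vector_perp(u)
      atoms <- list(
        O1 = cu_a + d * u,
        O2 = cu_a + (d + 0.8) * u + 0.4 * side,
        C1 = cu_a + (d + 1.4) * u,
        C2 = cu_a + (d + 2.0) * u + 0.7 * side,
        C3 = cu_a + (d + 2.6) * u
      )
      for (nm in names(atoms)) {
        serial <- serial + 1L
        elem <- substr(nm, 1, 1)
        lines <- c(lines, pdb_hetatm(serial, nm, "LIG", "L", i, atoms[[nm]], elem))
      }
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# a unit vector perpendicular to u
vector_perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- pracma_cross(u, ref)
  v / sqrt(sum(v^2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate paired calorimetry/absorbance rate data
#'
#' Emulates the tandem experiment in which plate-reader absorbance values
#' and calorimetry-derived reaction rates are measured at the same substrate
#' concentrations: ITC rates follow a Michaelis-Menten curve and the UV
#' absorbance readings are proportional to them with ratio `true_ratio`.
#'
#' @param true_ratio ground-truth uv/rate proportionality constant (> 0).
#' @param substrate_points_uM substrate concentrations (micromolar).
#' @param noise_rel relative (multiplicative) Gaussian noise SD on the
#'   absorbance values.
#' @param seed integer RNG seed.
#' @param km_uM,vmax_uM_s Michaelis parameters of the underlying rate curve.
#' @return A tibble with columns `substrate_uM`, `itc_rate_uM_s`,
#'   `uv_absorbance_mOD`.
#' @export
simulate_itc_rate_pairs <- function(true_ratio = 20.34,
                                    substrate_points_uM = c(10.9, 21.9, 43.8,
                                                            87.5, 175, 350),
                                    noise_rel = 0,
                                    seed = 1L,
                                    km_uM = 70,
                                    vmax_uM_s = 0.1) {
  check_positive(true_ratio, "true_ratio")
  if (any(substrate_points_uM <= 0)) {
    abort("Substrate points must be positive.", class = "dopatherm_invalid_value")
  }
  rate <- vmax_uM_s * substrate_points_uM / (km_uM + substrate_points_uM)
  uv <- true_ratio * rate
  if (noise_rel > 0) {
    uv <- uv * (1 + withr::with_seed(seed, rnorm(length(uv), 0, noise_rel)))
  }
  tibble::tibble(
    substrate_uM = substrate_points_uM,
    itc_rate_uM_s = rate,
    uv_absorbance_mOD = uv
  )
}
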