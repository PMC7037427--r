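#' Fit the dopachrome offset between kinetics and docking lines
#'
#' The docking-derived association line and the kinetics-derived van 't
#' Hoff points run roughly parallel on the (1/T, ln K) plane; their
#' vertical separation is the dopachrome offset DC. DC is fitted as a pure
#' least-squares vertical shift of the docking line (slope kept from the
#' docking fit), signed so that docking line + DC reproduces the kinetics
#' points. Its standard error comes from the scatter of the per-point
#' differences.
#'
#' The per-temperature free energies are reported on a consistent ladder:
#' `dg_assoc_kJ_mol` from the docking line (first-step association),
#' `dg_m_kJ_mol` from the DC-shifted line (the kinetics-apparent model),
#' and their difference `dg_dc_kJ_mol = dg_m - dg_assoc = -R T dc / 1000`,
#' which is positive exactly when the kinetics-apparent binding is weaker
#' than the docking binding.
#'
#' @param kinetics_points van 't Hoff points from
#'   [build_vant_hoff_points()] (>= 1 point).
#' @param docking_signature a `"thermo_signature"` fitted on docking points.
#' @param use_trendline if `TRUE`, fit DC to the kinetics trendline
#'   evaluated at the point temperatures instead of to the points
#'   themselves (identical when the points are collinear).
#' @return An object of class `"dc_shift"`: `dc`, `se_dc`, `dg_by_T` (a
#'   tibble with `temperature_K`, `dg_m_kJ_mol`, `dg_assoc_kJ_mol`,
#'   `dg_dc_kJ_mol`), plus the inputs.
#' @export
fit_dc_offset <- function(kinetics_points, docking_signature,
                          use_trendline = FALSE) {
  stopifnot(inherits(docking_signature, "thermo_signature"))
  if (nrow(kinetics_points) == 0) {
    abort("No kinetics points to fit the offset to.",
          class = "dopatherm_insufficient_data")
  }
  if (!all(is.finite(c(docking_signature$dH_kJ_mol,
                       docking_signature$dS_kJ_K_mol)))) {
    abort("Docking signature is not finite.", class = "dopatherm_invalid_value")
  }
  T_K <- kinetics_points$temperature_K
  y_kin <- kinetics_points$ln_k_norm
  if (use_trendline && nrow(kinetics_points) >= 2) {
    kin_line <- fit_vant_hoff(kinetics_points)
    y_kin <- predict_ln_k(kin_line, T_K)
  }
  y_dock <- predict_ln_k(docking_signature, T_K)
  diffs <- y_kin - y_dock
  dc <- mean(diffs)
  se_dc <- if (length(diffs) > 1) sd(diffs) / sqrt(length(diffs)) else 0
  dg_by_T <- tibble::tibble(
    temperature_K = T_K,
    dg_assoc_kJ_mol = -GAS_CONSTANT * T_K * y_dock / 1000,
    dg_m_kJ_mol = -GAS_CONSTANT * T_K * (y_dock + dc) / 1000
  )
  dg_by_T$dg_dc_kJ_mol <- dg_by_T$dg_m_kJ_mol - dg_by_T$dg_assoc_kJ_mol
  structure(list(
    dc = dc,
    se_dc = se_dc,
    dg_by_T = dg_by_T,
    kinetics_points = tibble::as_tibble(kinetics_points),
    docking_signature = docking_signature,
    use_trendline = use_trendline
  ), class = "dc_shift")
}

#' @export
print.dc_shift <- function(x, ...) {
  cat(sprintf(
    "Dopachrome offset DC = %.4g +/- %.2g  (dG_dc at 298.15 K = %.4g kJ/mol)\n",
    x$dc, x$se_dc, dopachrome_free_energy(x, 298.15)))
  invisible(x)
}

#' Dopachrome free-energy penalty at a temperature
#'
#' The free-energy cost associated with the dopachrome offset,
#' dG_dc = R T |DC| / 1000 (kJ/mol). It is proportional to both DC and T
#' and vanishes when the kinetics and docking lines coincide.
#'
#' @param dc a `"dc_shift"` object or a plain numeric offset.
#' @param temperature_K temperature(s) in Kelvin (default: room
#'   temperature, 298.15 K).
#' @return Numeric dG_dc in kJ/mol (vectorised over `temperature_K`).
#' @export
#' @examples
#' dopachrome_free_energy(6.07, 298.15)  # ~15.05 kJ/mol
dopachrome_free_energy <- function(dc, temperature_K = 298.15) {
  offset <- if (inherits(dc, "dc_shift")) dc$dc else dc
  if (!is.finite(offset)) {
    abort("`dc` must be finite.", class = "dopatherm_invalid_value")
  }
  GAS_CONSTANT * temperature_K * abs(offset) / 1000
}
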