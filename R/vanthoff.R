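#' Build van 't Hoff points from per-temperature Michaelis constants
#'
#' Under the assumption that product release is much slower than complex
#' dissociation, the Michaelis constant approximates the dissociation
#' constant, so an association constant normalized by enzyme concentration
#' can be formed as [E]/Km. Each temperature contributes one point
#' (1/T, ln([E]/Km)) to the van 't Hoff plot; the SD of the log constant is
#' obtained from the SEM of Km by the delta method. Only the intercept
#' (entropy) of the downstream line depends on the choice of [E]; the slope
#' (enthalpy) does not.
#'
#' @param km_summary a tibble with columns `temperature_C`, `km_mM` and
#'   optionally `sem_km` (e.g. from [aggregate_replicates()]).
#' @param enzyme_conc_M enzyme concentration used for normalization (M).
#' @return A tibble of class van 't Hoff points: `temperature_K`,
#'   `inv_T`, `ln_k_norm`, `sigma_ln_k`, `source = "kinetics"`.
#' @export
build_vant_hoff_points <- function(km_summary, enzyme_conc_M) {
  stopifnot(all(c("temperature_C", "km_mM") %in% names(km_summary)))
  check_positive(enzyme_conc_M, "enzyme_conc_M")
  if (any(km_summary$km_mM <= 0)) {
    abort("Km values must be strictly positive.", class = "dopatherm_invalid_value")
  }
  T_K <- celsius_to_kelvin(km_summary$temperature_C)
  km_M <- km_summary$km_mM / 1000
  sigma <- if ("sem_km" %in% names(km_summary)) {
    km_summary$sem_km / km_summary$km_mM  # delta method: sd(ln Km)
  } else {
    rep(0, nrow(km_summary))
  }
  tibble::tibble(
    temperature_K = T_K,
    inv_T = 1 / T_K,
    ln_k_norm = log(enzyme_conc_M / km_M),
    sigma_ln_k = sigma,
    source = "kinetics"
  )
}

#' Fit a van 't Hoff line to log association constants
#'
#' Straight-line regression of ln K on 1/T:
#' ln K = (-dH/R) (1/T) + dS/R, so the apparent enthalpy change is
#' dH = -R * slope and the apparent entropy change is dS = R * intercept.
#' Ordinary least squares by default; inverse-variance weighting is applied
#' when `weighted = TRUE` and all point SDs are positive.
#'
#' @param points a tibble of van 't Hoff points with columns
#'   `temperature_K`, `ln_k_norm` and optionally `sigma_ln_k` (see
#'   [build_vant_hoff_points()] and [docking_vant_hoff_points()]).
#' @param weighted logical; use inverse-variance weights 1/sigma^2.
#' @return An object of class `"thermo_signature"`: a list with
#'   `dH_kJ_mol`, `dS_kJ_K_mol`, `se_dH`, `se_dS`, `pearson_r`, `adj_r2`,
#'   `n`, and the underlying `points`.
#' @export
fit_vant_hoff <- function(points, weighted = FALSE) {
  stopifnot(all(c("temperature_K", "ln_k_norm") %in% names(points)))
  x <- 1 / points$temperature_K
  y <- points$ln_k_norm
  n <- length(x)
  if (n < 2) {
    abort("Need at least 2 temperatures for a van 't Hoff fit.",
          class = "dopatherm_insufficient_data")
  }
  if (diff(range(x)) == 0) {
    abort("All points share one temperature; the design is singular.",
          class = "dopatherm_singular_design")
  }
  w <- NULL
  if (weighted) {
    sig <- points$sigma_ln_k
    if (is.null(sig) || any(!is.finite(sig)) || any(sig <= 0)) {
      abort("Weighted fit requires strictly positive `sigma_ln_k` for every point.",
            class = "dopatherm_invalid_value")
    }
    w <- 1 / sig^2
  }
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  # collinear (noise-free) points trigger summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope <- cf["x", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  if (n > 2) {
    se_slope <- cf["x", "Std. Error"]
    se_intercept <- cf["(Intercept)", "Std. Error"]
    adj_r2 <- sm$adj.r.squared
  } else {
    # exact interpolating line: no residual degrees of freedom
    se_slope <- NA_real_
    se_intercept <- NA_real_
    adj_r2 <- NA_real_
  }
  structure(list(
    dH_kJ_mol = -GAS_CONSTANT * slope / 1000,
    dS_kJ_K_mol = GAS_CONSTANT * intercept / 1000,
    se_dH = GAS_CONSTANT * se_slope / 1000,
    se_dS = GAS_CONSTANT * se_intercept / 1000,
    pearson_r = stats::cor(x, y),
    adj_r2 = adj_r2,
    n = n,
    weighted = weighted,
    points = tibble::as_tibble(points)
  ), class = "thermo_signature")
}

#' @export
print.thermo_signature <- function(x, ...) {
  cat(sprintf(
    paste0("Apparent thermodynamic signature (van 't Hoff, %s, n = %d)\n",
           "  dH = %.4g +/- %.2g kJ/mol\n",
           "  dS = %.4g +/- %.2g kJ/(K mol)\n",
           "  Pearson r = %.3f, adj R2 = %.3f\n"),
    if (isTRUE(x$weighted)) "weighted" else "OLS", x$n,
    x$dH_kJ_mol, x$se_dH, x$dS_kJ_K_mol, x$se_dS,
    x$pearson_r, x$adj_r2))
  invisible(x)
}

#' Gibbs free energy from a thermodynamic signature
#'
#' Evaluates dG = dH - T dS at the requested temperature(s).
#'
#' @param sig a `"thermo_signature"` object (or a list with `dH_kJ_mol`
#'   and `dS_kJ_K_mol`).
#' @param temperature_K temperature(s) in Kelvin.
#' @return A tibble with columns `temperature_K`, `dG_kJ_mol`.
#' @export
gibbs_energy <- function(sig, temperature_K) {
  stopifnot(is.finite(sig$dH_kJ_mol), is.finite(sig$dS_kJ_K_mol))
  tibble::tibble(
    temperature_K = temperature_K,
    dG_kJ_mol = sig$dH_kJ_mol - temperature_K * sig$dS_kJ_K_mol
  )
}

#' Predict ln K from a fitted van 't Hoff line
#'
#' @param sig a `"thermo_signature"` object.
#' @param temperature_K temperature(s) in Kelvin.
#' @return Numeric vector of predicted log association constants.
#' @export
predict_ln_k <- function(sig, temperature_K) {
  (-sig$dH_kJ_mol * 1000 / GAS_CONSTANT) / temperature_K +
    sig$dS_kJ_K_mol * 1000 / GAS_CONSTANT
}
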