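# shared fixture builders; everything is generated in code, no stored data

lit_km_mM <- c(0.41, 0.52, 0.70, 0.62)
lit_vmax_mM_min <- c(0.029, 0.032, 0.038, 0.057)
assay_temps_C <- c(25, 31, 37, 43)
doubling_series_mM <- c(0.09375, 0.1875, 0.375, 0.75, 1.5, 3, 6)

# exact Michaelis-Menten rates at given parameters
exact_rates <- function(km, vmax, s = doubling_series_mM, temperature_C = 37) {
  tibble::tibble(
    substrate_mM = s,
    v_initial_mM_min = vmax * s / (km + s),
    temperature_C = temperature_C
  )
}

# van 't Hoff points lying exactly on a (dH, dS) line
exact_vh_points <- function(dH, dS, temps_C = assay_temps_C, source = "kinetics") {
  T_K <- temps_C + 273.15
  tibble::tibble(
    temperature_K = T_K,
    inv_T = 1 / T_K,
    ln_k_norm = -dH * 1000 / (8.314 * T_K) + dS * 1000 / 8.314,
    sigma_ln_k = 0,
    source = source
  )
}

# closed-form OLS slope/intercept (independent of lm and of the package path)
ols_line <- function(x, y) {
  sx <- x - mean(x)
  slope <- sum(sx * (y - mean(y))) / sum(sx^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
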