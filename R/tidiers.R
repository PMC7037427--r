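#' Tidy a Michaelis-Menten fit
#'
#' @param x an `"mm_fit"` object.
#' @param ... unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("km_mM", "vmax_mM_min"),
    estimate = c(x$km_mM, x$vmax_mM_min),
    std.error = c(x$se_km, x$se_vmax)
  )
}

#' @rdname tidy.mm_fit
#' @return `glance()` returns a one-row model summary.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    temperature_C = x$temperature_C,
    km_mM = x$km_mM, se_km = x$se_km,
    vmax_mM_min = x$vmax_mM_min, se_vmax = x$se_vmax,
    adj_r2 = x$adj_r2, n_rates = x$n_rates, rss = x$rss
  )
}

#' Tidy a thermodynamic signature
#'
#' @param x a `"thermo_signature"` object.
#' @param ... unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @export
tidy.thermo_signature <- function(x, ...) {
  tibble::tibble(
    term = c("dH_kJ_mol", "dS_kJ_K_mol"),
    estimate = c(x$dH_kJ_mol, x$dS_kJ_K_mol),
    std.error = c(x$se_dH, x$se_dS)
  )
}

#' @rdname tidy.thermo_signature
#' @export
glance.thermo_signature <- function(x, ...) {
  tibble::tibble(
    dH_kJ_mol = x$dH_kJ_mol, se_dH = x$se_dH,
    dS_kJ_K_mol = x$dS_kJ_K_mol, se_dS = x$se_dS,
    pearson_r = x$pearson_r, adj_r2 = x$adj_r2, n = x$n
  )
}

#' Tidy a proportional-ratio calibration
#'
#' @param x a `"ratio_fit"` object.
#' @param ... unused.
#' @export
glance.ratio_fit <- function(x, ...) {
  tibble::tibble(mean_ratio = x$mean_ratio, adj_r2 = x$adj_r2, n = x$n)
}

#' Tidy a dopachrome-offset fit
#'
#' @param x a `"dc_shift"` object.
#' @param ... unused.
#' @return `tidy()` returns the per-temperature free-energy ladder;
#'   `glance()` the one-row offset summary.
#' @export
tidy.dc_shift <- function(x, ...) {
  x$dg_by_T
}

#' @rdname tidy.dc_shift
#' @export
glance.dc_shift <- function(x, ...) {
  tibble::tibble(
    dc = x$dc, se_dc = x$se_dc,
    dg_dc_298K_kJ_mol = dopachrome_free_energy(x, 298.15),
    n_points = nrow(x$kinetics_points)
  )
}
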