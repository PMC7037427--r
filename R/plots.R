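#' Plot simulated or measured progress curves
#'
#' Absorbance against time, coloured by initial substrate concentration and
#' faceted by temperature.
#'
#' @param traces a plate tibble (see [simulate_progress_curves()]).
#' @return A ggplot object.
#' @export
plot_progress_curves <- function(traces) {
  traces |>
    dplyr::filter(!.data$is_blank) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$time_s / 60, y = .data$absorbance_mOD,
      colour = factor(.data$substrate_mM),
      group = interaction(.data$substrate_mM, .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$temperature_C),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (min)", y = "absorbance (mOD)",
                  colour = "L-DOPA (mM)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$rates$substrate_mM), length.out = 200)
  curve <- tibble::tibble(
    substrate_mM = s_grid,
    v = object$vmax_mM_min * s_grid / (object$km_mM + s_grid))
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$substrate_mM,
                               y = .data$v_initial_mM_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$v),
                       colour = "firebrick") +
    ggplot2::labs(x = "[L-DOPA] (mM)", y = "initial velocity (mM/min)",
                  title = sprintf("Km = %.3g mM, Vmax = %.3g mM/min",
                                  object$km_mM, object$vmax_mM_min)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.thermo_signature <- function(object, ...) {
  line <- tibble::tibble(
    inv_T = seq(min(object$points$inv_T), max(object$points$inv_T),
                length.out = 50))
  line$ln_k <- predict_ln_k(object, 1 / line$inv_T)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$inv_T, y = .data$ln_k_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$ln_k),
                       colour = "firebrick") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln K",
                  title = sprintf("dH = %.3g kJ/mol, dS = %.3g kJ/(K mol)",
                                  object$dH_kJ_mol, object$dS_kJ_K_mol)) +
    ggplot2::theme_minimal()
}

#' Combined van 't Hoff plot table
#'
#' The four series of the combined plot: kinetics points, kinetics
#' trendline, docking association line, and the DC-shifted docking line.
#'
#' @param dc_result a `"dc_shift"` object.
#' @param n_grid number of grid points per line series.
#' @return A tibble with `series`, `inv_T`, `ln_k`.
#' @export
vant_hoff_plot_table <- function(dc_result, n_grid = 50) {
  stopifnot(inherits(dc_result, "dc_shift"))
  pts <- dc_result$kinetics_points
  inv_grid <- seq(min(pts$inv_T), max(pts$inv_T), length.out = n_grid)
  T_grid <- 1 / inv_grid
  dock <- predict_ln_k(dc_result$docking_signature, T_grid)
  kin_line <- if (nrow(pts) >= 2) {
    predict_ln_k(fit_vant_hoff(pts), T_grid)
  } else {
    rep(NA_real_, n_grid)
  }
  dplyr::bind_rows(
    tibble::tibble(series = "kinetics points", inv_T = pts$inv_T,
                   ln_k = pts$ln_k_norm),
    tibble::tibble(series = "kinetics trendline", inv_T = inv_grid,
                   ln_k = kin_line),
    tibble::tibble(series = "docking line", inv_T = inv_grid, ln_k = dock),
    tibble::tibble(series = "shifted docking line", inv_T = inv_grid,
                   ln_k = dock + dc_result$dc)
  )
}

#' @export
autoplot.dc_shift <- function(object, ...) {
  tab <- vant_hoff_plot_table(object)
  pts <- dplyr::filter(tab, .data$series == "kinetics points")
  lines <- dplyr::filter(tab, .data$series != "kinetics points")
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$inv_T, y = .data$ln_k,
                                      colour = .data$series,
                                      linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts, colour = "firebrick") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln K",
                  title = sprintf("DC = %.3g (dG_dc = %.3g kJ/mol at 298.15 K)",
                                  object$dc,
                                  dopachrome_free_energy(object, 298.15))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
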