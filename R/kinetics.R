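#' Beer-Lambert conversion of absorbance to concentration
#'
#' Converts dopachrome absorbance (mOD) to product concentration (mM) using
#' c = A / (epsilon * L). The conversion is linear and maps 0 mOD to 0 mM.
#' With the dopachrome constants epsilon = 3700 M^-1 cm^-1 and L = 0.3 cm,
#' 1110 mOD corresponds to 1 mM.
#'
#' @param a_mOD absorbance in milli optical density units.
#' @param epsilon_M_cm molar absorptivity (M^-1 cm^-1), > 0.
#' @param path_cm optical path length (cm), > 0.
#' @return Concentration in mM (same shape as `a_mOD`).
#' @export
absorbance_to_concentration <- function(a_mOD, epsilon_M_cm = 3700,
                                        path_cm = 0.3) {
  check_positive(epsilon_M_cm, "epsilon_M_cm")
  check_positive(path_cm, "path_cm")
  (a_mOD / 1000) / (epsilon_M_cm * path_cm) * 1000
}

#' Subtract the blank (baseline) trace from assay traces
#'
#' Pairs every non-blank trace with the substrate-free blank measured at the
#' same temperature and subtracts it pointwise. Blank values are matched by
#' nearest time within half the median sampling step; when several blank
#' replicates exist at a temperature they are averaged first.
#'
#' @param traces a tibble of absorbance traces with columns `time_s`,
#'   `temperature_C`, `substrate_mM`, `replicate`, `absorbance_mOD`,
#'   `is_blank` (as written by [simulate_progress_curves()]).
#' @return The corrected non-blank traces, with a `baseline_corrected`
#'   column set to `TRUE`.
#' @export
subtract_baseline <- function(traces) {
  stopifnot(all(c("time_s", "temperature_C", "absorbance_mOD", "is_blank")
                %in% names(traces)))
  blanks <- dplyr::filter(traces, .data$is_blank)
  assays <- dplyr::filter(traces, !.data$is_blank)
  if (nrow(blanks) == 0) {
    abort("No blank traces found; cannot subtract baseline.",
          class = "dopatherm_missing_blank")
  }
  blank_mean <- blanks |>
    dplyr::group_by(.data$temperature_C, .data$time_s) |>
    dplyr::summarise(blank_mOD = mean(.data$absorbance_mOD), .groups = "drop")
  purrr::map_dfr(split(assays, assays$temperature_C), function(tr) {
    bl <- dplyr::filter(blank_mean, .data$temperature_C == tr$temperature_C[1])
    if (nrow(bl) == 0) {
      abort(sprintf("No blank at %.4g degC.", tr$temperature_C[1]),
            class = "dopatherm_missing_blank")
    }
    step <- median(diff(sort(unique(tr$time_s))))
    idx <- vapply(tr$time_s, function(t) {
      j <- which.min(abs(bl$time_s - t))
      if (abs(bl$time_s[j] - t) > step / 2) NA_integer_ else j
    }, integer(1))
    if (all(is.na(idx))) {
      abort("Blank and assay traces share no overlapping time range.",
            class = "dopatherm_no_overlap")
    }
    tr$absorbance_mOD <- tr$absorbance_mOD -
      ifelse(is.na(idx), 0, bl$blank_mOD[pmax(idx, 1L)])
    tr$baseline_corrected <- TRUE
    tr
  })
}

#' Initial reaction velocity from one absorbance trace
#'
#' Converts the in-window absorbance readings to concentration (mM) and fits
#' an ordinary least-squares line of concentration on time over
#' `[0, window_s]`; the slope (converted to mM/min) is the initial velocity.
#' The default window is the first eight minutes of the reaction.
#'
#' @param trace a tibble for a single trace with columns `time_s` and
#'   `absorbance_mOD` (strictly increasing times, finite absorbances).
#' @param window_s analysis window (s); points with `time_s <= window_s`
#'   are used. At least 3 such points are required.
#' @param epsilon_M_cm,path_cm Beer-Lambert constants.
#' @return A one-row tibble: `v_initial_mM_min`, `se_mM_min`, `n_points`
#'   (plus `substrate_mM`, `temperature_C`, `replicate` when present in
#'   `trace`).
#' @export
estimate_initial_velocity <- function(trace, window_s = 480,
                                      epsilon_M_cm = 3700, path_cm = 0.3) {
  stopifnot(all(c("time_s", "absorbance_mOD") %in% names(trace)))
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing within a trace.",
          class = "dopatherm_invalid_trace")
  }
  if (any(!is.finite(trace$absorbance_mOD))) {
    abort("Absorbance values must be finite.", class = "dopatherm_invalid_trace")
  }
  inw <- trace[trace$time_s <= window_s, ]
  if (nrow(inw) < 3) {
    abort(sprintf("Need >= 3 points with time_s <= %g; got %d.",
                  window_s, nrow(inw)),
          class = "dopatherm_insufficient_data")
  }
  conc <- absorbance_to_concentration(inw$absorbance_mOD, epsilon_M_cm, path_cm)
  fit <- lm(conc ~ inw$time_s)
  # noise-free traces trigger summary.lm's perfect-fit warning; harmless here
  sm <- suppressWarnings(summary(fit)$coefficients)
  out <- tibble::tibble(
    v_initial_mM_min = unname(coef(fit)[2]) * 60,
    se_mM_min = unname(sm[2, "Std. Error"]) * 60,
    n_points = nrow(inw)
  )
  for (nm in c("substrate_mM", "temperature_C", "replicate")) {
    if (nm %in% names(trace)) out[[nm]] <- trace[[nm]][1]
  }
  out
}

#' Initial velocities for a whole plate
#'
#' Applies [estimate_initial_velocity()] to every
#' (temperature, substrate, replicate) trace in a plate table.
#'
#' @inheritParams estimate_initial_velocity
#' @param traces a plate tibble (non-blank rows are used; run
#'   [subtract_baseline()] first if blanks are present).
#' @return A tibble of initial rates, one row per trace.
#' @export
initial_velocities <- function(traces, window_s = 480,
                               epsilon_M_cm = 3700, path_cm = 0.3) {
  if ("is_blank" %in% names(traces)) {
    traces <- dplyr::filter(traces, !.data$is_blank)
  }
  traces |>
    dplyr::group_by(.data$temperature_C, .data$substrate_mM, .data$replicate) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(~ estimate_initial_velocity(
      .x, window_s = window_s,
      epsilon_M_cm = epsilon_M_cm, path_cm = path_cm)) |>
    dplyr::ungroup()
}

# sum of squared MM residuals on the log-parameter scale
mm_rss <- function(lpar, s, v) {
  pred <- exp(lpar[2]) * s / (exp(lpar[1]) + s)
  sum((v - pred)^2)
}

#' Fit the Michaelis-Menten equation to initial rates
#'
#' Least-squares fit of v = Vmax S / (Km + S) to initial-rate data at a
#' single temperature. The fit is performed in (log Km, log Vmax) so both
#' parameters are positive by construction; starting values are the maximum
#' observed rate and the (interpolated) substrate at half that rate, with
#' jittered restarts on failure. Standard errors come from the Jacobian at
#' the optimum and are mapped back to the natural scale by the delta method.
#'
#' @param rates a tibble with columns `substrate_mM` and `v_initial_mM_min`
#'   (at least 3 distinct substrate concentrations, one temperature).
#' @param n_restarts number of jittered restarts attempted on failure.
#' @return An object of class `"mm_fit"`: a list with `km_mM`,
#'   `vmax_mM_min`, `se_km`, `se_vmax`, `adj_r2`, `n_rates`,
#'   `temperature_C`, `rss`, `convergence`.
#' @export
fit_michaelis_menten <- function(rates, n_restarts = 5) {
  stopifnot(all(c("substrate_mM", "v_initial_mM_min") %in% names(rates)))
  s <- rates$substrate_mM
  v <- rates$v_initial_mM_min
  if (length(unique(s)) < 2) {
    abort("Km and Vmax are unidentifiable from a single substrate concentration.",
          class = "dopatherm_unidentifiable")
  }
  if (length(unique(s)) < 3) {
    abort("Need >= 3 distinct substrate concentrations.",
          class = "dopatherm_insufficient_data")
  }
  tC <- if ("temperature_C" %in% names(rates)) rates$temperature_C[1] else NA_real_
  if (diff(range(v)) <= 1e-12 * max(abs(v), 1e-30)) {
    abort("Rates do not vary with substrate; Km is unidentifiable (degenerate design).",
          class = "dopatherm_unidentifiable")
  }
  vmax0 <- max(v)
  half <- vmax0 / 2
  ord <- order(s)
  km0 <- tryCatch(stats::approx(v[ord], s[ord], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- median(s)
  starts <- list(c(log(km0), log(vmax0)))
  fit <- NULL
  last_err <- NULL
  for (try in seq_len(1 + n_restarts)) {
    st <- starts[[1]]
    if (try > 1) st <- st + rnorm(2, 0, 0.5)  # jittered restart
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ exp(lvmax) * s / (exp(lkm) + s),
        data = data.frame(s = s, v = v),
        start = list(lkm = st[1], lvmax = st[2]),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-12)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("Michaelis-Menten fit failed to converge after restarts: ",
                 conditionMessage(last_err)),
          class = "dopatherm_fit_failure")
  }
  lp <- coef(fit)
  km <- exp(lp[["lkm"]])
  vmax <- exp(lp[["lvmax"]])
  # unidentifiable plateau: Km pushed far beyond the sampled range
  if (km > 1e3 * max(s)) {
    abort("Km estimate diverged beyond the sampled substrate range; design is uninformative.",
          class = "dopatherm_unidentifiable")
  }
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se_lkm <- sqrt(vc[1, 1])
  se_lvmax <- sqrt(vc[2, 2])
  pred <- vmax * s / (km + s)
  rss <- sum((v - pred)^2)
  tss <- sum((v - mean(v))^2)
  n <- length(v)
  adj_r2 <- 1 - (1 - (1 - rss / tss)) * (n - 1) / (n - 2)
  structure(list(
    temperature_C = tC,
    km_mM = unname(km),
    vmax_mM_min = unname(vmax),
    se_km = unname(km * se_lkm),      # delta method from log scale
    se_vmax = unname(vmax * se_lvmax),
    adj_r2 = adj_r2,
    n_rates = n,
    rss = rss,
    convergence = fit$convInfo$stopMessage %||% "converged",
    rates = tibble::tibble(substrate_mM = s, v_initial_mM_min = v)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit%s\n  Km   = %.4g +/- %.2g mM\n  Vmax = %.4g +/- %.2g mM/min\n  adj R2 = %.3f (n = %d)\n",
    if (is.finite(x$temperature_C)) sprintf(" at %g degC", x$temperature_C) else "",
    x$km_mM, x$se_km, x$vmax_mM_min, x$se_vmax, x$adj_r2, x$n_rates))
  invisible(x)
}

#' Fit Michaelis-Menten parameters per (temperature, replicate)
#'
#' Convenience wrapper applying [fit_michaelis_menten()] within each
#' temperature x replicate group of an initial-rate table, returning one
#' tidy row per fit.
#'
#' @param rates output of [initial_velocities()].
#' @param by grouping columns; the default fits one curve per temperature
#'   and replicate (duplicate-averaged granularity is obtained by averaging
#'   rates over replicates first).
#' @return A tibble with one row per fit (columns as in [tidy.mm_fit()]).
#' @export
fit_michaelis_menten_by <- function(rates, by = c("temperature_C", "replicate")) {
  rates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      d$temperature_C <- if ("temperature_C" %in% names(key))
        key$temperature_C else d$temperature_C[1]
      out <- glance(fit_michaelis_menten(d))
      out$temperature_C <- NULL  # already a grouping key
      out
    }) |>
    dplyr::ungroup()
}

#' Average replicate Michaelis-Menten fits per temperature
#'
#' Unweighted mean and standard error of the mean of Km and Vmax across the
#' replicate fits at each temperature.
#'
#' @param fits a tibble of per-replicate fits with columns `temperature_C`,
#'   `km_mM`, `vmax_mM_min` (e.g. from [fit_michaelis_menten_by()]).
#' @return A tibble with one row per temperature: `km_mM`, `sem_km`,
#'   `vmax_mM_min`, `sem_vmax`, `n_fits`.
#' @export
aggregate_replicates <- function(fits) {
  if (nrow(fits) == 0) {
    abort("No fits to aggregate.", class = "dopatherm_insufficient_data")
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  fits |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(
      sem_km = sem(.data$km_mM),
      km_mM = mean(.data$km_mM),
      sem_vmax = sem(.data$vmax_mM_min),
      vmax_mM_min = mean(.data$vmax_mM_min),
      n_fits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("temperature_C", "km_mM", "sem_km",
                  "vmax_mM_min", "sem_vmax", "n_fits")
}

#' Proportional calibration of absorbance against calorimetric rates
#'
#' Estimates the proportionality constant between plate-reader absorbance
#' readings and calorimetry-derived reaction rates measured at the same
#' substrate concentrations: `mean_ratio` is the mean of uv/rate across
#' points, and the adjusted R-squared reports how well the one-parameter
#' proportional model uv = ratio * rate explains the absorbance values.
#'
#' @param pairs a tibble with columns `itc_rate_uM_s` and
#'   `uv_absorbance_mOD` (>= 2 rows).
#' @return An object of class `"ratio_fit"` with `mean_ratio`, `adj_r2`, `n`.
#' @export
fit_proportional_ratio <- function(pairs) {
  stopifnot(all(c("itc_rate_uM_s", "uv_absorbance_mOD") %in% names(pairs)))
  rate <- pairs$itc_rate_uM_s
  uv <- pairs$uv_absorbance_mOD
  if (length(rate) < 2) {
    abort("Need at least 2 rate/absorbance pairs.",
          class = "dopatherm_insufficient_data")
  }
  if (any(rate == 0)) {
    abort("Calorimetric rates must be non-zero to form ratios.",
          class = "dopatherm_invalid_value")
  }
  if (all(uv == 0)) {
    abort("All absorbance values are zero; the ratio is degenerate.",
          class = "dopatherm_degenerate")
  }
  ratio <- mean(uv / rate)
  resid <- uv - ratio * rate
  tss <- sum((uv - mean(uv))^2)
  r2 <- 1 - sum(resid^2) / tss
  n <- length(uv)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(mean_ratio = ratio, adj_r2 = adj_r2, n = n),
            class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("Proportional uv/rate calibration: ratio = %.4g (adj R2 = %.3f, n = %d)\n",
              x$mean_ratio, x$adj_r2, x$n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
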