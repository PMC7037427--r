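test_that("Beer-Lambert conversion matches the closed form and is linear", {
  expect_equal(absorbance_to_concentration(1110, 3700, 0.3), 1, tolerance = 1e-12)
  expect_equal(absorbance_to_concentration(0), 0)
  expect_equal(absorbance_to_concentration(37, 3700, 1), 0.010, tolerance = 1e-12)
  a <- runif(20, 0, 2000); b <- runif(20, 0, 2000)
  expect_equal(absorbance_to_concentration(a + b),
               absorbance_to_concentration(a) + absorbance_to_concentration(b))
  expect_error(absorbance_to_concentration(1, epsilon_M_cm = 0),
               class = "dopatherm_invalid_value")
  expect_error(absorbance_to_concentration(1, path_cm = -0.3),
               class = "dopatherm_invalid_value")
})

test_that("baseline subtraction is pointwise and temperature-matched", {
  t <- seq(0, 100, by = 5)
  mk <- function(vals, blank, temp = 25) tibble::tibble(
    time_s = t, temperature_C = temp, substrate_mM = if (blank) 0 else 1,
    replicate = 1L, absorbance_mOD = vals, is_blank = blank)
  tr <- mk(3 * t + 7, FALSE)
  # a trace minus an identical blank is identically zero
  out <- subtract_baseline(dplyr::bind_rows(tr, mk(3 * t + 7, TRUE)))
  expect_equal(out$absorbance_mOD, rep(0, length(t)))
  expect_true(all(out$baseline_corrected))
  # a zero blank leaves the trace unchanged
  out2 <- subtract_baseline(dplyr::bind_rows(tr, mk(rep(0, length(t)), TRUE)))
  expect_equal(out2$absorbance_mOD, tr$absorbance_mOD)
  # blank at a different temperature does not pair
  expect_error(
    subtract_baseline(dplyr::bind_rows(tr, mk(rep(0, length(t)), TRUE, temp = 37))),
    class = "dopatherm_missing_blank")
  # disjoint time ranges cannot be paired
  bl <- mk(rep(0, length(t)), TRUE)
  bl$time_s <- bl$time_s + 10000
  expect_error(subtract_baseline(dplyr::bind_rows(tr, bl)),
               class = "dopatherm_no_overlap")
})

test_that("initial velocity is the windowed least-squares slope in mM/min", {
  t <- seq(0, 900, by = 5)
  # exact concentration line of slope 0.010 mM/min -> absorbance via eps*L
  conc <- 0.010 * t / 60
  tr <- tibble::tibble(time_s = t, absorbance_mOD = conc * 3700 * 0.3)
  iv <- estimate_initial_velocity(tr)
  expect_equal(iv$v_initial_mM_min, 0.010, tolerance = 1e-10)
  expect_equal(iv$se_mM_min, 0, tolerance = 1e-12)
  expect_equal(iv$n_points, sum(t <= 480))

  # linear for 8 min then flat: the estimate is the slope of the windowed
  # fit, not of the whole trace
  conc2 <- ifelse(t <= 480, 0.010 * t / 60, 0.010 * 480 / 60)
  tr2 <- tibble::tibble(time_s = t, absorbance_mOD = conc2 * 3700 * 0.3)
  iv2 <- estimate_initial_velocity(tr2)
  inw <- t <= 480
  oracle <- ols_line(t[inw], conc2[inw])["slope"] * 60
  expect_equal(iv2$v_initial_mM_min, unname(oracle), tolerance = 1e-12)
  expect_gt(iv2$v_initial_mM_min,
            ols_line(t, conc2)["slope"] * 60)  # full-trace slope is smaller

  expect_error(estimate_initial_velocity(tr[1:2, ]),
               class = "dopatherm_insufficient_data")
  expect_error(
    estimate_initial_velocity(tibble::tibble(time_s = c(0, 5, 5),
                                             absorbance_mOD = 1:3)),
    class = "dopatherm_invalid_trace")
})

test_that("Michaelis-Menten fitting recovers exact parameters and beats a grid oracle", {
  # noise-free recovery at the published 37 degC point estimates
  rates <- exact_rates(km = 0.70, vmax = 0.038)
  fit <- fit_michaelis_menten(rates)
  expect_equal(fit$km_mM, 0.70, tolerance = 1e-6)
  expect_equal(fit$vmax_mM_min, 0.038, tolerance = 1e-6)
  expect_gt(fit$adj_r2, 0.999)

  # noisy data: the optimum never exceeds a 400 x 400 log-grid search
  noisy <- rates
  noisy$v_initial_mM_min <- noisy$v_initial_mM_min *
    (1 + withr::with_seed(21L, rnorm(nrow(noisy), 0, 0.08)))
  nf <- fit_michaelis_menten(noisy)
  km_grid <- exp(seq(log(0.01), log(50), length.out = 400))
  vm_grid <- exp(seq(log(1e-4), log(1), length.out = 400))
  s <- noisy$substrate_mM
  v <- noisy$v_initial_mM_min
  rss_grid <- vapply(km_grid, function(km) {
    frac <- s / (km + s)
    min(vapply(vm_grid, function(vm) sum((v - vm * frac)^2), numeric(1)))
  }, numeric(1))
  expect_lte(nf$rss, min(rss_grid) + 1e-8)
})

test_that("degenerate rate designs are flagged unidentifiable", {
  flat <- tibble::tibble(substrate_mM = doubling_series_mM,
                         v_initial_mM_min = rep(0.02, 7))
  expect_error(fit_michaelis_menten(flat), class = "dopatherm_unidentifiable")
  one_s <- tibble::tibble(substrate_mM = rep(1.5, 5),
                          v_initial_mM_min = runif(5, 0.01, 0.02))
  expect_error(fit_michaelis_menten(one_s), class = "dopatherm_unidentifiable")
})

test_that("replicate aggregation averages within temperature", {
  f1 <- tibble::tibble(temperature_C = 25, km_mM = 0.5, vmax_mM_min = 0.03)
  three <- dplyr::bind_rows(f1, f1, f1)
  agg <- aggregate_replicates(three)
  expect_equal(agg$km_mM, 0.5)
  expect_equal(agg$sem_km, 0)
  two <- tibble::tibble(temperature_C = c(31, 31), km_mM = c(0.4, 0.6),
                        vmax_mM_min = c(0.03, 0.05))
  agg2 <- aggregate_replicates(two)
  expect_equal(agg2$km_mM, 0.5)
  expect_equal(agg2$sem_km, sd(c(0.4, 0.6)) / sqrt(2))
  mixed <- tidyr::crossing(temperature_C = assay_temps_C, replicate = 1:3) |>
    dplyr::mutate(km_mM = 0.1 * replicate, vmax_mM_min = 0.01 * replicate)
  agg3 <- aggregate_replicates(mixed)
  expect_equal(nrow(agg3), 4)
  expect_equal(agg3$n_fits, rep(3L, 4))
  expect_error(aggregate_replicates(mixed[0, ]),
               class = "dopatherm_insufficient_data")
})

test_that("proportional calibration reproduces an exact ratio with adj R2 = 1", {
  rate <- c(0.01, 0.02, 0.04, 0.06, 0.08, 0.095)
  pairs <- tibble::tibble(itc_rate_uM_s = rate,
                          uv_absorbance_mOD = 20.34 * rate)
  fit <- fit_proportional_ratio(pairs)
  expect_equal(fit$mean_ratio, 20.34, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1.0, tolerance = 1e-12)
  unit <- fit_proportional_ratio(
    tibble::tibble(itc_rate_uM_s = rate, uv_absorbance_mOD = rate))
  expect_equal(unit$mean_ratio, 1.0)
  expect_error(fit_proportional_ratio(
    tibble::tibble(itc_rate_uM_s = c(0, 0.01),
                   uv_absorbance_mOD = c(1, 2))),
    class = "dopatherm_invalid_value")
  expect_error(fit_proportional_ratio(
    tibble::tibble(itc_rate_uM_s = rate, uv_absorbance_mOD = rep(0, 6))),
    class = "dopatherm_degenerate")
  expect_error(fit_proportional_ratio(
    tibble::tibble(itc_rate_uM_s = 0.01, uv_absorbance_mOD = 0.2)),
    class = "dopatherm_insufficient_data")
})

test_that("the curve route agrees with an independent windowed-OLS + MM oracle", {
  # zero-noise consistency: running the pipeline on exact depleted curves
  # must equal applying the same windowed-OLS slope + MM fit computed here
  # from the raw integrator output
  p <- sim_params(noise_sigma_mOD = 0, n_replicates = 1)
  rv <- simulate_progress_curves(p) |> initial_velocities()
  for (i in seq_along(p$temperatures_C)) {
    prog <- mm_progress(p$substrate_series_mM, p$km_by_T_mM[i],
                        p$vmax_by_T_mM_min[i], p$duration_s, p$step_s)
    oracle_v <- vapply(split(prog, prog$substrate_mM0), function(d) {
      inw <- d$time_s <= 480
      unname(ols_line(d$time_s[inw], d$product_mM[inw])["slope"]) * 60
    }, numeric(1))
    got <- rv |>
      dplyr::filter(temperature_C == p$temperatures_C[i]) |>
      dplyr::arrange(substrate_mM) |>
      dplyr::pull(v_initial_mM_min)
    expect_equal(got, unname(oracle_v[order(as.numeric(names(oracle_v)))]),
                 tolerance = 1e-9)
  }
})
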