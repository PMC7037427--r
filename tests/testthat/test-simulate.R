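test_that("progress-curve integrator conserves mass and converges with step halving", {
  s0 <- c(0.09375, 0.75, 6)
  prog <- mm_progress(s0, km_mM = 0.5, vmax_mM_min = 0.04,
                      duration_s = 600, step_s = 5)
  expect_equal(prog$substrate_mM + prog$product_mM,
               prog$substrate_mM0, tolerance = 1e-9)
  fine <- mm_progress(s0, 0.5, 0.04, duration_s = 600, step_s = 2.5)
  p_end <- prog |> dplyr::filter(time_s == 600) |> dplyr::pull(product_mM)
  p_end_fine <- fine |> dplyr::filter(time_s == 600) |> dplyr::pull(product_mM)
  expect_lt(max(abs(p_end - p_end_fine) / p_end), 1e-6)
})

test_that("in the zero-order regime the early product slope equals Vmax", {
  # S0 >> Km: v ~ Vmax, so P(t) is a line of slope Vmax at early times
  prog <- mm_progress(100, km_mM = 0.5, vmax_mM_min = 0.04,
                      duration_s = 300, step_s = 5)
  slope <- ols_line(prog$time_s / 60, prog$product_mM)["slope"]
  expect_equal(unname(slope), 0.04, tolerance = 0.01)
})

test_that("simulated plates are seed-reproducible and carry blanks", {
  p <- sim_params(noise_sigma_mOD = 2, n_replicates = 2, seed = 42L)
  a <- simulate_progress_curves(p)
  b <- simulate_progress_curves(p)
  expect_identical(a, b)
  p2 <- sim_params(noise_sigma_mOD = 2, n_replicates = 2, seed = 43L)
  expect_false(identical(a, simulate_progress_curves(p2)))
  expect_setequal(unique(a$temperature_C[a$is_blank]), p$temperatures_C)
  # one blank trace per temperature, substrate-free
  expect_true(all(a$substrate_mM[a$is_blank] == 0))
  # Beer-Lambert scale: noise-free 1 mM product would read eps*L*1 mOD
  p0 <- sim_params(noise_sigma_mOD = 0, n_replicates = 1)
  cur <- simulate_progress_curves(p0)
  prog <- mm_progress(p0$substrate_series_mM, p0$km_by_T_mM[1],
                      p0$vmax_by_T_mM_min[1], p0$duration_s, p0$step_s)
  one <- cur |>
    dplyr::filter(temperature_C == 25, substrate_mM == 6, !is_blank)
  expect_equal(one$absorbance_mOD,
               3700 * 0.3 * prog$product_mM[prog$substrate_mM0 == 6],
               tolerance = 1e-12)
})

test_that("invalid simulation grids and values are rejected", {
  expect_error(sim_params(step_s = 600, duration_s = 600),
               class = "dopatherm_invalid_grid")
  expect_error(sim_params(epsilon_M_cm = -1),
               class = "dopatherm_invalid_value")
  expect_error(sim_params(temperatures_C = c(25, 25)),
               class = "dopatherm_invalid_value")
  expect_error(sim_params(substrate_series_mM = c(0, 1)),
               class = "dopatherm_invalid_value")
  expect_error(mm_progress(1, 0.5, 0.04, duration_s = 5, step_s = 5),
               class = "dopatherm_invalid_grid")
})

test_that("km_from_signature inverts the van 't Hoff line", {
  kt <- km_from_signature(-21.26, 0.058, 1e-6, assay_temps_C)
  pts <- build_vant_hoff_points(kt, 1e-6)
  sig <- fit_vant_hoff(pts)
  expect_equal(sig$dH_kJ_mol, -21.26, tolerance = 1e-9)
  expect_equal(sig$dS_kJ_K_mol, 0.058, tolerance = 1e-9)
})

test_that("noise-free decoy-free docking tables invert to the generator signature", {
  dk <- simulate_docking_table(-25.72, 0.078, n_runs = 5,
                               decoy_fraction = 0, energy_noise_kJ = 0,
                               seed = 7L)
  expect_true(all(dk$in_site_truth))
  expect_false(anyDuplicated(dk$run_id) > 0)
  best <- best_pose_per_temperature(dk)
  sig <- fit_vant_hoff(docking_vant_hoff_points(best))
  expect_equal(sig$dH_kJ_mol, -25.72, tolerance = 1e-9)
  expect_equal(sig$dS_kJ_K_mol, 0.078, tolerance = 1e-9)
})

test_that("decoy draws follow the requested fraction and tables are seed-stable", {
  dk <- simulate_docking_table(-25.72, 0.078, temperatures_C = 25,
                               n_runs = 200, decoy_fraction = 0.5,
                               energy_noise_kJ = 1, seed = 11L)
  n_in <- sum(dk$in_site_truth)
  # binomial(200, 0.5): stay within 3 SD of the mean
  expect_lt(abs(n_in - 100), 3 * sqrt(200 * 0.25) + 1)
  expect_identical(dk, simulate_docking_table(
    -25.72, 0.078, temperatures_C = 25, n_runs = 200,
    decoy_fraction = 0.5, energy_noise_kJ = 1, seed = 11L))
  expect_error(simulate_docking_table(-25, 0.07, n_runs = 0),
               class = "dopatherm_invalid_value")
  expect_error(simulate_docking_table(-25, 0.07, decoy_fraction = 1),
               class = "dopatherm_invalid_value")
})

test_that("pose PDB fixtures round-trip their offsets through a PDB parser", {
  cu <- rbind(c(12, 8, 30), c(15.5, 8, 30))
  tf <- withr::local_tempfile(fileext = ".pdb")
  simulate_pose_pdb(cu, c(3, 12), seed = 5L, path = tf)
  d <- measure_pose_distances(tf)
  expect_equal(d$pose_id, c(1L, 2L))
  expect_equal(d$min_o_cu_A, c(3, 12), tolerance = 0.01)
  # receptor-only file is still a valid PDB
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  simulate_pose_pdb(cu, numeric(), path = tf2)
  site <- read_active_site(tf2)
  expect_equal(site$cu_a, c(12, 8, 30))
  expect_error(simulate_pose_pdb(cu, c(-1)),
               class = "dopatherm_invalid_value")
  expect_error(simulate_pose_pdb(rbind(cu[1, ], cu[1, ]), 3),
               class = "dopatherm_invalid_value")
})

test_that("large pose fixtures keep unique pose ids and stay parseable", {
  cu <- rbind(c(0, 0, 0), c(4, 0, 0))
  offs <- runif(1000, 2, 20)
  tf <- withr::local_tempfile(fileext = ".pdb")
  simulate_pose_pdb(cu, offs, seed = 9L, path = tf)
  d <- measure_pose_distances(tf)
  expect_equal(nrow(d), 1000)
  expect_false(anyDuplicated(d$pose_id) > 0)
  expect_equal(d$min_o_cu_A[order(d$pose_id)], offs, tolerance = 0.01)
})

test_that("paired calorimetry/absorbance tables recover the true ratio", {
  pairs <- simulate_itc_rate_pairs(true_ratio = 20.34, noise_rel = 0)
  fit <- fit_proportional_ratio(pairs)
  expect_equal(fit$mean_ratio, 20.34, tolerance = 1e-12)
  expect_identical(pairs, simulate_itc_rate_pairs(true_ratio = 20.34,
                                                  noise_rel = 0))
  noisy1 <- simulate_itc_rate_pairs(noise_rel = 0.05, seed = 1L)
  noisy2 <- simulate_itc_rate_pairs(noise_rel = 0.05, seed = 2L)
  expect_false(identical(noisy1, noisy2))
  expect_error(simulate_itc_rate_pairs(true_ratio = 0),
               class = "dopatherm_invalid_value")
})
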