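# Orchestration tests use the coarse geometry and reduced photon counts.

.small_cfg <- function(...) {
  experiment_config(geometry = small_geometry_params(), n_photons = 2e4,
                    seed = 5, maxit = 150, ...)
}

test_that("configuration validation catches malformed inputs", {
  expect_error(experiment_config(scenario = "sideways"))
  expect_error(experiment_config(Ca_grid = numeric(0)), "non-empty")
  cfg <- .small_cfg()
  cfg$Ca_grid <- numeric(0)
  expect_error(run_aci_curve(cfg), "empty")
  cfg <- .small_cfg()
  cfg$I_grid <- numeric(0)
  expect_error(run_light_curve(cfg), "empty")
})

test_that("A_n increases with ambient CO2 and with irradiance", {
  cfg <- .small_cfg(Ca_grid = c(100, 250, 380, 700),
                    I_grid = c(150, 500, 1500))
  aci <- run_aci_curve(cfg)
  expect_equal(nrow(aci), 4)
  expect_true(all(diff(aci$A_n) > 0))
  expect_true(all(diff(aci$C_i) > 0))
  lrc <- run_light_curve(cfg)
  expect_equal(nrow(lrc), 3)
  expect_true(all(diff(lrc$A_n) > 0))
  # saturating shape: the slope flattens at high light
  slopes <- diff(lrc$A_n) / diff(lrc$I_inc)
  expect_lt(slopes[2], slopes[1])
})

test_that("well-mixed oracle agrees with the transport solver when mixing is fast", {
  vol <- small_volume()
  props <- chlorophyll_absorption(optical_properties(), vol)
  f <- run_light_model(vol, props, n_photons = 2e4, seed = 9)
  en <- energetics_state(vol, f, incident_light(1500))
  st <- anatomical_stats(vol)
  scale <- 1e4
  tp_fast <- transport_params(
    D_co2_liquid = 1.89e-9 * scale, D_co2_gas = 1.57e-5 * scale,
    D_o2_liquid = 1.97e-9 * scale, D_o2_gas = 2.10e-5 * scale,
    D_hco3_liquid = 1.17e-9 * scale,
    P_co2_bs_membrane = 3.5e-3 * scale, P_co2_chloroplast = 1.75e-3 * scale,
    P_co2_m_membrane = 1.6e-2 * scale, P_o2_chloroplast = 1.25e-2 * scale,
    P_o2_membrane = 2.5e-2 * scale, g_s = 0.2 * scale)
  res3d <- solve_steady_state(vol, en, tp_fast, maxit = 150)
  oracle <- well_mixed_oracle(st, en, transport_params(),
                              conductance_scale = scale)
  expect_true(oracle$converged)
  expect_equal(res3d$A_n, oracle$A_n, tolerance = 0.02)
})

test_that("well-mixed oracle behaves sensibly at its edges", {
  vol <- small_volume()
  props <- chlorophyll_absorption(optical_properties(), vol)
  f <- run_light_model(vol, props, n_photons = 2e4, seed = 9)
  en <- energetics_state(vol, f, incident_light(1500))
  st <- anatomical_stats(vol)
  o1 <- well_mixed_oracle(st, en)
  # no PEPC capacity: the CO2-concentrating mechanism collapses and only
  # plasmodesmata-fed direct fixation remains
  kp0 <- kinetic_params(V_pmax = 1e-9)
  o0 <- well_mixed_oracle(st, en, kp = kp0)
  expect_lt(o0$A_n, 0.6 * o1$A_n)
  expect_lt(o0$C_BS, o1$C_BS)
  # larger bundle-sheath conductance lowers the concentration gradient
  tp_leaky <- transport_params(zeta_plasmodesmata = 0.3)
  o2 <- well_mixed_oracle(st, en, tp = tp_leaky)
  expect_lt(o2$C_BS, o1$C_BS)
})

test_that("2D cross-sections reproduce the 3D result for a uniform phantom", {
  # a laterally uniform (y-invariant) tissue: every cross-section must give
  # the 3D answer once the airspace is pinned at the 3D mean
  vol0 <- small_volume()
  labs <- vol0$labels
  labs[] <- labs[, rep(1L, dim(labs)[2]), ]       # replicate slice 1 along y
  ids <- vol0$cell_instance_ids
  ids[] <- ids[, rep(1L, dim(ids)[2]), ]
  vol <- label_volume(labs, vol0$voxel_pitch_um, cell_instance_ids = ids,
                      cells = vol0$cells, params = vol0$params)
  cfg <- .small_cfg()
  cfg$geometry <- vol
  res3d <- run_pipeline(cfg)
  # uniform light along y to match the y-invariant tissue
  res3d$energy$j_let_density[] <-
    res3d$energy$j_let_density[, rep(1L, dim(labs)[2]), ]
  # symmetry oracle: on a y-invariant tissue the in-plane solve must equal
  # the 3D solve under the same uniform-airspace treatment
  L <- kranz_labels()
  mean_c <- mean(res3d$co2[vol$labels == L["IAS"]])
  mean_o <- mean(res3d$o2[vol$labels == L["IAS"]])
  pinned <- solve_steady_state(vol, res3d$energy, cfg$transport,
                               cfg$kinetics, pore_scale = res3d$pore_scale,
                               maxit = 150,
                               fix_gas_at = c(co2 = mean_c, o2 = mean_o))
  slice <- run_2d_slice_mode(cfg, slice_y = 3L, result3d = res3d)
  expect_equal(slice$slices$A_n, pinned$A_n, tolerance = 0.02)
  # the uniform-airspace premise makes the 2D mode underestimate the full
  # 3D assimilation on this airspace network
  expect_lt(slice$slices$A_n, res3d$A_n)
  expect_error(run_2d_slice_mode(cfg, slice_y = 999L, result3d = res3d),
               "invalid")
})

test_that("report writes deterministic tables with provenance headers", {
  dir1 <- file.path(tempdir(), "rep1")
  dir2 <- file.path(tempdir(), "rep2")
  tab <- data.frame(a = 1:3, b = c(0.1, 0.2, 0.3))
  cfg <- .small_cfg()
  f1 <- report(list(curve = tab), dir1, cfg)
  f2 <- report(list(curve = tab), dir2, cfg)
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1, n = 1), "kranzsim")
  expect_error(report(list(tab), dir1), "malformed")
  unlink(c(dir1, dir2), recursive = TRUE)
})
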