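test_that("Beer-Lambert slab oracle: absorbing, index-matched slab", {
  vol <- slab_volume(thickness_vox = 50, pitch_um = 4)   # 200 um slab
  mua <- 1e4
  props <- slab_props(mua = mua, mus = 0)
  f <- run_photon_transport(vol, props, 665, n_photons = 4e5, seed = 11)
  T_expected <- exp(-mua * 200e-6)   # exp(-2)
  expect_equal(unname(f$budget["T"]), T_expected, tolerance = 0.01)
  expect_equal(unname(f$budget["R"]), 0, tolerance = 1e-12)
  expect_equal(unname(f$budget["A"]), 1 - T_expected, tolerance = 0.01)
})

test_that("pure scattering slab absorbs nothing and conserves photons", {
  vol <- slab_volume()
  props <- slab_props(mua = 0, mus = 2e4, g = 0.9)
  f <- run_photon_transport(vol, props, 665, n_photons = 1e5, seed = 4)
  expect_equal(unname(f$budget["A"]), 0, tolerance = 1e-12)
  expect_equal(sum(f$budget[c("R", "T")]), 1, tolerance = 1e-9)
  # transparent slab: everything transmits
  props0 <- slab_props(mua = 0, mus = 0)
  f0 <- run_photon_transport(vol, props0, 665, n_photons = 1e4, seed = 4)
  expect_equal(unname(f0$budget["T"]), 1)
})

test_that("photon budget closes and the voxel field integrates to A", {
  vol <- small_volume()
  props <- chlorophyll_absorption(optical_properties(), vol)
  f <- run_photon_transport(vol, props, 665, n_photons = 1e5, seed = 2)
  # R + T + A + lateral_loss = 1 within 3 Monte Carlo standard errors
  tot <- sum(f$budget)
  sigma <- 1 / sqrt(f$n_photons)
  expect_lt(abs(tot - 1), 3 * sigma + 1e-9)
  expect_equal(sum(f$frac_absorbed), unname(f$budget["A"]), tolerance = 1e-9)
  expect_true(all(f$frac_absorbed >= 0))
  # determinism
  f2 <- run_photon_transport(vol, props, 665, n_photons = 1e5, seed = 2)
  expect_identical(f$frac_absorbed, f2$frac_absorbed)
})

test_that("Monte Carlo error scales as one over the square root of photons", {
  vol <- slab_volume(thickness_vox = 20)
  props <- slab_props(mua = 5e3, mus = 5e3, g = 0.8)
  A_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      run_photon_transport(vol, props, 665, n, seed = s)$budget[["A"]]
    }, 0)
  }
  s_small <- sd(A_at(1e4, 1:8))
  s_big <- sd(A_at(9e4, 1:8))
  expect_gt(s_small / s_big, 1.5)   # expected ratio 3
  expect_lt(s_small / s_big, 6)
})

test_that("chlorophyll absorption assignment matches the arithmetic", {
  vol <- small_volume()
  st <- anatomical_stats(vol)
  props <- chlorophyll_absorption(optical_properties(), vol, chl_leaf = 539,
                                  f_chl_bs = 0.5)
  tab <- props[["665"]]
  mua_m <- tab$mua[tab$class == "M_CHLOROPLAST"]
  expect_equal(mua_m, unname(269.5 * 0.00466 / st$chloroplast_volume_m),
               tolerance = 1e-9)
  # reference arithmetic: 269.5 umol m-2 over 13e-6 m3 m-2 at 0.00466
  expect_equal(269.5 * 0.00466 / 13e-6, 9.66e4, tolerance = 1e-3)
  # zero bundle-sheath fraction zeroes the BS coefficient
  p0 <- chlorophyll_absorption(optical_properties(), vol, f_chl_bs = 0)
  expect_equal(p0[["665"]]$mua[p0[["665"]]$class == "BS_CHLOROPLAST"], 0)
})

test_that("wavelength combination is a convex voxelwise blend", {
  vol <- small_volume()
  props <- chlorophyll_absorption(optical_properties(), vol)
  fr <- run_photon_transport(vol, props, 665, 1e4, seed = 1)
  fb <- run_photon_transport(vol, props, 470, 1e4, seed = 2)
  only_red <- combine_wavelengths(list("470" = fb, "665" = fr),
                                  c("665" = 1.0))
  expect_identical(only_red$frac_absorbed, fr$frac_absorbed)
  both <- combine_wavelengths(list("470" = fb, "665" = fr))
  expect_equal(both$frac_absorbed, 0.1 * fb$frac_absorbed +
                 0.9 * fr$frac_absorbed, tolerance = 1e-12)
  expect_equal(unname(both$budget["A"]),
               0.1 * unname(fb$budget["A"]) + 0.9 * unname(fr$budget["A"]),
               tolerance = 1e-12)
  same <- combine_wavelengths(list("470" = fr, "665" = fr), c("470" = 0.3,
                                                             "665" = 0.7))
  expect_equal(same$frac_absorbed, fr$frac_absorbed, tolerance = 1e-12)
})

test_that("depth profile sums to total absorbance and accumulates monotonically", {
  vol <- small_volume()
  props <- chlorophyll_absorption(optical_properties(), vol)
  f <- run_photon_transport(vol, props, 665, 1e4, seed = 5)
  prof <- depth_absorption_profile(f)
  expect_equal(sum(prof$absorbed), unname(f$budget["A"]), tolerance = 1e-9)
  expect_true(all(diff(cumsum(prof$absorbed)) >= -1e-15))
  cls <- depth_absorption_profile(f, vol, "BS_CHLOROPLAST")
  L <- kranz_labels()
  expect_equal(sum(cls$absorbed),
               sum(f$frac_absorbed[vol$labels == L["BS_CHLOROPLAST"]]),
               tolerance = 1e-12)
})

test_that("absorbed irradiance density books back to class absorbances", {
  vol <- small_volume()
  props <- chlorophyll_absorption(optical_properties(), vol)
  f <- run_photon_transport(vol, props, 665, 1e4, seed = 6)
  li <- incident_light(1500)
  irr <- absorbed_irradiance_density(f, li, vol)
  st <- anatomical_stats(vol)
  h <- vol$voxel_pitch_um * 1e-6
  # integral of the density times voxel volume / S_leaf = I_inc * absorbance
  expect_equal(sum(irr$density) * h^3 / st$S_leaf,
               1500 * unname(f$budget["A"]), tolerance = 1e-9)
  expect_equal(irr$I_abs_M, 1500 * irr$absorbance_M, tolerance = 1e-12)
  # the worked split: class absorbances (0.55, 0.28) at 1500
  expect_equal(0.55 * 1500, 825)
  expect_equal(0.28 * 1500, 420)
  # zero field gives zero density
  f0 <- f; f0$frac_absorbed[] <- 0
  irr0 <- absorbed_irradiance_density(f0, li, vol)
  expect_true(all(irr0$density == 0))
})

test_that("degenerate optical inputs are rejected", {
  vol <- small_volume()
  props <- optical_properties()
  props[["665"]]$mua[5] <- NA
  expect_error(run_photon_transport(vol, props, 665, 1e4, 1), "non-finite")
  expect_error(run_photon_transport(vol, optical_properties(), 550, 1e4, 1),
               "wavelength")
  expect_error(run_photon_transport(vol, optical_properties(), 665, 100, 1),
               "at least")
  expect_error(incident_light(1000, c("470" = 0.5, "665" = 0.4)), "sum to 1")
})
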