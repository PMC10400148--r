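test_that("cyclic electron transport fraction reproduces the reported pairs", {
  # printed u -> printed fCET pairs; the computed fractions agree with the
  # reported two-decimal values to one printed unit (u = 0.89 computes to
  # 0.209, reported as 0.20)
  pairs <- data.frame(
    u = c(0.89, 0.28, 0.33, 0.96, 0.31),
    fCET = c(0.20, 0.85, 0.81, 0.08, 0.83)
  )
  got <- cet_fraction(pairs$u)
  expect_true(all(abs(got - pairs$fCET) <= 0.011))
  exact <- 2:5  # these round-trip exactly at two decimals
  expect_equal(round(got[exact], 2), pairs$fCET[exact])
  # the reported aggregative mesophyll pair (u = 0.99 -> 0.01) computes to
  # 0.021; the printed value reflects rounding of u upstream
  expect_equal(round(cet_fraction(0.99), 2), 0.02)
  expect_equal(cet_fraction(1), 0)
  expect_equal(cet_fraction(0), 1)
})

test_that("fCET is independent of the absorbed-irradiance scale", {
  p <- energetics_params()
  for (u in c(0.1, 0.28, 0.5, 0.89, 0.97)) {
    for (I in c(1e-3, 1, 1e4)) {
      cet <- p$phi1_LL * (1 - u) * I
      let <- p$phi2_LL / (1 + p$phi2_LL / p$phi1_LL) * u * I
      expect_equal(cet / (cet + let), cet_fraction(u, p), tolerance = 1e-12)
    }
  }
})

test_that("alpha2 under limiting light matches direct arithmetic", {
  expect_equal(alpha2_ll(0), 0.83 / 1.88298, tolerance = 1e-4)
  expect_equal(alpha2_ll(1), 0)
  expect_equal(alpha2_ll(0.85), 0.1245 / 1.03298, tolerance = 1e-4)
})

test_that("non-rectangular hyperbola returns the smaller root and its limits", {
  theta <- 0.97
  aI <- 44.08; jmax <- 138.43
  j <- potential_let_rate(aI / 0.4408, 0.4408, jmax, theta)
  # root residual
  expect_lt(abs(theta * j^2 - (aI + jmax) * j + aI * jmax), 1e-6)
  expect_equal(j, 43.5, tolerance = 0.01)
  # saturation and limiting-light slope
  expect_equal(potential_let_rate(1e9, 0.44, jmax, theta), jmax,
               tolerance = 1e-3)
  small <- potential_let_rate(1e-6, 0.44, jmax, theta)
  expect_equal(small / 1e-6, 0.44, tolerance = 1e-4)
  # bounded by both branches on random inputs
  set.seed(42)
  I <- runif(100, 0, 5000); a <- runif(100, 0.1, 0.5)
  j <- potential_let_rate(I, a, jmax, theta)
  expect_true(all(j <= pmin(a * I, jmax) + 1e-9))
  # Blackman limit at theta = 0
  expect_equal(potential_let_rate(c(10, 1e4), 0.4, 100, 0), c(4, 100))
})

test_that("ATP production multiplier and singularities", {
  expect_equal(atp_multiplier(0), 0.75)
  expect_equal(atp_multiplier(0.85), 2.15 / 0.6, tolerance = 1e-12)
  expect_error(atp_production(10, 1, class_name = "bundle sheath"),
               "bundle sheath")
  expect_equal(atp_production(0, 0.2), 0)
  # field form integrates per leaf area
  expect_equal(
    atp_production(rep(2, 10), 0, S_leaf = 1e-4, voxel_volume = 1e-6),
    0.75 * 2 * 10 * 1e-6 / 1e-4)
})

test_that("NADPH production is half the LET electron flux", {
  expect_equal(nadph_production(0), 0)
  expect_equal(nadph_production(rep(2, 5), S_leaf = 1e-3, voxel_volume = 1e-5),
               0.5 * 2 * 5 * 1e-5 / 1e-3)
  # consistency with the ATP multiplier
  j <- 123.4; f <- 0.3
  expect_equal(nadph_production(j),
               0.5 * atp_production(j, f) / atp_multiplier(f))
})

test_that("bundle-sheath fractions behave at the trivial points", {
  expect_equal(bundle_fractions(10, 10)$fATP_BS, 0.5)
  expect_equal(bundle_fractions(10, 0)$fATP_BS, 0)
  fr <- bundle_fractions(3, 1, 8, 2)
  expect_equal(fr$fNADPH_BS, 0.2)
})

test_that("fluorescence-derived ATP production", {
  rec <- fluorescence_record(1500, Fs = 0.5, Fm_prime = 1)
  expect_equal(atp_from_fluorescence(rec), 406.25)
  expect_equal(atp_from_fluorescence(fluorescence_record(1500, 1, 1)), 0)
  p0 <- energetics_params(x = 0)
  expect_equal(atp_from_fluorescence(rec, p0), 0.325 * 1500 * 0.5)
  expect_error(fluorescence_record(1500, 0.5, 0.4))
})

test_that("jmax fitting recovers known capacities from noisy records", {
  p <- energetics_params()
  abs_M <- 0.55; abs_BS <- 0.28
  a2_M <- alpha2_ll(cet_fraction(p$u_M, p), p)
  a2_BS <- alpha2_ll(cet_fraction(p$u_BS, p), p)
  ratio <- a2_BS * abs_BS / (a2_M * abs_M)
  jmax_M_true <- 140
  jmax_BS_true <- ratio * jmax_M_true
  I <- c(50, 150, 300, 600, 1000, 1500, 2000)
  mod <- atp_light_response(I, abs_M, abs_BS, p, jmax_M = jmax_M_true,
                            jmax_BS = jmax_BS_true)
  set.seed(7)
  noisy <- mod$jATP * (1 + rnorm(length(I), 0, 0.01))
  # invert the fluorescence relation to build records with these jATP values
  recs <- lapply(seq_along(I), function(i) {
    dF <- noisy[i] * (1 - p$x) / (p$s_prime * I[i])
    fluorescence_record(I[i], Fs = 1 - dF, Fm_prime = 1)
  })
  fit <- fit_jmax(recs, abs_M, abs_BS, p)
  expect_equal(fit$jmax_M, jmax_M_true, tolerance = 0.05)
  expect_equal(fit$jmax_BS, jmax_BS_true, tolerance = 0.05)
  # degenerate designs are rejected
  expect_error(fit_jmax(recs[1:3], abs_M, abs_BS, p), "at least 4")
  same <- lapply(1:5, function(i) fluorescence_record(800, 0.5, 1))
  expect_error(fit_jmax(same, abs_M, abs_BS, p), "ill-posed")
})

test_that("ATP allocation splits by x and densities integrate back", {
  p <- energetics_params()  # x = 0.40
  al <- allocate_atp(100, p)
  expect_equal(al$jATP_C3, 60)
  expect_equal(al$jATP_C4, 40)
  al2 <- allocate_atp(100, p, d = 165e-6, f_bs_chloroplast = 0.0909,
                      f_m_cytosol = 0.05)
  expect_equal(al2$j_star_ATP_C3 * 165e-6 * 0.0909, 60, tolerance = 1e-12)
  expect_equal(al2$j_star_ATP_C4 * 165e-6 * 0.05, 40, tolerance = 1e-12)
  p1 <- energetics_params(x = 1)
  expect_equal(allocate_atp(100, p1)$jATP_C3, 0)
})

test_that("leaf ATP light response saturates and is non-decreasing", {
  I <- seq(10, 3000, by = 10)
  mod <- atp_light_response(I, 0.55, 0.28)
  expect_true(all(diff(mod$jATP) > -1e-9))
  p <- energetics_params()
  ceiling_atp <- atp_multiplier(cet_fraction(p$u_M, p), p) * p$jmax_M +
    atp_multiplier(cet_fraction(p$u_BS, p), p) * p$jmax_BS
  expect_true(all(mod$jATP <= ceiling_atp + 1e-9))
  expect_gt(utils::tail(mod$jATP, 1), 0.9 * ceiling_atp)
})
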