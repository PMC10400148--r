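test_that("Rubisco rate: half-saturation, ATP cap, and the worked value", {
  # half-saturation: dissolved CO2 equivalent to K_mC, no O2, ATP abundant
  C_half <- ppm_to_liquid(485)
  expect_equal(rubisco_rate(C_half, 0, 100, 1e9), 50, tolerance = 1e-9)
  # ATP-limited branch at saturating CO2 approaches jATP_C3/3
  expect_equal(rubisco_rate(ppm_to_liquid(1e7), 0, 1e12, 90), 30,
               tolerance = 1e-3)
  # area-based analog of the kinetics at 1900 ubar CO2 / 210 mbar O2
  k <- physical_constants()
  got <- rubisco_rate(ppm_to_liquid(1900), ppm_to_liquid(210e3, k$henry_o2),
                      78.5, 1e9)
  expect_equal(got, 78.5 * 1900 / (1900 + 485 * (1 + 210 / 146)),
               tolerance = 1e-6)
  expect_equal(got, 48.4, tolerance = 1e-3)
  expect_error(rubisco_rate(-1, 0, 1, 1), "negative")
  # min rule: result never exceeds either branch
  set.seed(3)
  C <- runif(50, 1e-4, 0.2); O <- runif(50, 0, 0.5)
  r <- rubisco_rate(C, O, 5e6, 8e6)
  expect_true(all(r <= 5e6 + 1e-9))
  expect_true(all(r >= 0))
})

test_that("PEPC rate: half-saturation and the ATP-limited branch", {
  expect_equal(pepc_rate(2e-2, 100, 1e9), 50)
  expect_equal(pepc_rate(0.5, 100, 0), 0)
  expect_equal(pepc_rate(1e9, 183, 80), 40)
  b <- seq(0, 1, by = 0.05)
  r <- pepc_rate(b, 183, 90)
  expect_true(all(diff(r) >= -1e-12))
})

test_that("CA hydration follows the reversible Michaelis-Menten form", {
  kp <- kinetic_params()
  H <- proton_concentration(7.5)
  # equilibrium: zero net rate
  C_eq <- 0.1 * H / kp$K_eq
  expect_equal(ca_hydration(C_eq, 0.1, H, kp), 0, tolerance = 1e-6)
  # first-order limit at low CO2, no bicarbonate
  C <- 1e-4
  expect_equal(ca_hydration(C, 0, H, kp), kp$V_CAmax * C / kp$K_CO2,
               tolerance = 1e-4)
  # independent transcription of the rate law
  C <- 0.0127; B <- 0.1
  ref <- kp$V_CAmax * (C - B * H / kp$K_eq) /
    (kp$K_CO2 + kp$K_CO2 / kp$K_HCO3 * B + C)
  expect_equal(ca_hydration(C, B, H, kp), ref, tolerance = 1e-12)
})

test_that("spontaneous hydration: worked value, equilibrium, and sign", {
  kp <- kinetic_params()
  H <- proton_concentration(7.5)
  # k1 * 0.0127 mol m-3 = 4.95e-4 mol m-3 s-1 (reported in umol m-3 s-1)
  expect_equal(spontaneous_hydration(0.0127, 0, H, kp), 4.953e-4 * 1e6,
               tolerance = 1e-3)
  # equilibrium ratio k1 K / (k2 H)
  B_eq <- kp$k1 * kp$K_a * 1e3 * 0.0127 / (kp$k2 * H)
  expect_equal(spontaneous_hydration(0.0127, B_eq, H, kp), 0,
               tolerance = 1e-9)
  expect_lt(spontaneous_hydration(0, 0.1, H, kp), 0)
})

test_that("respiration integrates exactly to R_d over the respiring volume", {
  st <- anatomical_stats(small_volume())
  resp <- respiration_rates(1.70, st)
  # R* d f_resp = R_d by construction
  expect_equal(resp$R_star * st$d * st$f_resp, 1.70, tolerance = 1e-12)
  expect_equal(sum(resp$per_class), 1.70, tolerance = 1e-12)
  expect_equal(respiration_rates(0, st)$R_star, 0)
  # per-class rates are proportional to class volume
  fr <- st$volume_fraction
  expect_equal(resp$per_class[["M_CYTOSOL"]] / resp$per_class[["EPIDERMIS"]],
               fr[["M_CYTOSOL"]] / fr[["EPIDERMIS"]], tolerance = 1e-9)
})

test_that("photorespiration rates keep the 3:1 O2:CO2 stoichiometry", {
  n <- 40
  Vc <- rep(10, n); O <- rep(0.3, n); C <- rep(0.05, n)
  gs <- 0.5 / 2862
  pr <- photorespiration_rates(Vc, O, C, gs, 1e-18, 2e-17, 5e-17)
  expect_equal(pr$r_o2 * 5e-17 / (pr$r_co2 * 2e-17), 3, tolerance = 1e-12)
  # hand integration for uniform fields; the O/C ratio is taken on the
  # gas-equivalent scale (Henry 0.032 for O2, 0.83 for CO2)
  ratio_gas <- (0.3 / 0.032) / (0.05 / 0.83)
  expect_equal(pr$r_co2, n * 10 * gs * ratio_gas * 1e-18 / 2e-17,
               tolerance = 1e-9)
  z <- photorespiration_rates(Vc, rep(0, n), C, gs, 1e-18, 2e-17, 5e-17)
  expect_equal(z$r_co2, 0)
  expect_equal(z$r_o2, 0)
})

test_that("decarboxylation conserves the whole-leaf PEP carboxylation flux", {
  Vp <- runif(100, 0, 20)
  vbar <- decarboxylation_source(Vp, 1e-18, 5e-17)
  expect_equal(vbar * 5e-17, sum(Vp) * 1e-18, tolerance = 1e-12)
  expect_equal(decarboxylation_source(rep(0, 10), 1e-18, 5e-17), 0)
  # uniform Vp = 10 with V_Mcy / V_BSch = 2 doubles the density
  expect_equal(decarboxylation_source(rep(10, 20), 1e-18, 1e-17), 20)
})

test_that("area-volume scaling and its round trip", {
  q <- volumetric_scaling(78.5, 165e-6, 15e-6 / 165e-6)
  expect_equal(q, 78.5 / 15e-6, tolerance = 1e-9)  # ~5.23e6 umol m-3 s-1
  expect_equal(q, 5.23e6, tolerance = 1e-2)
  expect_equal(volumetric_scaling(42, 1, 1), 42)
  expect_equal(volumetric_scaling(3.3, 200e-6, 0.1) * 200e-6 * 0.1, 3.3)
})

test_that("oxygen evolution is a quarter of linear electron transport", {
  expect_equal(oxygen_evolution(100), 25)
  expect_equal(oxygen_evolution(rep(0, 5)), rep(0, 5))
  j <- runif(10, 0, 1e6)
  expect_equal(sum(oxygen_evolution(j)), sum(j) / 4)
})
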