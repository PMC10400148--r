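test_that("gas-liquid conversions round-trip and match the hand value", {
  # 1 ubar of CO2 dissolves to 3.35e-5 mol m-3 at 25 C with H = 0.83
  expect_equal(ppm_to_liquid(1), 3.35e-5, tolerance = 1e-3)
  x <- c(0.1, 380, 1584, 1e4)
  expect_equal(liquid_to_ppm(ppm_to_liquid(x)), x, tolerance = 1e-12)
  expect_equal(ppm_to_liquid(380), 0.0127, tolerance = 1e-2)
  # O2: 210 mmol/mol in air-saturated water is about 0.27 mol m-3
  k <- physical_constants()
  expect_equal(ppm_to_liquid(210e3, k$henry_o2), 0.27, tolerance = 0.01)
})
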