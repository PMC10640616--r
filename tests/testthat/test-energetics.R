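test_that("incident fluence converts mW/mm2 and seconds to J/cm2", {
  expect_equal(incident_fluence(12.5, 0.2), 0.25)
  expect_equal(incident_fluence(10, 0.1), 0.1)
  expect_equal(incident_fluence(10, 0.4), 2 * incident_fluence(10, 0.2))
})

test_that("optical model reproduces the worked absorbed-energy estimate", {
  p <- optical_energy_params(power_density = 12.5, pulse_width = 0.2,
                             cross_section = 2e-15,
                             molecules_per_cell = 1e5,
                             cell_footprint = 1e-5)
  expect_equal(optical_absorbed_energy(p), 5.0e-6, tolerance = 1e-12)
  # no molecules, no absorption
  p0 <- p; p0$molecules_per_cell <- 0
  expect_equal(optical_absorbed_energy(p0), 0)
  # halving the footprint doubles the areal absorption
  ph <- p; ph$cell_footprint <- p$cell_footprint / 2
  expect_equal(optical_absorbed_energy(ph), 2 * optical_absorbed_energy(p))
  # optically thick input is refused
  pt <- p; pt$molecules_per_cell <- 1e9
  expect_error(optical_absorbed_energy(pt), "thick")
})

test_that("electrical model reproduces the worked Joule estimate", {
  p <- electrical_energy_params(voltage = 3)
  # (3 / 7e-3)^2 / 0.58 * 0.02 * 1e-5 / 1e4
  expect_equal(electrical_dissipated_energy(p), 6.33357e-6,
               tolerance = 1e-5)
  p0 <- electrical_energy_params(voltage = 0)
  expect_equal(electrical_dissipated_energy(p0), 0)
  # quadratic in V
  p4 <- electrical_energy_params(voltage = 12)
  expect_equal(electrical_dissipated_energy(p4),
               16 * electrical_dissipated_energy(p))
})

test_that("energy models obey their scaling laws to 1e-12", {
  po <- optical_energy_params(12.5)
  pe <- electrical_energy_params(3)
  scale_check <- function(base, field, factor, expected_ratio, fun) {
    p2 <- base; p2[[field]] <- base[[field]] * factor
    abs(fun(p2) / fun(base) - expected_ratio)
  }
  expect_lt(scale_check(po, "pulse_width", 3, 3, optical_absorbed_energy),
            1e-12)
  expect_lt(scale_check(po, "molecules_per_cell", 0.5, 0.5,
                        optical_absorbed_energy), 1e-12)
  expect_lt(scale_check(pe, "pulse_width", 5, 5,
                        electrical_dissipated_energy), 1e-12)
  expect_lt(scale_check(pe, "voltage", 2, 4,
                        electrical_dissipated_energy), 1e-12)
  expect_lt(scale_check(pe, "layer_height", 2, 2,
                        electrical_dissipated_energy), 1e-12)
  expect_lt(scale_check(pe, "resistivity", 2, 0.5,
                        electrical_dissipated_energy), 1e-12)
})

test_that("SI and mixed-unit routes agree to 1e-12 relative", {
  p <- optical_energy_params(12.5, pulse_width = 0.2)
  # direct SI: W/m2 * s * (sigma N / A, dimensionless) -> J/m2 -> J/cm2
  si <- (12.5 * 1e3) * 0.2 * (2e-15 * 1e5 / 1e-5) / 1e4
  expect_equal(optical_absorbed_energy(p), si, tolerance = 1e-12)
})

test_that("with the documented closure the two modalities are comparable", {
  eo <- optical_absorbed_energy(optical_energy_params(12.5))
  ee <- electrical_dissipated_energy(electrical_energy_params(3))
  expect_lt(max(eo / ee, ee / eo), 2)
})

test_that("solution depletion yields molecules per cell", {
  expect_equal(molecules_from_depletion(1e-9, 1e-9, 1e-3, 1e6), 0)
  # 1e-10 mol/L depleted in 1 mL over 6.022e7 cells: ~1e3 molecules/cell
  expect_equal(molecules_from_depletion(2e-10, 1e-10, 1e-3, 6.02214076e7),
               1e3, tolerance = 1e-9)
  expect_equal(molecules_from_depletion(2e-10, 1e-10, 1e-3, 2 * 6.02214076e7),
               5e2, tolerance = 1e-9)
  expect_error(molecules_from_depletion(1e-10, 2e-10, 1e-3, 1e6),
               "exceeds")
})
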