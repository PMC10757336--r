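test_that("layered oracle reproduces the validation-cell field", {
  lay <- list(list(thickness = 175e-6, material = "PET"),
              list(thickness = 10e-3, material = "medium"),
              list(thickness = 175e-6, material = "PET"))
  o <- layered_1d_oracle(lay, 5, 60e3)
  expect_equal(signif(o$E_mag[2], 3), 0.0954)
  expect_equal(Mod(o$J), 0.1431, tolerance = 1e-3)
  expect_equal(Mod(o$Z_total), 34.95, tolerance = 1e-3)
  # single medium layer at DC: resistive divider E = V/d
  od <- layered_1d_oracle(list(list(thickness = 2e-3, material = "medium")), 3, 0)
  expect_equal(Mod(od$E[1]), 3 / 2e-3)
  # widening the medium gap to 22 mm leaves the field unchanged to 3 s.f.
  lay22 <- lay
  lay22[[2]]$thickness <- 22e-3
  o22 <- layered_1d_oracle(lay22, 5, 60e3)
  expect_equal(signif(o22$E_mag[2], 3), signif(o$E_mag[2], 3))
  # zero-thickness layer dropped with a warning
  expect_warning(layered_1d_oracle(c(lay, list(list(thickness = 0, material = "PET"))),
                                   5, 60e3), "zero-thickness")
})

test_that("3D solve of the validation cell matches the 1D oracle", {
  g <- build_validation_cell(gap = 10e-3, resolution = 1e-3)
  sol <- solve_em(g, em_bc(5, 60e3))
  o <- layered_1d_oracle(list(list(thickness = 175e-6, material = "PET"),
                              list(thickness = 10e-3, material = "medium"),
                              list(thickness = 175e-6, material = "PET")),
                         5, 60e3)
  med <- label_mask(g, "medium")
  E_med <- sol$E_mag[med]
  expect_equal(mean(E_med), o$E_mag[2], tolerance = 0.05)
  # uniform within 5% across the central 80% of the gap
  nx <- g$shape[1]
  core <- seq(ceiling(nx * 0.2), floor(nx * 0.8))
  Ecore <- sol$E_mag[core, , ]
  Ecore <- Ecore[!is.na(Ecore)]
  expect_lt((max(Ecore) - min(Ecore)) / mean(Ecore), 0.05)
  # terminal currents equal in magnitude
  expect_equal(Mod(sol$I_active), Mod(sol$I_ground), tolerance = 1e-6)
})

test_that("resolved thin-film solve agrees with the oracle and the lumped mode", {
  # quasi-1D column: small plates, film resolved with 10 cells
  asm <- electrode_assembly(plate_size = c(1.4e-3, 1.4e-3), pet_thickness = 175e-6)
  g <- build_validation_cell(gap = 3.5e-3, resolution = 17.5e-6,
                             pet_mode = "resolved", assembly = asm)
  sol <- solve_em(g, em_bc(5, 60e3), exclude_rel = 0, tol = 1e-10,
                  maxit = 200000L)
  o <- layered_1d_oracle(list(list(thickness = 175e-6, material = "PET"),
                              list(thickness = 3.5e-3, material = "medium"),
                              list(thickness = 175e-6, material = "PET")),
                         5, 60e3)
  med <- label_mask(g, "medium")
  expect_equal(mean(sol$E_mag[med]), o$E_mag[2], tolerance = 0.05)
  g2 <- build_validation_cell(gap = 3.5e-3, resolution = 17.5e-6,
                              pet_mode = "lumped", assembly = asm)
  sol2 <- solve_em(g2, em_bc(5, 60e3))
  med2 <- label_mask(g2, "medium")
  expect_equal(mean(sol2$E_mag[med2]), mean(sol$E_mag[med]), tolerance = 0.05)
})

test_that("DC resistive limit reproduces the plate capacitor", {
  # bare plates spanning the whole cross-section (fringing suppressed),
  # uniform medium: E = V/d and I = sigma V A / d
  asm <- electrode_assembly(plate_size = c(5e-3, 5e-3), pet_thickness = 0)
  d <- 4e-3
  g <- build_validation_cell(gap = d, resolution = 0.25e-3, assembly = asm)
  sol <- solve_em(g, em_bc(V_amp = 2, f = 0))
  med <- label_mask(g, "medium")
  expect_equal(mean(Mod(sol$E$x[med])), 2 / d, tolerance = 0.02)
  A <- 5e-3 * 5e-3
  expect_equal(Mod(sol$I_active), 1.5 * 2 * A / d, tolerance = 0.02)
})

test_that("solver is linear in the drive and conserves terminal current", {
  g <- build_validation_cell(gap = 5e-3, resolution = 1e-3)
  s1 <- solve_em(g, em_bc(5, 60e3), tol = 1e-10)
  s2 <- solve_em(g, em_bc(10, 60e3), tol = 1e-10)
  med <- label_mask(g, "medium")
  expect_equal(s2$E_mag[med], 2 * s1$E_mag[med], tolerance = 1e-6)
  expect_equal(Mod(s2$I_active), 2 * Mod(s1$I_active), tolerance = 1e-6)
  expect_equal(Mod(s1$I_active), Mod(s1$I_ground), tolerance = 1e-6)
  # zero drive: zero field and current
  s0 <- solve_em(g, em_bc(0, 60e3))
  expect_equal(max(s0$E_mag[med]), 0, tolerance = 1e-12)
  expect_equal(Mod(s0$I_active), 0, tolerance = 1e-12)
  # protocol rescaling equals the fresh solve at the doubled drive
  s1r <- rescale_protocol(s1, 2)
  expect_lt(max(abs(s1r$E_mag[med] - s2$E_mag[med])) / max(s2$E_mag[med]), 1e-6)
  expect_equal(Mod(s1r$I_active), Mod(s2$I_active), tolerance = 1e-6)
})

test_that("degenerate electrode geometries are refused", {
  g <- build_validation_cell(gap = 5e-3, resolution = 1e-3)
  # drop the ground plate entirely
  lab <- g$label_table
  codes <- g$labels
  codes[codes == match("ITO_ground", lab)] <- match("medium", lab)
  g2 <- voxel_grid(codes, g$spacing, g$origin, lab)
  attr(g2, "electrodes") <- attr(g, "electrodes")
  expect_error(solve_em(g2, em_bc(5, 60e3)), "electrode")
})

test_that("series-resistor correction matches the bench arithmetic", {
  sr <- apply_series_resistor(5, 3.21e-5, 21.89e3)
  expect_equal(sr$I, 31.8e-6, tolerance = 0.1e-6 / 31.8e-6)
  expect_equal(signif(0.095 * sr$scale, 2), 0.094)
  # R_s = 0 is the identity
  expect_equal(apply_series_resistor(5, 3.21e-5, 0)$I, 3.21e-5)
  expect_error(apply_series_resistor(5, 3.21e-5, -1), ">= 0")
  expect_error(apply_series_resistor(5, 0, 100), "I_base")
})

test_that("current-to-field back-calculation is a linear rescaling", {
  expect_equal(signif(field_from_measured_current(0.095, 3.21e-5, 2.43e-5), 2),
               0.072)
  expect_identical(field_from_measured_current(0.095, 3.21e-5, 3.21e-5), 0.095)
  e1 <- field_from_measured_current(0.095, 3.21e-5, 2e-5)
  e2 <- field_from_measured_current(0.095, 3.21e-5, 1e-5)
  expect_equal(e1, 2 * e2)
  expect_error(field_from_measured_current(0.1, 0, 1e-5), "I_pred")
})
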