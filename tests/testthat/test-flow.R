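test_that("planar channel reproduces the Poiseuille profile and wall shear", {
  ch <- planar_channel(ncells_h = 48, U = 1e-3, H = 1e-3)
  sol <- solve_flow(ch$grid, ch$bc, tol = 1e-9)
  sol <- shear_stress(sol)
  mid <- dim(sol$vel$x)[1] %/% 2
  prof <- sol$vel$x[mid, , 2]
  # parabolic: max / mean = 1.5
  expect_equal(max(prof) / mean(prof), 1.5, tolerance = 0.01)
  # mass conservation: slice mean equals the imposed outflow velocity
  expect_equal(mean(prof), ch$U, tolerance = 1e-6)
  # wall shear tau = 6 mu U / h
  mu <- 6.89e-4
  tau_wall <- 6 * mu * ch$U / ch$H
  expect_equal(sol$tau[mid, 1, 2], tau_wall, tolerance = 0.03)
  expect_equal(sol$tau[mid, 48, 2], tau_wall, tolerance = 0.03)
  # with the published viscosity and U = 1 mm/s, h = 1 mm: 4.134e-3 Pa
  expect_equal(tau_wall, 4.134e-3, tolerance = 1e-4)
})

test_that("voxelized circular duct develops max/mean = 2", {
  d <- circular_duct(ncells_d = 30)
  sol <- solve_flow(d$grid, d$bc, tol = 1e-8)
  mid <- dim(sol$vel$x)[1] %/% 2
  sl <- sol$vel$x[mid, , ]
  fm <- sol$fluid_mask[mid, , ]
  expect_equal(max(sl[fm]) / mean(sl[fm]), 2.0, tolerance = 0.02)
})

test_that("zero driving produces an identically zero field", {
  ch <- planar_channel(ncells_h = 16, aspect = 2, U = 0)
  sol <- solve_flow(ch$grid, ch$bc)
  expect_equal(max(abs(sol$u$x)), 0)
  expect_equal(max(abs(sol$u$y)), 0)
  expect_equal(max(abs(sol$u$z)), 0)
})

test_that("Stokes flow is linear in the imposed flow rate", {
  d <- circular_duct(ncells_d = 14, length_cells = 30)
  s1 <- solve_flow(d$grid, d$bc, tol = 1e-10)
  bc2 <- d$bc
  bc2$values["xmax"] <- 2 * d$U
  s2 <- solve_flow(d$grid, bc2, tol = 1e-10)
  fm <- s1$fluid_mask
  scale <- max(abs(s1$speed[fm]))
  expect_lt(max(abs(s2$speed[fm] - 2 * s1$speed[fm])) / (2 * scale), 1e-6)
  # shear stress scales linearly too
  s1 <- shear_stress(s1)
  s2 <- shear_stress(s2)
  expect_lt(max(abs(s2$tau[fm] - 2 * s1$tau[fm])) / max(s1$tau[fm]), 1e-6)
})

test_that("interior divergence vanishes to solver tolerance", {
  d <- circular_duct(ncells_d = 14, length_cells = 30)
  sol <- solve_flow(d$grid, d$bc, tol = 1e-9)
  # normalize against the outlet velocity scale U / h
  expect_lt(flow_divergence(sol) / (d$U / d$h), 1e-6)
})

test_that("global mass balance closes across all boundaries", {
  d <- circular_duct(ncells_d = 14, length_cells = 30)
  sol <- solve_flow(d$grid, d$bc, tol = 1e-9)
  # net flux = sum of divergence * cell volume over fluid cells
  n <- sol$grid$shape
  h <- sol$grid$spacing
  div <- (sol$u$x[2:(n[1] + 1), , ] - sol$u$x[1:n[1], , ] +
          sol$u$y[, 2:(n[2] + 1), ] - sol$u$y[, 1:n[2], ] +
          sol$u$z[, , 2:(n[3] + 1)] - sol$u$z[, , 1:n[3]]) / h
  net <- sum(div[sol$fluid_mask]) * h^3
  outlet_flux <- d$U * sum(sol$fluid_mask[n[1], , ]) * h^2
  expect_lt(abs(net) / outlet_flux, 1e-6)
})

test_that("uniform translation has zero shear stress", {
  # constructed solution: uniform u in a wall-free periodic-like box
  ch <- planar_channel(ncells_h = 8, aspect = 2)
  sol <- solve_flow(ch$grid, flow_bc(
    sides = list(xmin = "pressure", xmax = "velocity", ymin = "slip",
                 ymax = "slip", zmin = "slip", zmax = "slip"),
    velocity_sides = list(xmax = 1e-3), open_label0 = FALSE))
  expect_equal(max(sol$speed), 1e-3, tolerance = 1e-8)
  sol <- shear_stress(sol)
  expect_lt(max(sol$tau, na.rm = TRUE), 1e-3 * 6.89e-4 / 1e-3 * 1e-6)
})

test_that("grid refinement changes duct wall shear by less than 5%", {
  tau_mean <- vapply(c(12, 24), function(nc) {
    d <- circular_duct(ncells_d = nc, length_cells = 2 * nc)
    sol <- shear_stress(solve_flow(d$grid, d$bc, tol = 1e-8))
    mid <- dim(sol$tau)[1] %/% 2
    sl <- sol$tau[mid, , ]
    mean(sl[sol$fluid_mask[mid, , ]])
  }, numeric(1))
  expect_lt(abs(tau_mean[2] - tau_mean[1]) / tau_mean[2], 0.05)
})

test_that("Reynolds diagnostic follows rho u L / mu", {
  ch <- planar_channel(ncells_h = 16, aspect = 2, U = 1e-3)
  sol <- solve_flow(ch$grid, ch$bc)
  re <- reynolds(sol, L_char = 500e-6)
  # mid-channel speed 1.5 U: Re = 994 * 1.5e-3 * 5e-4 / 6.89e-4
  expect_equal(re$max, 994 * max(sol$speed, na.rm = TRUE) * 5e-4 / 6.89e-4,
               tolerance = 1e-10)
  re2 <- reynolds(sol, L_char = 1e-3)
  expect_equal(re2$max, 2 * re$max)
  expect_equal(reynolds(sol, L_char = 5e-4)$field[8, 8, 2],
               994 * sol$speed[8, 8, 2] * 5e-4 / 6.89e-4)
})

test_that("disconnected fluid regions are refused or frozen", {
  lab <- array("medium", dim = c(12, 8, 3))
  lab[6, , ] <- "PCL"   # wall splitting the duct in two
  g <- voxel_grid(lab, 1e-4)
  bc <- flow_bc(sides = list(xmin = "pressure", xmax = "velocity",
                             ymin = "wall", ymax = "wall",
                             zmin = "slip", zmax = "slip"),
                velocity_sides = list(xmax = 1e-3), open_label0 = FALSE)
  expect_warning(solve_flow(g, bc), "isolated fluid cells frozen")
})
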