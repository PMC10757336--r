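test_that("ROI extraction recovers the scaffold envelope box", {
  sp <- scaffold_spec("orthogonal")
  asm <- assemble_chamber(sp, "horizontal", spacing = 400e-6)
  roi <- extract_roi(asm)
  ext <- roi$box$hi - roi$box$lo
  expect_equal(ext, c(10.0, 10.0, 2.75) * 1e-3, tolerance = asm$spacing / 2.75e-3)
  hc <- scaffold_spec("honeycomb")
  asmh <- assemble_chamber(hc, "horizontal", spacing = 400e-6)
  roih <- extract_roi(asmh)
  expect_equal(roih$box$hi - roih$box$lo, c(10.2, 10.2, 3.0) * 1e-3,
               tolerance = asmh$spacing / 3e-3)
  expect_gt(roi$n_fluid, 0)
  expect_gt(roi$n_solid, 0)
  # scaffold-only grid: ROI is the whole grid
  g <- generate_scaffold(sp, 100e-6)
  roig <- extract_roi(g)
  expect_equal(sum(roig$mask), prod(g$shape))
  # scaffold absent -> error
  empty <- voxel_grid(array("medium", dim = c(5, 5, 5)), 1e-4)
  expect_error(extract_roi(empty, scaffold_spec("orthogonal")), "absent")
})

test_that("histogram of a uniform field is a single peak at the value", {
  g <- voxel_grid(array("medium", dim = c(6, 6, 6)), 1e-4)
  f <- array(0.01, dim = g$shape)
  hist <- roi_histogram(f, array(TRUE, dim = g$shape), g,
                        bins = seq(0, 0.02, by = 0.001))
  expect_equal(sum(hist$normalized == 1), 1L)
  expect_equal(hist$mean, 0.01)
  expect_equal(sum(hist$volume), 216 * (1e-4)^3)
})

test_that("histogram of a linear ramp is uniform across covered bins", {
  n <- c(50, 4, 4)
  g <- voxel_grid(array("medium", dim = n), 1e-4)
  ramp <- array(rep((seq_len(50) - 0.5) / 50, times = 16), dim = n)
  hist <- roi_histogram(ramp, array(TRUE, dim = n), g,
                        bins = seq(0, 1, by = 0.1))
  expect_lt(diff(range(hist$volume)) / mean(hist$volume), 1 / 5 + 1e-9)
  expect_equal(hist$mean, mean(ramp))
})

test_that("histogram mean equals an independent volume-weighted summation", {
  set.seed(11)
  n <- c(10, 10, 10)
  lab <- array(sample(c("medium", "PCL"), prod(n), replace = TRUE), dim = n)
  g <- voxel_grid(lab, 2e-4)
  f <- array(runif(prod(n)), dim = n)
  mask <- array(FALSE, dim = n)
  mask[3:8, 3:8, 3:8] <- TRUE
  hist <- roi_histogram(f, mask, g)
  med <- array(g$labels == match("medium", g$label_table), dim = n)
  inc <- mask & med
  # independent summation oracle
  expect_equal(hist$mean, sum(f[inc] * 1) / sum(inc))
  expect_equal(hist$roi_volume, sum(inc) * (2e-4)^3)
  # mass conservation: total histogram volume = ROI fluid volume
  expect_equal(sum(hist$volume), hist$roi_volume)
})

test_that("window scoring returns in-window fractions and pass/fail", {
  g <- voxel_grid(array("medium", dim = c(6, 6, 6)), 1e-4)
  target <- microenv_target(required_fraction = 0.5)
  uni <- array(0.01, dim = g$shape)
  attr(uni, "units") <- "Pa"
  h1 <- roi_histogram(uni, array(TRUE, dim = g$shape), g)
  sc <- score_against_target(h1, target)
  expect_equal(sc$fraction[1], 1.0)   # 0.01 Pa inside 1.47e-3..2.4e-2
  expect_true(sc$pass[1])
  hot <- array(0.5, dim = g$shape)
  attr(hot, "units") <- "Pa"
  sc2 <- score_against_target(roi_histogram(hot, array(TRUE, dim = g$shape), g),
                              target)
  expect_equal(sc2$fraction, c(0, 0))
  expect_false(any(sc2$pass))
  # bimodal half in / half out
  bi <- array(rep(c(0.01, 0.5), length.out = prod(g$shape)), dim = g$shape)
  attr(bi, "units") <- "Pa"
  sc3 <- score_against_target(roi_histogram(bi, array(TRUE, dim = g$shape), g),
                              target)
  expect_equal(sc3$fraction[1], 0.5, tolerance = 1 / 216)
  # unit mismatch is refused
  expect_error(score_against_target(h1, target, what = "field"), "mismatch")
})

test_that("protocol rescaling equals a fresh solve at the scaled drive", {
  ch <- planar_channel(ncells_h = 16, aspect = 2, U = 1e-3)
  s1 <- shear_stress(solve_flow(ch$grid, ch$bc, tol = 1e-10))
  bc2 <- ch$bc
  bc2$values["xmax"] <- 0.01 * ch$U
  s2 <- shear_stress(solve_flow(ch$grid, bc2, tol = 1e-10))
  s1s <- rescale_protocol(s1, 0.01)
  fm <- s1$fluid_mask
  expect_lt(max(abs(s1s$speed[fm] - s2$speed[fm])) / max(s2$speed[fm]), 1e-6)
  expect_lt(max(abs(s1s$tau[fm] - s2$tau[fm])) / max(s2$tau[fm]), 1e-6)
  # identity at factor 1
  expect_identical(rescale_protocol(s1, 1)$speed, s1$speed)
  expect_error(rescale_protocol(s1, -2), ">= 0")
})

test_that("window fractions commute with rescaling (change of variables)", {
  g <- voxel_grid(array("medium", dim = c(8, 8, 8)), 1e-4)
  set.seed(3)
  f <- array(runif(512, 0, 0.1), dim = g$shape)
  attr(f, "units") <- "Pa"
  hist <- roi_histogram(f, array(TRUE, dim = g$shape), g)
  q <- 0.2
  scaled <- rescale_protocol(hist, q)
  target <- microenv_target()
  frac_scaled <- score_against_target(scaled, target)$fraction
  # equal to the fraction of the *unscaled* values inside windows / q
  tgt2 <- microenv_target(shear_windows = lapply(microenv_target()$shear_windows,
                                                 function(w) w / q))
  frac_div <- score_against_target(hist, tgt2)$fraction
  expect_equal(frac_scaled, frac_div)
})

test_that("field-window scoring accepts V/m units", {
  g <- voxel_grid(array("medium", dim = c(5, 5, 5)), 1e-4)
  f <- array(0.1, dim = g$shape)
  attr(f, "units") <- "V/m"
  sc <- score_against_target(roi_histogram(f, array(TRUE, dim = g$shape), g),
                             microenv_target())
  expect_equal(sc$fraction, 1.0)
  expect_true(sc$pass)
})
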