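test_that("default scaffold specs carry the published dimensions", {
  o <- scaffold_spec("orthogonal")
  expect_equal(o$envelope, c(10.0, 10.0, 2.75) * 1e-3)
  expect_equal(o$filament, 500e-6)
  expect_equal(o$pore, 500e-6)
  expect_equal(o$superposition, 0.10)
  h <- scaffold_spec("honeycomb")
  expect_equal(h$envelope, c(10.2, 10.2, 3.0) * 1e-3)
  expect_equal(h$filament, 250e-6)
  expect_equal(h$pore, 300e-6)
})

test_that("woodpile solid fraction matches an independent Monte-Carlo oracle", {
  sp <- scaffold_spec("orthogonal")
  g <- generate_scaffold(sp, 31.25e-6)
  vox <- label_fraction(g, "PCL")
  mc <- woodpile_mc_fraction(sp, n = 3e5)
  expect_equal(vox, mc, tolerance = 0.02)
})

test_that("voxelization converges to the true solid fraction as h shrinks", {
  # reference: independent Monte-Carlo integration of the explicit
  # cylinder union (SE ~ 5e-4 at n = 1e6); halving the spacing shrinks
  # the voxelization error (an oscillatory O(h) term, so successive
  # *differences* are not monotone, but the error against the truth is)
  sp <- scaffold_spec("orthogonal")
  ref <- woodpile_mc_fraction(sp, n = 1e6)
  e1 <- abs(label_fraction(generate_scaffold(sp, 125e-6), "PCL") - ref)
  e2 <- abs(label_fraction(generate_scaffold(sp, 62.5e-6), "PCL") - ref)
  e3 <- abs(label_fraction(generate_scaffold(sp, 31.25e-6), "PCL") - ref)
  expect_lt(e2, e1)
  expect_lt(e3, e1)
  expect_lt(e3, 0.01)
})

test_that("degenerate lattices behave analytically", {
  # pore -> very large: one filament per layer, volume = cylinders / envelope
  sp <- scaffold_spec("orthogonal", envelope = c(4e-3, 4e-3, 0.5e-3),
                      filament = 500e-6, pore = 1, superposition = 0)
  g <- generate_scaffold(sp, 40e-6)
  vox <- label_fraction(g, "PCL")
  # single layer, one cylinder along y: pi r^2 L / (Lx Ly Lz)
  anal <- pi * (250e-6)^2 * 4e-3 / prod(sp$envelope)
  expect_equal(vox, anal, tolerance = 0.05)
  # honeycomb with zero truss: entirely medium
  hz <- scaffold_spec("honeycomb", filament = 0)
  gz <- generate_scaffold(hz, 100e-6)
  expect_equal(label_fraction(gz, "PCL"), 0)
})

test_that("too-coarse resolution is refused with the computed minimum", {
  sp <- scaffold_spec("orthogonal")
  err <- tryCatch(generate_scaffold(sp, 300e-6), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "pore/3")
})

test_that("labels partition the grid exhaustively and exclusively", {
  g <- generate_scaffold(scaffold_spec("honeycomb"), 100e-6)
  expect_true(all(g$labels %in% seq_along(g$label_table)))
  asm <- assemble_chamber(scaffold_spec("orthogonal"), "horizontal",
                          electrodes = electrode_assembly(gap = 22e-3),
                          spacing = 500e-6)
  expect_true(all(asm$labels %in% c(0L, seq_along(asm$label_table))))
})

test_that("default scaffold grids are mirror-symmetric about mid-planes", {
  g <- generate_scaffold(scaffold_spec("orthogonal"), 50e-6)
  lab <- g$labels
  expect_identical(lab, lab[rev(seq_len(dim(lab)[1])), , ])
  expect_identical(lab, lab[, rev(seq_len(dim(lab)[2])), ])
  gh <- generate_scaffold(scaffold_spec("honeycomb"), 75e-6)
  labh <- gh$labels
  expect_identical(labh, labh[rev(seq_len(dim(labh)[1])), , ])
  expect_identical(labh, labh[, , rev(seq_len(dim(labh)[3]))])
})

test_that("chamber assembly places electrodes at the prescribed separation", {
  asm <- assemble_chamber(scaffold_spec("orthogonal"), "horizontal",
                          electrodes = electrode_assembly(gap = 22e-3),
                          spacing = 400e-6)
  act <- which(label_mask(asm, "ITO_active"), arr.ind = TRUE)
  gnd <- which(label_mask(asm, "ITO_ground"), arr.ind = TRUE)
  ax <- grid_axes(asm)
  # inner faces of the two plates
  x_act_inner <- min(ax$x[act[, 1]]) - asm$spacing / 2
  x_gnd_inner <- max(ax$x[gnd[, 1]]) + asm$spacing / 2
  # within one voxel per plate of the nominal 22 mm
  expect_lt(abs((x_act_inner - x_gnd_inner) - 22e-3), 2 * asm$spacing + 1e-12)
})

test_that("holder kind does not change the scaffold volume", {
  # the scaffold is merely re-oriented between holders; its voxelized
  # volume must agree up to grid-alignment (discretization) differences
  sp <- scaffold_spec("orthogonal")
  a1 <- assemble_chamber(sp, "horizontal", spacing = 250e-6)
  a2 <- assemble_chamber(sp, "vertical", spacing = 250e-6)
  n1 <- sum(label_mask(a1, "PCL"))
  n2 <- sum(label_mask(a2, "PCL"))
  expect_equal(n1, n2, tolerance = 0.05)
})

test_that("chamber has exactly one outlet exit region at the bottom", {
  for (holder in c("horizontal", "vertical")) {
    asm <- assemble_chamber(scaffold_spec("orthogonal"), holder, spacing = 400e-6)
    op <- attr(asm, "outlet_patch")
    expect_identical(op$face, "zmin")
    med <- match("medium", asm$label_table)
    bottom <- asm$labels[, , 1] == med
    ax <- grid_axes(asm)
    inx <- ax$x > op$lo[1] & ax$x < op$hi[1]
    iny <- ax$y > op$lo[2] & ax$y < op$hi[2]
    # the exit patch is wet and is the only wet region under the holder
    expect_true(all(bottom[inx, iny]))
    # exit cross-section matches the calibrated area to within a voxel
    # ring (a large relative band at this coarse spacing)
    n_exit <- sum(inx) * sum(iny)
    a_exit <- n_exit * asm$spacing^2
    a_cal <- (50e-6 / 60 / 4) / 0.120
    w_cal <- sqrt(a_cal)
    expect_lte(a_exit, (w_cal + 2 * asm$spacing)^2)
    expect_gte(a_exit, (w_cal - 2 * asm$spacing)^2)
  }
})

test_that("electrode plates intersecting the scaffold are refused", {
  expect_error(
    assemble_chamber(scaffold_spec("orthogonal"), "vertical",
                     electrodes = electrode_assembly(gap = 2e-3),
                     spacing = 400e-6),
    "intersect")
})

test_that("validation cell reproduces the plate stack", {
  g <- build_validation_cell(gap = 10e-3, resolution = 0.5e-3)
  med <- label_mask(g, "medium")
  # medium slab thickness along x within one voxel
  runs <- apply(med, 1, any)
  expect_equal(sum(runs) * g$spacing, 10e-3, tolerance = g$spacing)
  g22 <- build_validation_cell(gap = 22e-3, resolution = 0.5e-3)
  expect_equal(sum(apply(label_mask(g22, "medium"), 1, any)) * g22$spacing,
               22e-3, tolerance = g22$spacing)
  # plates present and disjoint
  expect_gt(sum(label_mask(g, "ITO_active")), 0)
  expect_gt(sum(label_mask(g, "ITO_ground")), 0)
  meta <- attr(g, "electrodes")
  expect_equal(meta$pet_thickness, 175e-6)
  # bare-plate variant: zero PET thickness in the lumped metadata
  g0 <- build_validation_cell(gap = 10e-3, resolution = 0.5e-3,
                              assembly = electrode_assembly(pet_thickness = 0))
  expect_equal(attr(g0, "electrodes")$pet_thickness, 0)
})

test_that("synthetic dye recordings advance at the seeded velocity", {
  rec <- synthetic_dye_recording(2.36e-3, 7e-3, frame_rate = 30, noise_sd = 0)
  expect_equal(max(rec$time) - min(rec$time), 7e-3 / 2.36e-3, tolerance = 1e-9)
  expect_equal(max(rec$position) - min(rec$position), 7e-3, tolerance = 1e-12)
  # v = 0: constant position
  rec0 <- synthetic_dye_recording(0, 7e-3, frame_rate = 30, noise_sd = 0)
  expect_true(all(rec0$position == 0))
  # reproducible under a seed, without touching the global RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  r1 <- synthetic_dye_recording(1e-3, 5e-3, 20, noise_sd = 1e-4, seed = 7)
  r2 <- synthetic_dye_recording(1e-3, 5e-3, 20, noise_sd = 1e-4, seed = 7)
  expect_identical(r1, r2)
  after <- rnorm(1)
  expect_identical(before, after)
})
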