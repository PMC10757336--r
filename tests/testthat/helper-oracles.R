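# Independent geometric oracle for the woodpile lattice: explicit
# enumeration of every filament cylinder and a point-in-cylinder test,
# written separately from the generator's implicit function.
woodpile_point_solid <- function(x, y, z, envelope, d, pore, superposition) {
  r <- d / 2
  pz <- d * (1 - superposition)
  p <- d + pore
  n_layers <- floor((envelope[3] - d) / pz + 1e-9) + 1
  inside <- x >= 0 & x <= envelope[1] & y >= 0 & y <= envelope[2] &
    z >= 0 & z <= envelope[3]
  solid <- rep(FALSE, length(x))
  for (k in seq_len(n_layers) - 1) {
    zc <- r + k * pz
    if (k %% 2 == 0) {
      Lt <- envelope[2]
      nf <- floor((Lt - d) / p + 1e-9) + 1
      off <- (Lt - (nf - 1) * p) / 2
      for (m in seq_len(nf) - 1) {
        cc <- off + m * p
        solid <- solid | ((y - cc)^2 + (z - zc)^2 <= r^2)
      }
    } else {
      Lt <- envelope[1]
      nf <- floor((Lt - d) / p + 1e-9) + 1
      off <- (Lt - (nf - 1) * p) / 2
      for (m in seq_len(nf) - 1) {
        cc <- off + m * p
        solid <- solid | ((x - cc)^2 + (z - zc)^2 <= r^2)
      }
    }
  }
  solid & inside
}

# Monte-Carlo solid-fraction estimate over the envelope
woodpile_mc_fraction <- function(spec, n = 2e5, seed = 42) {
  set.seed(seed)
  L <- spec$envelope
  x <- runif(n, 0, L[1]); y <- runif(n, 0, L[2]); z <- runif(n, 0, L[3])
  mean(woodpile_point_solid(x, y, z, L, spec$filament, spec$pore,
                            spec$superposition))
}

# planar channel grid + BCs used by several flow tests
planar_channel <- function(ncells_h = 48, aspect = 3, U = 1e-3, H = 1e-3) {
  h <- H / ncells_h
  g <- voxel_grid(array("medium", dim = c(aspect * ncells_h, ncells_h, 3)), h)
  bc <- flow_bc(sides = list(xmin = "pressure", xmax = "velocity",
                             ymin = "wall", ymax = "wall",
                             zmin = "slip", zmax = "slip"),
                velocity_sides = list(xmax = U), open_label0 = FALSE)
  list(grid = g, bc = bc, U = U, H = H, h = h)
}

# circular duct along x, voxelized; solid jacket labeled PCL
circular_duct <- function(ncells_d = 30, length_cells = 90, U = 1e-3, D = 3e-3) {
  h <- D / ncells_d
  nt <- ncells_d + 4
  n <- c(length_cells, nt, nt)
  ax <- ((seq_len(nt)) - 0.5 - nt / 2) * h
  r2 <- outer(ax^2, ax^2, `+`)
  lab <- array("PCL", dim = n)
  disk <- r2 <= (D / 2)^2
  for (i in seq_len(n[1])) lab[i, , ][disk] <- "medium"
  g <- voxel_grid(lab, h)
  bc <- flow_bc(sides = list(xmin = "pressure", xmax = "velocity"),
                velocity_sides = list(xmax = U), default_side = "wall",
                open_label0 = FALSE)
  list(grid = g, bc = bc, U = U, D = D, h = h)
}
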