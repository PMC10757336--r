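#' Parametric scaffold specification
#'
#' Two lattice families are supported. `"orthogonal"`: a woodpile lattice of
#' parallel cylindrical filaments, rotated 90 degrees per layer, with
#' vertical pitch `filament * (1 - superposition)` and in-plane pitch
#' `filament + pore`. `"honeycomb"`: prismatic walls of thickness
#' `filament_or_truss` around hexagonal channels of across-flats width
#' `pore` running along the envelope's z axis (configurable via
#' `channel_axis`).
#'
#' Defaults reproduce the two candidate culture scaffolds: orthogonal
#' 10.0 x 10.0 x 2.75 mm with 500 um filament and pore and 10% filament
#' superposition; honeycomb 10.2 x 10.2 x 3.0 mm with 250 um truss and
#' 300 um macropore.
#'
#' @param kind `"orthogonal"` or `"honeycomb"`.
#' @param envelope Length-3 numeric, envelope (Lx, Ly, Lz) in metres.
#' @param filament Filament diameter (orthogonal) or truss/wall thickness
#'   (honeycomb), metres.
#' @param pore Pore size (orthogonal) or macropore across-flats width
#'   (honeycomb), metres.
#' @param superposition Orthogonal only: fractional overlap of successive
#'   layers, in [0, 0.5).
#' @param material Material label for the solid phase (default `"PCL"`;
#'   the honeycomb's carbonate apatite has no dedicated electrical property
#'   set, so it defaults to PCL as well).
#' @param channel_axis Honeycomb only: local axis of the prismatic
#'   channels, one of `"x"`, `"y"`, `"z"`.
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(kind = c("orthogonal", "honeycomb"),
                          envelope = NULL, filament = NULL, pore = NULL,
                          superposition = NULL, material = "PCL",
                          channel_axis = "z") {
  kind <- match.arg(kind)
  if (kind == "orthogonal") {
    if (is.null(envelope)) envelope <- c(10.0, 10.0, 2.75) * 1e-3
    if (is.null(filament)) filament <- 500e-6
    if (is.null(pore)) pore <- 500e-6
    if (is.null(superposition)) superposition <- 0.10
  } else {
    if (is.null(envelope)) envelope <- c(10.2, 10.2, 3.0) * 1e-3
    if (is.null(filament)) filament <- 250e-6
    if (is.null(pore)) pore <- 300e-6
    superposition <- 0
  }
  stopifnot(all(envelope > 0), filament >= 0, pore > 0,
            superposition >= 0, superposition < 0.5,
            channel_axis %in% c("x", "y", "z"))
  structure(
    list(kind = kind, envelope = as.numeric(envelope),
         filament = as.numeric(filament), pore = as.numeric(pore),
         superposition = as.numeric(superposition), material = material,
         channel_axis = channel_axis),
    class = "scaffold_spec"
  )
}

# Implicit solid indicator for the woodpile lattice, local coordinates with
# the envelope spanning [0, L] per axis. Vectorized over points.
.solid_orthogonal <- function(spec, x, y, z) {
  d <- spec$filament
  r <- d / 2
  pz <- d * (1 - spec$superposition)
  p <- d + spec$pore
  L <- spec$envelope
  n_layers <- max(1L, floor((L[3] - d) / pz + 1e-9) + 1L)
  inside <- x >= 0 & x <= L[1] & y >= 0 & y <= L[2] & z >= 0 & z <= L[3]
  solid <- rep(FALSE, length(x))
  k_lo <- pmax(0L, pmin(n_layers - 1L, as.integer(floor((z - r) / pz))))
  for (dk in 0:1) {
    k <- pmin(k_lo + dk, n_layers - 1L)
    zc <- r + k * pz
    dz <- z - zc
    # alternate filament direction per layer; transverse coordinate t
    even <- k %% 2L == 0L
    t <- ifelse(even, y, x)
    Lt <- ifelse(even, L[2], L[1])
    nf <- pmax(1L, as.integer(floor((Lt - d) / p + 1e-9)) + 1L)
    off <- (Lt - (nf - 1L) * p) / 2
    m <- pmin(pmax(round((t - off) / p), 0), nf - 1L)
    dt <- t - (off + m * p)
    solid <- solid | (dz * dz + dt * dt <= r * r)
  }
  solid & inside
}

# Hexagon "across-flats" distance from the origin (flats normal to the
# 0/60/120 degree axes).
.hex_dist <- function(dx, dy) {
  pmax(abs(dx), abs(dx / 2 + dy * sqrt(3) / 2), abs(dx / 2 - dy * sqrt(3) / 2))
}

# Implicit solid indicator for honeycomb walls, local coordinates in [0, L].
.solid_honeycomb <- function(spec, x, y, z) {
  a <- spec$pore          # channel across-flats width
  t <- spec$filament      # wall thickness
  L <- spec$envelope
  ax <- spec$channel_axis
  # permute so channels run along the local w axis, lattice in (u, v)
  if (ax == "z") { u <- x; v <- y; w <- z; Lu <- L[1]; Lv <- L[2]; Lw <- L[3] }
  else if (ax == "y") { u <- x; v <- z; w <- y; Lu <- L[1]; Lv <- L[3]; Lw <- L[2] }
  else { u <- y; v <- z; w <- x; Lu <- L[2]; Lv <- L[3]; Lw <- L[1] }
  inside <- x >= 0 & x <= L[1] & y >= 0 & y <= L[2] & z >= 0 & z <= L[3]
  if (t <= 0) return(rep(FALSE, length(x)))
  p <- a + t              # across-flats centre spacing of the channel lattice
  # lattice vectors (p, 0) and (p/2, p*sqrt(3)/2); one channel centred on the
  # envelope centre
  du <- u - Lu / 2
  dv <- v - Lv / 2
  jf <- dv / (p * sqrt(3) / 2)
  if_ <- du / p - jf / 2
  in_channel <- rep(FALSE, length(u))
  for (j0 in 0:1) {
    for (i0 in 0:1) {
      jc <- floor(jf) + j0
      ic <- floor(if_) + i0
      cu <- (ic + jc / 2) * p
      cv <- jc * p * sqrt(3) / 2
      in_channel <- in_channel | (.hex_dist(du - cu, dv - cv) <= a / 2)
    }
  }
  !in_channel & inside
}

# Dispatch on kind; points in local envelope coordinates [0, L].
.scaffold_solid <- function(spec, x, y, z) {
  if (spec$kind == "orthogonal") .solid_orthogonal(spec, x, y, z)
  else .solid_honeycomb(spec, x, y, z)
}

#' Voxelize a scaffold on a regular grid
#'
#' The grid covers the envelope (centred at the origin); each cell centre is
#' classified by the lattice's implicit solid function. The resolution must
#' place at least 3 cells across a pore so that pore channels stay
#' connected.
#'
#' @param spec A [scaffold_spec()].
#' @param resolution Cell edge (m); must be `<= pore / 3`.
#' @param medium Label for the fluid phase (default `"medium"`).
#' @return A [voxel_grid()] whose labels are `spec$material` or `medium`,
#'   with the spec attached as attribute `"scaffold_spec"`.
#' @export
generate_scaffold <- function(spec, resolution, medium = "medium") {
  stopifnot(inherits(spec, "scaffold_spec"), resolution > 0)
  if (resolution > spec$pore / 3 + 1e-12) {
    stop(sprintf(
      "resolution %g m too coarse for pore %g m; need <= %g m (pore/3)",
      resolution, spec$pore, spec$pore / 3), call. = FALSE)
  }
  L <- spec$envelope
  n <- pmax(1L, as.integer(round(L / resolution)))
  h <- resolution
  origin <- -n * h / 2
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(n[d]) - 0.5) * h)
  label_table <- c(medium, spec$material)
  codes <- array(1L, dim = n)
  # classify slab-wise in z to bound transient memory on fine grids
  nxy <- n[1] * n[2]
  xs <- rep(ax[[1]] + L[1] / 2, times = n[2])
  ys <- rep(ax[[2]] + L[2] / 2, each = n[1])
  slab <- max(1L, as.integer(2e6 %/% nxy))
  for (k0 in seq(1L, n[3], by = slab)) {
    ks <- k0:min(n[3], k0 + slab - 1L)
    zs <- rep(ax[[3]][ks] + L[3] / 2, each = nxy)
    solid <- .scaffold_solid(spec, rep(xs, length(ks)), rep(ys, length(ks)), zs)
    codes[, , ks][solid] <- 2L
  }
  g <- voxel_grid(codes, h, origin, label_table)
  attr(g, "scaffold_spec") <- spec
  g
}

#' Electrode assembly specification
#'
#' A pair of parallel coaxial ITO-on-PET plates. The ITO coating is the
#' conductor; the PET film (175 um) faces the medium and acts as the
#' capacitive dielectric barrier.
#'
#' @param gap Inner separation between the plates' medium-facing surfaces, m.
#' @param plate_size Length-2 plate extent in metres (default 33 x 18 mm).
#' @param pet_thickness PET film thickness, m (default 175 um).
#' @return An object of class `electrode_assembly`.
#' @export
electrode_assembly <- function(gap = 22e-3, plate_size = c(33e-3, 18e-3),
                               pet_thickness = 175e-6) {
  stopifnot(gap > 0, all(plate_size > 0), pet_thickness >= 0)
  structure(list(gap = gap, plate_size = as.numeric(plate_size),
                 pet_thickness = pet_thickness),
            class = "electrode_assembly")
}

# Paint a box primitive (global coords, lo/hi per axis) onto codes.
.paint_box <- function(codes, grid_origin, h, n, lo, hi, code, only_over = NULL) {
  idx <- lapply(1:3, function(d) {
    c0 <- grid_origin[d] + (seq_len(n[d]) - 0.5) * h
    which(c0 > lo[d] & c0 < hi[d])
  })
  if (any(lengths(idx) == 0L)) return(codes)
  sub <- codes[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (is.null(only_over)) sub[] <- code
  else sub[sub %in% only_over] <- code
  codes[idx[[1]], idx[[2]], idx[[3]]] <- sub
  codes
}

#' Assemble the culture-chamber model domain
#'
#' Builds the composite voxel model used by both solvers: a cylindrical
#' medium volume (radius 20 mm, height 30 mm, axis z), the scaffold centred
#' between the electrodes, a simplified printed holder, and (optionally)
#' the capacitive electrode pair facing each other along x.
#'
#' Holder simplification: the published holders are external CAD blueprints;
#' here they are reduced to parametric solids that keep the functional
#' differences. `"vertical"`: the scaffold stands upright (thin axis along
#' x, facing the electrodes) on a base block with a single vertical outlet
#' channel to the chamber bottom. `"horizontal"`: the scaffold lies flat
#' (thin axis along z) on a plenum box that collects flow through the
#' scaffold and routes it through two lateral channels merging into a
#' single exit channel at the chamber bottom. The exit channel cross-section
#' is identical for both holders.
#'
#' @param scaffold A scaffold grid from [generate_scaffold()] (its attached
#'   spec is re-evaluated implicitly at chamber resolution, with subcell
#'   supersampling in the scaffold envelope), or a [scaffold_spec()].
#' @param holder `"horizontal"` or `"vertical"`.
#' @param electrodes An [electrode_assembly()], or `NULL` for no electrodes.
#' @param spacing Chamber grid spacing (m).
#' @param chamber_radius,chamber_height Cylinder dimensions (m).
#' @param exit_area Outlet exit channel cross-section area (m^2). The
#'   default is calibrated so that one quarter of the 50 mL/min pump flow
#'   gives the 0.120 m/s holder-connector mean velocity.
#' @param supersample Odd integer; subcell sampling factor for scaffold
#'   voxel classification (majority vote). 1 disables.
#' @return A [voxel_grid()] with attributes `"roi_box"` (scaffold envelope,
#'   global lo/hi), `"outlet_patch"` (exit-channel box on the bottom
#'   face), `"electrodes"` (assembly metadata plus label names) and
#'   `"scaffold_spec"`.
#' @export
assemble_chamber <- function(scaffold, holder = c("horizontal", "vertical"),
                             electrodes = NULL, spacing = 200e-6,
                             chamber_radius = 20e-3, chamber_height = 30e-3,
                             exit_area = (50e-6 / 60 / 4) / 0.120,
                             supersample = 3L) {
  holder <- match.arg(holder)
  spec <- if (inherits(scaffold, "scaffold_spec")) scaffold
          else attr(scaffold, "scaffold_spec")
  if (is.null(spec)) stop("scaffold grid lacks a scaffold_spec attribute", call. = FALSE)
  h <- spacing
  R <- chamber_radius
  H <- chamber_height
  n <- as.integer(round(c(2 * R, 2 * R, H) / h))
  origin <- c(-R, -R, -H / 2)
  label_table <- c("medium", spec$material, "C8", "ITO_active", "ITO_ground")
  if (spec$material == "C8") label_table <- c("medium", "C8", "ITO_active", "ITO_ground")
  code_of <- function(lab) match(lab, label_table)
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(n[d]) - 0.5) * h)

  # 1. cylinder of medium, outside = 0
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  disk <- r2 <= R^2
  codes <- array(0L, dim = n)
  codes[rep(as.vector(disk), times = n[3])] <- code_of("medium")

  # scaffold placement: envelope centred at the origin
  L <- spec$envelope
  if (holder == "horizontal") {
    # local (x,y,z) -> global (x,y,z)
    ext <- L
    to_local <- function(x, y, z) list(x = x + L[1] / 2, y = y + L[2] / 2, z = z + L[3] / 2)
  } else {
    # upright: local z (thin axis) -> global x, local x -> global y, local y -> global z
    ext <- c(L[3], L[1], L[2])
    to_local <- function(x, y, z) list(x = y + L[1] / 2, y = z + L[2] / 2, z = x + L[3] / 2)
  }
  scaf_lo <- -ext / 2
  scaf_hi <- ext / 2

  # 2. holder solids and channels
  w_exit <- sqrt(exit_area)
  med <- code_of("medium")
  c8 <- code_of("C8")
  if (holder == "horizontal") {
    zb <- scaf_lo[3]                     # scaffold underside
    # plenum block from chamber bottom up to the scaffold underside;
    # the footprint leaves >= 0.5 mm of wall around every internal
    # channel so walls survive voxelization at chamber resolutions
    codes <- .paint_box(codes, origin, h, n, c(-7e-3, -7e-3, -H / 2),
                        c(7e-3, 7e-3, zb), c8, only_over = med)
    # upper cavity + top opening under the scaffold
    codes <- .paint_box(codes, origin, h, n, c(-5e-3, -5e-3, zb - 2e-3),
                        c(5e-3, 5e-3, zb - 0.8e-3), med, only_over = c8)
    codes <- .paint_box(codes, origin, h, n, c(-4.5e-3, -4.5e-3, zb - 0.9e-3),
                        c(4.5e-3, 4.5e-3, zb + h), med, only_over = c8)
    # two lateral channels (area rule: each half the exit area)
    w_lat <- sqrt(exit_area / 2)
    y_drop <- 5.8e-3
    zc <- zb - 1.4e-3
    for (s in c(-1, 1)) {
      codes <- .paint_box(codes, origin, h, n,
                          c(-w_lat / 2, min(s * 5e-3, s * y_drop) - w_lat / 2, zc - w_lat / 2),
                          c(w_lat / 2, max(s * 5e-3, s * y_drop) + w_lat / 2, zc + w_lat / 2),
                          med, only_over = c8)
      # vertical drop down to the collector
      codes <- .paint_box(codes, origin, h, n,
                          c(-w_lat / 2, s * y_drop - w_lat / 2, -H / 2 + 0.4e-3),
                          c(w_lat / 2, s * y_drop + w_lat / 2, zc + w_lat / 2),
                          med, only_over = c8)
    }
    # collector along y joining the two drops, then the single exit
    codes <- .paint_box(codes, origin, h, n,
                        c(-w_exit / 2, -y_drop - w_lat / 2, -H / 2 + 0.4e-3),
                        c(w_exit / 2, y_drop + w_lat / 2, -H / 2 + 0.4e-3 + w_exit),
                        med, only_over = c8)
    codes <- .paint_box(codes, origin, h, n,
                        c(-w_exit / 2, -w_exit / 2, -H / 2 - h),
                        c(w_exit / 2, w_exit / 2, -H / 2 + 0.5e-3 + w_exit),
                        med, only_over = c8)
  } else {
    zb <- scaf_lo[3]                     # scaffold bottom edge (global z)
    # base block with a holding slot
    codes <- .paint_box(codes, origin, h, n, c(-2.5e-3, -6.5e-3, -H / 2),
                        c(2.5e-3, 6.5e-3, zb + 0.4e-3), c8, only_over = med)
    codes <- .paint_box(codes, origin, h, n,
                        c(scaf_lo[1] - h, scaf_lo[2] - h, zb - h),
                        c(scaf_hi[1] + h, scaf_hi[2] + h, zb + 0.4e-3 + h),
                        med, only_over = c8)
    # single vertical outlet channel under the scaffold
    codes <- .paint_box(codes, origin, h, n,
                        c(-w_exit / 2, -w_exit / 2, -H / 2 - h),
                        c(w_exit / 2, w_exit / 2, zb), med, only_over = c8)
  }

  # 3. scaffold voxels (supersampled majority classification). When the
  # cells are coarser than the pore itself, majority voting cannot
  # resolve the lattice and only disconnects the minority phase (it can
  # even erase the scaffold entirely at resonant spacings); fall back to
  # centre-point classification, which preserves the connectivity of
  # prismatic channels.
  si <- lapply(1:3, function(d) which(ax[[d]] > scaf_lo[d] - h & ax[[d]] < scaf_hi[d] + h))
  if (any(lengths(si) == 0L)) stop("scaffold does not fit inside the chamber", call. = FALSE)
  s <- max(1L, as.integer(supersample))
  if (h > spec$pore) s <- 1L
  offs <- (seq_len(s) - (s + 1) / 2) / s * h
  xs <- ax[[1]][si[[1]]]; ys <- ax[[2]][si[[2]]]; zs <- ax[[3]][si[[3]]]
  nn <- c(length(xs), length(ys), length(zs))
  votes <- array(0L, dim = nn)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    px <- rep(xs + ox, times = nn[2] * nn[3])
    py <- rep(rep(ys + oy, each = nn[1]), times = nn[3])
    pz <- rep(zs + oz, each = nn[1] * nn[2])
    lc <- to_local(px, py, pz)
    votes <- votes + array(.scaffold_solid(spec, lc$x, lc$y, lc$z), dim = nn)
  }
  solid <- votes * 2L > s^3
  sub <- codes[si[[1]], si[[2]], si[[3]], drop = FALSE]
  sub[solid & sub == med] <- code_of(spec$material)
  codes[si[[1]], si[[2]], si[[3]]] <- sub

  # 4. electrode plates (ITO, PET lumped at the medium-facing surface)
  electrodes_meta <- NULL
  if (!is.null(electrodes)) {
    stopifnot(inherits(electrodes, "electrode_assembly"))
    gap <- electrodes$gap
    ps <- electrodes$plate_size
    if (gap / 2 < max(abs(scaf_lo[1]), abs(scaf_hi[1]))) {
      stop("electrode plates intersect the scaffold", call. = FALSE)
    }
    t_pl <- 2 * h   # plate voxel thickness (conductor imposed as equipotential)
    for (side in c(1, -1)) {
      lab <- if (side > 0) "ITO_active" else "ITO_ground"
      x0 <- side * gap / 2
      lo <- c(min(x0, x0 + side * t_pl), -ps[1] / 2, -ps[2] / 2)
      hi <- c(max(x0, x0 + side * t_pl), ps[1] / 2, ps[2] / 2)
      codes <- .paint_box(codes, origin, h, n, lo, hi, code_of(lab),
                          only_over = med)
    }
    electrodes_meta <- list(active = "ITO_active", ground = "ITO_ground",
                            pet_thickness = electrodes$pet_thickness,
                            pet_material = "PET", gap = gap,
                            plate_size = ps)
  }

  g <- voxel_grid(codes, h, origin, label_table)
  attr(g, "scaffold_spec") <- spec
  attr(g, "roi_box") <- list(lo = scaf_lo, hi = scaf_hi)
  attr(g, "outlet_patch") <- list(face = "zmin",
                                  lo = c(-w_exit / 2, -w_exit / 2),
                                  hi = c(w_exit / 2, w_exit / 2))
  attr(g, "electrodes") <- electrodes_meta
  g
}

#' Build the capacitive-coupling validation cell
#'
#' The bench validation setup: two ITO-PET plates (33 x 18 mm) mounted
#' `gap` apart with culture medium between them, PET films facing the
#' medium, inside a non-conducting enclosure. The stack runs along x.
#'
#' @param gap Medium slab thickness (m), default 10 mm.
#' @param resolution Voxel edge (m).
#' @param pet_mode `"lumped"` (no PET voxels; the film enters the field
#'   solver as a surface impedance, thickness recorded in metadata) or
#'   `"resolved"` (PET voxelized explicitly; requires `resolution <=`
#'   `pet_thickness`).
#' @param assembly An [electrode_assembly()] providing plate size and PET
#'   thickness; its `gap` field is ignored in favour of `gap`.
#' @return A [voxel_grid()] with attribute `"electrodes"` as in
#'   [assemble_chamber()].
#' @export
build_validation_cell <- function(gap = 10e-3, resolution = 0.5e-3,
                                  pet_mode = c("lumped", "resolved"),
                                  assembly = electrode_assembly()) {
  pet_mode <- match.arg(pet_mode)
  stopifnot(gap > 0, resolution > 0)
  h <- resolution
  ps <- assembly$plate_size
  d_pet <- assembly$pet_thickness
  n_med <- max(1L, as.integer(round(gap / h)))
  n_pet <- if (pet_mode == "resolved" && d_pet > 0) {
    if (h > d_pet + 1e-15) stop("resolution too coarse to resolve the PET film", call. = FALSE)
    max(1L, as.integer(round(d_pet / h)))
  } else 0L
  n_ito <- 2L
  nx <- n_med + 2L * (n_pet + n_ito)
  ny <- as.integer(round(ps[1] / h))
  nz <- as.integer(round(ps[2] / h))
  label_table <- c("medium", "PET", "ITO_active", "ITO_ground")
  codes <- array(0L, dim = c(nx, ny, nz))
  i <- 1L
  codes[i:(i + n_ito - 1L), , ] <- 3L; i <- i + n_ito          # active ITO
  if (n_pet > 0) { codes[i:(i + n_pet - 1L), , ] <- 2L; i <- i + n_pet }
  codes[i:(i + n_med - 1L), , ] <- 1L; i <- i + n_med          # medium slab
  if (n_pet > 0) { codes[i:(i + n_pet - 1L), , ] <- 2L; i <- i + n_pet }
  codes[i:(i + n_ito - 1L), , ] <- 4L                          # ground ITO
  origin <- c(-(nx * h) / 2, -(ny * h) / 2, -(nz * h) / 2)
  g <- voxel_grid(codes, h, origin, label_table)
  attr(g, "electrodes") <- list(
    active = "ITO_active", ground = "ITO_ground",
    pet_thickness = if (pet_mode == "lumped") d_pet else 0,
    pet_material = "PET", gap = gap, plate_size = ps)
  g
}

#' Synthetic dye-front recording
#'
#' Emulates the bench measurement of perfusion velocity: a dye front
#' advected at constant velocity is sampled at a fixed frame rate with
#' Gaussian position noise (camera/feature-extraction error).
#'
#' @param true_velocity Front velocity, m/s (>= 0).
#' @param path_length Observed path length, m.
#' @param frame_rate Sampling rate, Hz.
#' @param noise_sd Position noise standard deviation, m.
#' @param t0 Timestamp of the first frame, s.
#' @param seed Optional integer; when given, the noise is drawn under a
#'   local RNG state so the recording is reproducible without touching the
#'   caller's RNG.
#' @return Data frame with columns `time` (s) and `position` (m).
#' @export
synthetic_dye_recording <- function(true_velocity, path_length, frame_rate,
                                    noise_sd = 0, t0 = 0, seed = NULL) {
  stopifnot(true_velocity >= 0, path_length > 0, frame_rate > 0, noise_sd >= 0)
  duration <- if (true_velocity > 0) path_length / true_velocity else 1
  t <- seq(0, duration, by = 1 / frame_rate)
  if (t[length(t)] < duration - 1e-12) t <- c(t, duration)
  pos <- true_velocity * t
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(seed)
    }
    pos <- pos + stats::rnorm(length(t), 0, noise_sd)
  }
  data.frame(time = t0 + t, position = pos)
}
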