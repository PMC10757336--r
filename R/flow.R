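#' Flow boundary conditions
#'
#' Boundary handling for [solve_flow()]. Every fluid-solid interface is
#' no-slip. Cells with label code 0 ("outside") act as pressure openings at
#' gauge pressure 0 when `open_label0 = TRUE` (the jagged cylindrical
#' chamber surface is an atmospheric-pressure inlet in the bioreactor
#' model); otherwise they are solid. The six box sides take one of
#' `"pressure"` (gauge 0 opening), `"wall"` (no-slip), `"slip"`
#' (symmetry), or `"velocity"` (prescribed mean normal outflow velocity
#' via `velocity_sides`). An `outlet_patch` prescribes an outflow velocity
#' on a rectangular patch of one side, overriding that side's base type.
#'
#' The absolute pressure level is immaterial for incompressible flow: the
#' standard-atmosphere inlet (1.01e5 Pa) maps to gauge 0.
#'
#' @param sides Named character vector / list for `xmin`, `xmax`, `ymin`,
#'   `ymax`, `zmin`, `zmax`; unspecified sides default to `default_side`.
#' @param velocity_sides Named numeric: outflow speed (m/s, >= 0) for sides
#'   of type `"velocity"`.
#' @param outlet_patch `NULL`, or `list(face =, lo =, hi =, velocity =)`
#'   with `lo`/`hi` the patch rectangle (m, global coordinates) in the
#'   side's two tangential axes (lower axis first).
#' @param default_side Type for unspecified sides.
#' @param open_label0 Treat label-code-0 cells as pressure openings?
#' @return An object of class `flow_bc`.
#' @export
flow_bc <- function(sides = list(), velocity_sides = NULL,
                    outlet_patch = NULL, default_side = "slip",
                    open_label0 = TRUE) {
  nm <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  types <- rep(default_side, 6)
  names(types) <- nm
  for (s in names(sides)) {
    if (!s %in% nm) stop("unknown side: ", s, call. = FALSE)
    types[s] <- sides[[s]]
  }
  if (!all(types %in% c("pressure", "wall", "slip", "velocity"))) {
    stop("side types must be pressure/wall/slip/velocity", call. = FALSE)
  }
  vals <- rep(0, 6)
  names(vals) <- nm
  for (s in names(velocity_sides)) vals[s] <- velocity_sides[[s]]
  if (any(vals < 0)) stop("outflow velocities must be >= 0", call. = FALSE)
  if (!is.null(outlet_patch)) {
    stopifnot(all(c("face", "lo", "hi", "velocity") %in% names(outlet_patch)),
              outlet_patch$velocity >= 0)
  }
  if (!any(types == "pressure") && is.null(outlet_patch) && !open_label0) {
    stop("need at least one pressure reference (pressure side or open cells)",
         call. = FALSE)
  }
  structure(list(types = types, values = vals, outlet_patch = outlet_patch,
                 open_label0 = open_label0),
            class = "flow_bc")
}

#' Default chamber flow boundary conditions
#'
#' All chamber surfaces are atmospheric-pressure inlets except the holder
#' outlet exit channel, which carries the prescribed mean outflow velocity
#' (default 0.120 m/s, the holder-connector average fed back from the
#' channel-network solution).
#'
#' @param grid Chamber grid from [assemble_chamber()].
#' @param outlet_velocity Mean outflow speed at the exit channel, m/s.
#' @return A [flow_bc()].
#' @export
chamber_flow_bc <- function(grid, outlet_velocity = 0.120) {
  op <- attr(grid, "outlet_patch")
  if (is.null(op)) stop("grid has no outlet_patch attribute", call. = FALSE)
  flow_bc(sides = list(zmin = "pressure", zmax = "pressure"),
          outlet_patch = list(face = op$face, lo = op$lo, hi = op$hi,
                              velocity = outlet_velocity),
          default_side = "pressure", open_label0 = TRUE)
}

# cell classes for the kernel: 0 open, 1 fluid, 2 solid
.flow_cellclass <- function(grid, fluid_label, open_label0) {
  cls <- array(2L, dim = grid$shape)
  cls[grid$labels == match(fluid_label, grid$label_table)] <- 1L
  cls[grid$labels == 0L] <- if (open_label0) 0L else 2L
  cls
}

.side_axes <- list(xmin = c(2L, 3L), xmax = c(2L, 3L),
                   ymin = c(1L, 3L), ymax = c(1L, 3L),
                   zmin = c(1L, 2L), zmax = c(1L, 2L))

#' Solve steady creeping (Stokes) flow on a labeled voxel grid
#'
#' Incompressible Stokes flow on the MAC staggered grid: momentum
#' `-mu * lap(u) + grad(p) = 0` and continuity `div(u) = 0`, with no-slip
#' at fluid-solid interfaces and the boundary conditions of `bc`. Inertia
#' is neglected: the perfusion regime is Re << 1 by design, and the
#' [reynolds()] diagnostic verifies applicability per run. The discrete
#' saddle-point system is solved by preconditioned MINRES.
#'
#' @param grid A [voxel_grid()].
#' @param bc A [flow_bc()].
#' @param fluid Fluid [material_spec()] (needs `mu`).
#' @param tol Relative residual tolerance (default 1e-8).
#' @param maxit Maximum MINRES iterations.
#' @return An object of class `flow_solution`: staggered face velocities
#'   `u$x`, `u$y`, `u$z` (m/s), cell pressures `p` (Pa, gauge; `NA` outside
#'   the fluid), cell-centred velocity `vel` and magnitude `speed`, the
#'   grid, convergence info, and `fluid_mask`.
#' @export
solve_flow <- function(grid, bc, fluid = get_material("medium"),
                       tol = 1e-8, maxit = 50000L) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(bc, "flow_bc"),
            inherits(fluid, "material_spec"))
  if (!isTRUE(fluid$fluid)) stop("material is not a fluid", call. = FALSE)
  fl <- fluid$name
  if (!fl %in% grid$label_table) stop("grid has no '", fl, "' cells", call. = FALSE)
  cls <- .flow_cellclass(grid, fl, bc$open_label0)
  if (!any(cls == 1L)) stop("no fluid cells", call. = FALSE)
  # connectivity: fluid pockets with no path to the main wet region cannot
  # flow and would leave their pressure undetermined; freeze them as solid
  wet <- cls != 2L
  main <- array(flood_mask_cpp(as.integer(dim(cls)), as.vector(wet)),
                dim = dim(cls))
  if (any(wet & !main)) {
    n_iso <- sum(wet & !main & cls == 1L)
    if (n_iso == sum(cls == 1L)) {
      stop("fluid region is disconnected from all boundary openings", call. = FALSE)
    }
    if (n_iso > 0) {
      warning(sprintf("%d isolated fluid cells frozen (no path to an opening)",
                      n_iso), call. = FALSE)
    }
    cls[wet & !main] <- 2L
  }

  type_code <- c(pressure = 0L, wall = 1L, slip = 2L, velocity = 3L)
  side_type <- unname(type_code[bc$types])
  side_value <- numeric(6)
  for (s in seq_len(6)) {
    nmm <- names(bc$types)[s]
    if (bc$types[s] == "velocity") {
      # signed normal velocity for outflow through that side
      sgn <- if (grepl("min$", nmm)) -1 else 1
      side_value[s] <- sgn * bc$values[nmm]
    }
  }
  patch_side <- -1L
  patch_rect <- c(0L, -1L, 0L, -1L)
  patch_value <- 0
  if (!is.null(bc$outlet_patch)) {
    op <- bc$outlet_patch
    nm <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
    patch_side <- match(op$face, nm) - 1L
    axes <- .side_axes[[op$face]]
    rect <- integer(4)
    for (t in 1:2) {
      a <- axes[t]
      lo_i <- floor((op$lo[t] - grid$origin[a]) / grid$spacing)
      hi_i <- ceiling((op$hi[t] - grid$origin[a]) / grid$spacing) - 1
      rect[2 * t - 1] <- max(0L, as.integer(lo_i))
      rect[2 * t] <- min(grid$shape[a] - 1L, as.integer(hi_i))
    }
    patch_rect <- rect
    sgn <- if (grepl("min$", op$face)) -1 else 1
    patch_value <- sgn * op$velocity
  }

  res <- stokes_minres_solve(
    as.integer(grid$shape), as.integer(cls), side_type, side_value,
    patch_side, patch_rect, patch_value,
    fluid$mu, grid$spacing, tol, as.integer(maxit))
  if (res$relres > tol * 10) {
    stop(sprintf("flow solver did not converge: relative residual %.3e after %d iterations",
                 res$relres, res$iterations), call. = FALSE)
  }
  u <- list(x = res$u[[1]], y = res$u[[2]], z = res$u[[3]])
  n <- grid$shape
  vel <- list(
    x = (u$x[1:n[1], , , drop = FALSE] + u$x[2:(n[1] + 1), , , drop = FALSE]) / 2,
    y = (u$y[, 1:n[2], , drop = FALSE] + u$y[, 2:(n[2] + 1), , drop = FALSE]) / 2,
    z = (u$z[, , 1:n[3], drop = FALSE] + u$z[, , 2:(n[3] + 1), drop = FALSE]) / 2)
  speed <- sqrt(vel$x^2 + vel$y^2 + vel$z^2)
  fluid_mask <- cls == 1L
  speed[!fluid_mask] <- NA_real_
  structure(
    list(u = u, p = res$p, vel = vel, speed = speed, grid = grid,
         fluid = fluid, fluid_mask = fluid_mask,
         iterations = res$iterations, relres = res$relres, bc = bc),
    class = "flow_solution")
}


#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d x %d x %d cells, %d fluid; %d iterations, relres %.2e\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              sum(x$fluid_mask), x$iterations, x$relres))
  invisible(x)
}

#' Maximum interior divergence of a flow solution
#'
#' Mass-balance diagnostic: the discrete divergence in every fluid cell,
#' normalized by the outlet flux scale `U / h`.
#'
#' @param sol A `flow_solution`.
#' @return Max absolute divergence (1/s) over fluid cells.
#' @export
flow_divergence <- function(sol) {
  n <- sol$grid$shape
  h <- sol$grid$spacing
  div <- (sol$u$x[2:(n[1] + 1), , , drop = FALSE] - sol$u$x[1:n[1], , , drop = FALSE] +
          sol$u$y[, 2:(n[2] + 1), , drop = FALSE] - sol$u$y[, 1:n[2], , drop = FALSE] +
          sol$u$z[, , 2:(n[3] + 1), drop = FALSE] - sol$u$z[, , 1:n[3], drop = FALSE]) / h
  max(abs(div[sol$fluid_mask]))
}

# cell-centred gradient of a cell-centred velocity component along axis a.
# Wall-adjacent cells (interior solid neighbour, or a no-slip domain side
# given by bmode) take the one-sided gradient to the no-slip plane half a
# cell away; slip sides have zero tangential gradient; open sides fall
# back to a one-sided interior difference. solid marks interior solid
# cells; bmode = c(min, max) in {"wall", "zero", "oneside"}.
.cc_gradient <- function(field, fluid, solid, a, h, bmode = c("oneside", "oneside")) {
  n <- dim(field)
  shp <- function(arr, by, fill) {
    # shift arr by one cell along axis a, direction by (+1 or -1)
    out <- array(fill, dim = n)
    idx_src <- lapply(n, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[a]] <- 2:n[a]; idx_src[[a]] <- 1:(n[a] - 1) }
    else { idx_dst[[a]] <- 1:(n[a] - 1); idx_src[[a]] <- 2:n[a] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  up <- shp(field, 1, NA_real_)    # value at cell - 1 along a
  dn <- shp(field, -1, NA_real_)   # value at cell + 1 along a
  fup <- shp(fluid, 1, FALSE)
  fdn <- shp(fluid, -1, FALSE)
  up[!fup] <- NA_real_
  dn[!fdn] <- NA_real_
  both <- !is.na(up) & !is.na(dn)
  g <- array(0, dim = n)
  g[both] <- (dn[both] - up[both]) / (2 * h)
  # interior wall: missing neighbour is a solid cell -> no-slip at h/2
  wall_up <- shp(solid, 1, bmode[1] == "wall")
  wall_dn <- shp(solid, -1, bmode[2] == "wall")
  zero_up <- shp(array(FALSE, n), 1, bmode[1] == "zero")
  zero_dn <- shp(array(FALSE, n), -1, bmode[2] == "zero")
  only_dn <- is.na(up) & !is.na(dn)
  only_up <- !is.na(up) & is.na(dn)
  w_up <- only_dn & wall_up
  w_dn <- only_up & wall_dn
  g[w_up] <- field[w_up] / (h / 2)
  g[w_dn] <- -field[w_dn] / (h / 2)
  o_dn <- only_dn & !wall_up & !zero_up
  o_up <- only_up & !wall_dn & !zero_dn
  g[o_dn] <- (dn[o_dn] - field[o_dn]) / h
  g[o_up] <- (field[o_up] - up[o_up]) / h
  # zero-gradient cases (slip sides) stay 0; doubly-isolated cells stay 0
  g[!fluid] <- 0
  g
}

#' Shear rate and shear stress fields
#'
#' Computes the shear rate `gdot = sqrt(2 D:D)` from the symmetric part
#' `D` of the cell-centred velocity-gradient tensor, and the Newtonian
#' shear stress `tau = mu * gdot`. In cells sharing a face with a solid the
#' wall-normal gradient is taken one-sided to the wall (no-slip plane at
#' half a cell), so their `tau` is the wall-shear estimate.
#'
#' @param sol A `flow_solution`.
#' @param mu Dynamic viscosity, Pa s (default: the solution's fluid).
#' @return `sol` with added cell fields `shear_rate` (1/s) and `tau` (Pa,
#'   `units` attribute `"Pa"`), plus `wall_adjacent` mask.
#' @export
shear_stress <- function(sol, mu = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  if (is.null(mu)) mu <- sol$fluid$mu
  h <- sol$grid$spacing
  n <- sol$grid$shape
  fl <- sol$fluid_mask
  solid <- array(sol$grid$labels != 0L, dim = n) & !fl
  comp <- list(sol$vel$x, sol$vel$y, sol$vel$z)
  for (ci in 1:3) comp[[ci]][!fl] <- 0
  # boundary treatment per axis side for tangential derivatives:
  # wall & velocity sides pin the tangential velocity at the boundary
  # plane; slip sides are symmetry planes; pressure sides are open
  bmode_of <- function(type) switch(type, wall = "wall", velocity = "wall",
                                    slip = "zero", pressure = "oneside")
  bm <- lapply(1:3, function(a) c(bmode_of(sol$bc$types[2 * a - 1]),
                                  bmode_of(sol$bc$types[2 * a])))
  # gradient tensor g[[i]][[a]] = d u_i / d x_a; diagonal terms exactly
  # from the staggered face velocities
  face_diff <- function(d) {
    idx_hi <- idx_lo <- lapply(n, seq_len)
    idx_hi[[d]] <- idx_hi[[d]] + 1L
    (sol$u[[d]][idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] -
     sol$u[[d]][idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]) / h
  }
  gt <- lapply(1:3, function(ci) lapply(1:3, function(a) {
    if (ci == a) {
      g <- face_diff(ci)
      g[!fl] <- 0
      g
    } else {
      .cc_gradient(comp[[ci]], fl, solid, a, h, bm[[a]])
    }
  }))
  ss <- array(0, dim = sol$grid$shape)
  for (ci in 1:3) for (a in 1:3) {
    D <- (gt[[ci]][[a]] + gt[[a]][[ci]]) / 2
    ss <- ss + 2 * D * D
  }
  gdot <- sqrt(ss)
  gdot[!fl] <- NA_real_
  tau <- mu * gdot
  attr(tau, "units") <- "Pa"
  attr(gdot, "units") <- "1/s"
  wall_adj <- fl & .touches(solid)
  sol$shear_rate <- gdot
  sol$tau <- tau
  sol$wall_adjacent <- wall_adj
  sol
}

# cells sharing a face with a TRUE cell of mask
.touches <- function(mask) {
  n <- dim(mask)
  out <- array(FALSE, dim = n)
  out[-n[1], , ] <- out[-n[1], , ] | mask[-1, , ]
  out[-1, , ] <- out[-1, , ] | mask[-n[1], , ]
  out[, -n[2], ] <- out[, -n[2], ] | mask[, -1, ]
  out[, -1, ] <- out[, -1, ] | mask[, -n[2], ]
  out[, , -n[3]] <- out[, , -n[3]] | mask[, , -1]
  out[, , -1] <- out[, , -1] | mask[, , -n[3]]
  out
}

#' Cell Reynolds number diagnostic
#'
#' `Re = rho * |u| * L_char / mu` per fluid cell. The characteristic
#' length convention is configurable (default: the scaffold pore size when
#' the grid carries a scaffold spec, otherwise the cell size); the creeping
#' -flow approximation is justified where `Re` stays well below 1.
#'
#' @param sol A `flow_solution`.
#' @param fluid Fluid material (default: the solution's).
#' @param L_char Characteristic length, m.
#' @return List with `field` (cell array), `max`, `mean` over fluid cells.
#' @export
reynolds <- function(sol, fluid = NULL, L_char = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  if (is.null(fluid)) fluid <- sol$fluid
  if (is.null(L_char)) {
    sp <- attr(sol$grid, "scaffold_spec")
    L_char <- if (!is.null(sp)) sp$pore else sol$grid$spacing
  }
  if (L_char <= 0) stop("L_char must be > 0", call. = FALSE)
  re <- fluid$rho * sol$speed * L_char / fluid$mu
  list(field = re, max = max(re[sol$fluid_mask]),
       mean = mean(re[sol$fluid_mask]), L_char = L_char)
}
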