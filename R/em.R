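#' Electric-field boundary conditions
#'
#' Frequency-domain drive for the quasistatic solver: potential amplitude
#' `V_amp` on the active electrode conductor, 0 V on the ground electrode,
#' at frequency `f`. The baseline stimulation protocol is a 10 V
#' peak-to-peak sine (amplitude 5 V) at 60 kHz.
#'
#' @param V_amp Active-electrode potential amplitude, V (>= 0).
#' @param f Frequency, Hz (> 0 for frequency-domain solves; 0 = DC).
#' @param R_s Optional series measurement resistor, Ohm (see
#'   [apply_series_resistor()]).
#' @return An object of class `em_bc`.
#' @export
em_bc <- function(V_amp = 5, f = 60e3, R_s = NULL) {
  stopifnot(is.numeric(V_amp), V_amp >= 0, f >= 0)
  if (!is.null(R_s) && R_s < 0) stop("R_s must be >= 0", call. = FALSE)
  structure(list(V_amp = V_amp, f = f, R_s = R_s), class = "em_bc")
}

#' Solve the quasistatic electric-field problem on a labeled voxel grid
#'
#' Solves the current-conservation equation `div(sigma*(x) grad V) = 0`
#' with complex admittivity `sigma* = sigma + i w eps0 eps_r`, Dirichlet
#' potentials on the electrode conductors, and insulating (no-flux)
#' conditions on outside cells and domain boundaries. Electrode conductors
#' (ITO) are imposed as equipotential Dirichlet regions, justified by their
#' conductivity contrast of 6+ orders of magnitude over the medium.
#'
#' Thin PET films on the electrodes are handled in one of two ways: if the
#' grid metadata carries a nonzero lumped `pet_thickness`, the film enters
#' as a surface impedance `Z = d / sigma*_PET` on electrode-medium faces;
#' if the film is voxel-resolved, its cells participate like any other
#' material.
#'
#' Cells whose admittivity magnitude falls below `exclude_rel` times the
#' largest non-electrode admittivity are treated as perfect insulators and
#' removed from the unknown set: at 60 kHz the scaffold and holder
#' polymers conduct ~1e-5 of the medium, so dropping them changes the
#' fields by parts in 1e5 while keeping the system well conditioned. Set
#' `exclude_rel = 0` to keep every material.
#'
#' @param grid A [voxel_grid()], typically from [assemble_chamber()] or
#'   [build_validation_cell()] (metadata attribute `"electrodes"` names the
#'   active/ground labels).
#' @param bc An [em_bc()].
#' @param materials Material registry.
#' @param exclude_rel Relative admittivity threshold below which a
#'   material is treated as a perfect insulator.
#' @param tol Relative residual tolerance (default 1e-8).
#' @param maxit Maximum COCG iterations.
#' @param active,ground Electrode labels; default from grid metadata.
#' @return An object of class `em_solution`: complex potential `V` (cell
#'   array, `NA` in excluded cells), complex field components `E` (V/m),
#'   field magnitude `E_mag` (`units` `"V/m"`), current density magnitude
#'   `J_mag`, terminal currents `I_active`, `I_ground` (complex, A), the
#'   grid, and convergence info.
#' @export
solve_em <- function(grid, bc, materials = default_materials(),
                     exclude_rel = 1e-4, tol = 1e-8, maxit = 50000L,
                     active = NULL, ground = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(bc, "em_bc"))
  meta <- attr(grid, "electrodes")
  if (is.null(active)) active <- meta$active
  if (is.null(ground)) ground <- meta$ground
  if (is.null(active) || is.null(ground)) {
    stop("no electrode labels: supply active/ground or grid metadata", call. = FALSE)
  }
  act_code <- match(active, grid$label_table)
  gnd_code <- match(ground, grid$label_table)
  if (is.na(act_code) || is.na(gnd_code) || !any(grid$labels == act_code) ||
      !any(grid$labels == gnd_code)) {
    stop("both electrode conductor regions must be present in the grid", call. = FALSE)
  }
  if (any(.touches(array(grid$labels == act_code, dim = grid$shape)) &
          array(grid$labels == gnd_code, dim = grid$shape))) {
    stop("electrodes touch: short-circuit geometry", call. = FALSE)
  }

  # admittivity per label (electrode labels resolve to the conductor metal)
  lab_sigma <- vapply(grid$label_table, function(lb) {
    nm <- if (lb %in% c(active, ground)) "ITO" else lb
    if (!nm %in% names(materials)) {
      stop(sprintf("no material registered for label '%s'", nm), call. = FALSE)
    }
    complex_conductivity(materials[[nm]], bc$f)
  }, complex(1))
  non_elec <- !(grid$label_table %in% c(active, ground))
  smax <- max(Mod(lab_sigma[non_elec]))
  lab_sigma[non_elec & Mod(lab_sigma) < exclude_rel * smax] <- 0 + 0i

  sigma <- array(0 + 0i, dim = grid$shape)
  for (li in seq_along(grid$label_table)) {
    sigma[grid$labels == li] <- lab_sigma[li]
  }
  role <- array(0L, dim = grid$shape)
  role[grid$labels == act_code] <- 1L
  role[grid$labels == gnd_code] <- 2L

  z_pet <- 0 + 0i
  if (!is.null(meta$pet_thickness) && meta$pet_thickness > 0) {
    s_pet <- complex_conductivity(materials[[meta$pet_material]], bc$f)
    z_pet <- meta$pet_thickness / s_pet
  }

  res <- em_cocg_solve(as.integer(grid$shape), as.vector(sigma),
                       as.vector(role), bc$V_amp, z_pet,
                       grid$spacing, tol, as.integer(maxit))
  if (res$relres > tol * 10) {
    stop(sprintf("em solver did not converge: relative residual %.3e after %d iterations",
                 res$relres, res$iterations), call. = FALSE)
  }
  V <- array(res$V, dim = grid$shape)
  E <- list(x = array(res$E[[1]], dim = grid$shape),
            y = array(res$E[[2]], dim = grid$shape),
            z = array(res$E[[3]], dim = grid$shape))
  E_mag <- sqrt(Mod(E$x)^2 + Mod(E$y)^2 + Mod(E$z)^2)
  attr(E_mag, "units") <- "V/m"
  J_mag <- E_mag * Mod(sigma)
  attr(J_mag, "units") <- "A/m^2"
  structure(
    list(V = V, E = E, E_mag = E_mag, J_mag = J_mag, grid = grid, bc = bc,
         sigma = sigma,
         I_active = res$I_active, I_ground = res$I_ground,
         iterations = res$iterations, relres = res$relres,
         n_unknowns = res$n_unknowns),
    class = "em_solution")
}

#' @export
print.em_solution <- function(x, ...) {
  cat(sprintf("<em_solution> %d x %d x %d cells, %g unknowns; %d iterations, relres %.2e\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$n_unknowns, x$iterations, x$relres))
  cat(sprintf("  |I_active| = %.4g A, |I_ground| = %.4g A\n",
              Mod(x$I_active), Mod(x$I_ground)))
  invisible(x)
}

#' Analytic 1D layered-media oracle
#'
#' For a stack of planar layers normal to the field axis, current
#' continuity makes the complex current density `J` uniform; each layer
#' contributes a series impedance per unit area `Z_k = d_k / sigma*_k`, so
#' `J = V_amp / sum(Z_k)` and `E_k = J / sigma*_k`. Independent of plate
#' area by construction. For the bench validation cell
#' (PET 175 um | medium 10 mm | PET 175 um) at 5 V and 60 kHz this
#' predicts a uniform medium field of 0.095 V/m.
#'
#' @param layers List of `list(thickness =, material =)` entries (thickness
#'   m; material a [material_spec()] or registry label).
#' @param V_amp Potential amplitude across the stack, V.
#' @param f Frequency, Hz.
#' @param registry Material registry for label lookup.
#' @return List with `E` (complex field per layer, V/m), `E_mag`, `J`
#'   (complex current density, A/m^2), `Z_total` (area-normalized
#'   impedance, Ohm m^2), and the input layer table.
#' @export
layered_1d_oracle <- function(layers, V_amp, f, registry = default_materials()) {
  stopifnot(length(layers) >= 1)
  keep <- vapply(layers, function(l) l$thickness > 0, logical(1))
  if (!all(keep)) {
    warning("dropping zero-thickness layer(s)", call. = FALSE)
    layers <- layers[keep]
  }
  sig <- vapply(layers, function(l) {
    m <- l$material
    if (is.character(m)) m <- get_material(m, registry)
    complex_conductivity(m, f)
  }, complex(1))
  d <- vapply(layers, function(l) l$thickness, numeric(1))
  Z <- d / sig
  J <- V_amp / sum(Z)
  E <- J / sig
  list(E = E, E_mag = Mod(E), J = J, Z_total = sum(Z),
       layers = data.frame(thickness = d, Z = Z))
}

#' Correct predicted terminal current and fields for a series resistor
#'
#' The bench measurement reads the current across a series resistor `R_s`
#' that the field model neglects. The setup impedance is inferred from the
#' uncorrected prediction as `Z = V_amp / I_base` (taken purely reactive
#' when only a current magnitude is supplied, as appropriate for a
#' capacitively dominated stack); the corrected current is
#' `I = V_amp / |Z + R_s|` and, by linearity, all fields scale by
#' `I / I_base`.
#'
#' @param V_amp Drive amplitude, V.
#' @param I_base Predicted terminal current without the resistor, A
#'   (magnitude, or complex).
#' @param R_s Series resistance, Ohm (>= 0).
#' @return List with `I` (corrected magnitude, A) and `scale`
#'   (`I / I_base`, the factor to apply to any predicted field).
#' @export
apply_series_resistor <- function(V_amp, I_base, R_s) {
  if (R_s < 0) stop("R_s must be >= 0", call. = FALSE)
  if (Mod(I_base) <= 0) stop("I_base must be > 0", call. = FALSE)
  Z <- if (is.complex(I_base)) V_amp / I_base
       else complex(real = 0, imaginary = -V_amp / I_base)
  I_corr <- V_amp / Mod(Z + R_s)
  list(I = I_corr, scale = I_corr / Mod(I_base))
}

#' Back-calculate the field from a measured terminal current
#'
#' The quasistatic model is linear, so a predicted field/current pair
#' rescales to a measured current: `E_est = E_pred * I_meas / I_pred`.
#'
#' @param E_pred Predicted field magnitude, V/m.
#' @param I_pred Predicted terminal current magnitude, A (> 0).
#' @param I_meas Measured terminal current magnitude, A.
#' @return Estimated field magnitude, V/m.
#' @export
field_from_measured_current <- function(E_pred, I_pred, I_meas) {
  if (I_pred <= 0) stop("I_pred must be > 0", call. = FALSE)
  E_pred * I_meas / I_pred
}
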