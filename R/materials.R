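#' Physical constants
#'
#' Vacuum permittivity in F/m, used when converting relative permittivity to
#' the imaginary part of the complex admittivity.
#' @keywords internal
EPS0 <- 8.854e-12

#' Construct a material specification
#'
#' A material carries the electrical properties used by the quasistatic
#' field solver (conductivity `sigma`, relative permittivity `eps_r`) and,
#' for fluids, the rheological properties used by the flow solver (dynamic
#' viscosity `mu`, density `rho`).
#'
#' Note on units: the culture-medium viscosity 6.89e-4 Pa s is a *dynamic*
#' viscosity (Pa s); shear stress is computed as `mu * shear_rate`, valid
#' for Newtonian fluids.
#'
#' @param name Label (character scalar).
#' @param sigma Electric conductivity, S/m. Must be >= 0.
#' @param eps_r Relative permittivity (dimensionless). Must be >= 1.
#' @param mu Dynamic viscosity, Pa s (fluids only; `NA` for solids).
#' @param rho Density, kg/m^3 (fluids only; `NA` for solids).
#' @param fluid Logical; is this material a fluid the flow solver may move?
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, sigma, eps_r, mu = NA_real_, rho = NA_real_,
                          fluid = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(sigma) || sigma < 0) {
    stop("sigma must be a non-negative conductivity in S/m", call. = FALSE)
  }
  if (!is.numeric(eps_r) || eps_r < 1) {
    stop("eps_r must be >= 1", call. = FALSE)
  }
  if (isTRUE(fluid)) {
    if (!is.finite(mu) || mu <= 0) stop("fluid materials need mu > 0 (Pa s)", call. = FALSE)
    if (!is.finite(rho) || rho <= 0) stop("fluid materials need rho > 0 (kg/m^3)", call. = FALSE)
  }
  structure(
    list(name = name, sigma = as.numeric(sigma), eps_r = as.numeric(eps_r),
         mu = as.numeric(mu), rho = as.numeric(rho), fluid = isTRUE(fluid)),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material '%s'> sigma = %g S/m, eps_r = %g", x$name, x$sigma, x$eps_r))
  if (x$fluid) cat(sprintf(", mu = %g Pa s, rho = %g kg/m^3", x$mu, x$rho))
  cat("\n")
  invisible(x)
}

#' Built-in material registry
#'
#' The default registry holds the five materials of the bioreactor model
#' domains: osteogenic culture medium at 37 C, the ITO and PET parts of the
#' capacitive electrodes, the C8 PLA composite used for printed bioreactor
#' parts, and the PCL scaffold polymer. The honeycomb scaffold is modelled
#' with PCL electrical properties by default (no dedicated property set is
#' available for carbonate apatite); override via `material_overrides` in the
#' solvers if needed.
#'
#' @return A named list of [material_spec()] objects, class `material_registry`.
#' @export
default_materials <- function() {
  reg <- list(
    medium = material_spec("medium", sigma = 1.5, eps_r = 80.1,
                           mu = 6.89e-4, rho = 9.94e2, fluid = TRUE),
    ITO    = material_spec("ITO", sigma = 1e6, eps_r = 1),
    PET    = material_spec("PET", sigma = 1e-21, eps_r = 3),
    C8     = material_spec("C8", sigma = 1e-21, eps_r = 2.7),
    PCL    = material_spec("PCL", sigma = 1e-13, eps_r = 3.2)
  )
  class(reg) <- "material_registry"
  reg
}

#' Look up a material in a registry
#'
#' @param name Material label.
#' @param registry A material registry (default [default_materials()]).
#' @return The [material_spec()] for `name`.
#' @export
get_material <- function(name, registry = default_materials()) {
  if (!name %in% names(registry)) {
    stop(sprintf("unknown material '%s'; registered: %s", name,
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  registry[[name]]
}

#' Complex admittivity of a material at a given frequency
#'
#' Under the quasistatic approximation the frequency-domain current
#' conservation equation uses the complex admittivity
#' `sigma* = sigma + i * 2*pi*f * eps0 * eps_r`. At `f = 0` this reduces to
#' the DC conductivity.
#'
#' @param material A [material_spec()] (or a registry label).
#' @param f Frequency in Hz, >= 0.
#' @param registry Registry used when `material` is given as a label.
#' @return Complex admittivity in S/m.
#' @export
complex_conductivity <- function(material, f, registry = default_materials()) {
  if (is.character(material)) material <- get_material(material, registry)
  stopifnot(inherits(material, "material_spec"))
  if (!is.numeric(f) || any(f < 0)) {
    stop("frequency must be >= 0 Hz", call. = FALSE)
  }
  complex(real = material$sigma, imaginary = 2 * pi * f * EPS0 * material$eps_r)
}

#' Write / read a material registry as a YAML config
#'
#' Users can add or override materials without code changes; the file is a
#' map from label to `sigma`, `eps_r` and (for fluids) `mu`, `rho`.
#'
#' @param registry A `material_registry`.
#' @param path File path.
#' @return `read_materials` returns a `material_registry`.
#' @export
write_materials <- function(registry, path) {
  lst <- lapply(unclass(registry), function(m) {
    out <- list(sigma = m$sigma, eps_r = m$eps_r)
    if (isTRUE(m$fluid)) {
      out$mu <- m$mu
      out$rho <- m$rho
      out$fluid <- TRUE
    }
    out
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_materials
#' @export
read_materials <- function(path) {
  lst <- yaml::read_yaml(path)
  reg <- lapply(names(lst), function(nm) {
    m <- lst[[nm]]
    material_spec(nm, sigma = m$sigma, eps_r = m$eps_r,
                  mu = if (is.null(m$mu)) NA_real_ else m$mu,
                  rho = if (is.null(m$rho)) NA_real_ else m$rho,
                  fluid = isTRUE(m$fluid))
  })
  names(reg) <- names(lst)
  class(reg) <- "material_registry"
  reg
}
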