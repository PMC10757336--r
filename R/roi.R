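#' Osteogenic microenvironment target windows
#'
#' Literature windows for osteoinductive stimulation of mesenchymal
#' stromal cells: wall shear stress 1.47-24 mPa and 0.20-13.35 mPa, and
#' electric field magnitude 1.0e-5 to 1.3e3 V/m. A candidate design passes
#' a window when at least `required_fraction` of the ROI fluid volume lies
#' inside it.
#'
#' @param shear_windows List of length-2 numeric windows, Pa.
#' @param field_window Length-2 numeric window, V/m.
#' @param required_fraction Required in-window volume fraction in (0, 1].
#' @return An object of class `microenv_target`.
#' @export
microenv_target <- function(shear_windows = list(c(1.47e-3, 24e-3),
                                                 c(0.20e-3, 13.35e-3)),
                            field_window = c(1.0e-5, 1.3e3),
                            required_fraction = 0.5) {
  for (w in c(shear_windows, list(field_window))) {
    stopifnot(length(w) == 2L, w[1] < w[2])
  }
  stopifnot(required_fraction > 0, required_fraction <= 1)
  structure(list(shear_windows = shear_windows, field_window = field_window,
                 required_fraction = required_fraction),
            class = "microenv_target")
}

#' Extract the scaffold-envelope region of interest
#'
#' The ROI is the axis-aligned envelope volume surrounding the culture
#' scaffold; stimulation dose statistics are computed over the fluid cells
#' inside it.
#'
#' @param grid A [voxel_grid()] carrying a scaffold (from
#'   [generate_scaffold()] or [assemble_chamber()]).
#' @param scaffold_spec Optional [scaffold_spec()]; defaults to the grid's
#'   attached spec.
#' @return List with `mask` (logical cell array over the envelope box),
#'   `n_fluid`, `n_solid` (cell counts inside, fluid = medium cells),
#'   `box` (global lo/hi, m).
#' @export
extract_roi <- function(grid, scaffold_spec = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  spec <- if (!is.null(scaffold_spec)) scaffold_spec else attr(grid, "scaffold_spec")
  if (is.null(spec)) stop("no scaffold spec available", call. = FALSE)
  if (!spec$material %in% grid$label_table ||
      !any(grid$labels == match(spec$material, grid$label_table))) {
    stop("scaffold absent from grid", call. = FALSE)
  }
  box <- attr(grid, "roi_box")
  if (is.null(box)) {
    # scaffold-only grid: the envelope is the whole grid extent
    box <- list(lo = grid$origin, hi = grid$origin + grid$shape * grid$spacing)
  }
  ax <- grid_axes(grid)
  inx <- ax$x > box$lo[1] & ax$x < box$hi[1]
  iny <- ax$y > box$lo[2] & ax$y < box$hi[2]
  inz <- ax$z > box$lo[3] & ax$z < box$hi[3]
  mask <- array(FALSE, dim = grid$shape)
  mask[inx, iny, inz] <- TRUE
  med_code <- match("medium", grid$label_table)
  n_fluid <- if (is.na(med_code)) 0L else sum(mask & grid$labels == med_code)
  solid_code <- match(spec$material, grid$label_table)
  list(mask = mask, n_fluid = n_fluid,
       n_solid = sum(mask & grid$labels == solid_code), box = box)
}

#' Volume-weighted ROI histogram of a cell field
#'
#' Statistics over the fluid cells of the ROI: each cell contributes its
#' volume `h^3`. Counts are normalized to the peak bin (the figures'
#' convention); the figure-equivalent "node occurrence" histogram is
#' approximated by cell values weighted by cell volume, which is the
#' well-defined continuum limit of the same quantity.
#'
#' @param field Cell scalar array (may carry a `units` attribute).
#' @param roi Result of [extract_roi()], or a logical mask array.
#' @param grid The [voxel_grid()] the field lives on.
#' @param fluid_mask Logical array of cells to include (default: cells
#'   labeled `"medium"`). Solid scaffold cells are excluded from dose
#'   statistics; pass a custom mask to include them for sensitivity
#'   studies.
#' @param bins Bin edges; default 100 equal bins from 0 to the ROI max.
#' @return An object of class `roi_histogram`: `edges`, `volume` (m^3 per
#'   bin), `normalized` (peak = 1), `roi_volume`, `mean`, `max`, `values`
#'   (included cell values), `weights`, `units`.
#' @export
roi_histogram <- function(field, roi, grid, fluid_mask = NULL, bins = NULL) {
  mask <- if (is.list(roi)) roi$mask else roi
  stopifnot(all(dim(field) == grid$shape), all(dim(mask) == grid$shape))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  if (is.null(fluid_mask)) {
    med <- match("medium", grid$label_table)
    if (is.na(med)) stop("grid has no medium cells; supply fluid_mask", call. = FALSE)
    fluid_mask <- array(grid$labels == med, dim = grid$shape)
  }
  inc <- mask & fluid_mask & !is.na(field)
  if (!any(inc)) stop("no fluid cells in the ROI", call. = FALSE)
  vals <- field[inc]
  h3 <- grid$spacing^3
  if (is.null(bins)) {
    top <- max(vals)
    if (top <= 0) top <- 1
    bins <- seq(0, top, length.out = 101L)
  }
  cut_idx <- findInterval(vals, bins, rightmost.closed = TRUE, all.inside = TRUE)
  vol <- numeric(length(bins) - 1L)
  agg <- tapply(rep(h3, length(vals)), factor(cut_idx, levels = seq_along(vol)), sum)
  vol[!is.na(agg)] <- agg[!is.na(agg)]
  peak <- max(vol)
  structure(
    list(edges = bins, volume = vol,
         normalized = if (peak > 0) vol / peak else vol,
         roi_volume = sum(inc) * h3,
         mean = mean(vals), max = max(vals),
         values = vals, weights = rep(h3, length(vals)),
         units = attr(field, "units")),
    class = "roi_histogram")
}

#' @export
print.roi_histogram <- function(x, ...) {
  cat(sprintf("<roi_histogram> %d bins, ROI fluid volume %.3g m^3, mean %.4g %s, max %.4g\n",
              length(x$volume), x$roi_volume, x$mean,
              if (is.null(x$units)) "" else x$units, x$max))
  invisible(x)
}

#' In-window volume fractions against a microenvironment target
#'
#' Fraction of the ROI fluid volume whose field value falls inside each
#' target window; a window passes when its fraction reaches the target's
#' required fraction. Units carried on the field select the window family
#' (`"Pa"` -> shear windows, `"V/m"` -> field window); a histogram without
#' units must match `what`.
#'
#' @param hist A [roi_histogram()].
#' @param target A [microenv_target()].
#' @param what `"shear"` or `"field"`; default inferred from units.
#' @return Data frame with window lo/hi, `fraction` and `pass`.
#' @export
score_against_target <- function(hist, target, what = NULL) {
  stopifnot(inherits(hist, "roi_histogram"), inherits(target, "microenv_target"))
  if (is.null(what)) {
    if (is.null(hist$units)) stop("field has no units; pass `what`", call. = FALSE)
    what <- switch(hist$units, "Pa" = "shear", "V/m" = "field",
                   stop("unsupported field units: ", hist$units, call. = FALSE))
  } else if (!is.null(hist$units)) {
    expect <- switch(what, shear = "Pa", field = "V/m")
    if (hist$units != expect) {
      stop(sprintf("unit mismatch: field in %s but target windows in %s",
                   hist$units, expect), call. = FALSE)
    }
  }
  windows <- if (what == "shear") target$shear_windows else list(target$field_window)
  tot <- sum(hist$weights)
  rows <- lapply(windows, function(w) {
    fr <- sum(hist$weights[hist$values >= w[1] & hist$values <= w[2]]) / tot
    data.frame(lo = w[1], hi = w[2], fraction = fr,
               pass = fr >= target$required_fraction)
  })
  do.call(rbind, rows)
}

#' Rescale a solved protocol by linearity
#'
#' Both physics are linear in their drive (Stokes flow in the pump rate,
#' the quasistatic field in the electrode amplitude), so scaling a solved
#' field by `factor` equals a fresh solve at the scaled protocol. Supports
#' `flow_solution`, `em_solution` and `roi_histogram` inputs.
#'
#' @param x Solution or histogram to rescale.
#' @param factor Non-negative scale factor.
#' @return Object of the same class with all linear fields scaled.
#' @export
rescale_protocol <- function(x, factor) {
  if (!is.numeric(factor) || factor < 0) {
    stop("scale factor must be >= 0", call. = FALSE)
  }
  scale_keep <- function(f) {
    u <- attr(f, "units")
    f <- f * factor
    attr(f, "units") <- u
    f
  }
  if (inherits(x, "flow_solution")) {
    x$u <- lapply(x$u, `*`, factor)
    x$vel <- lapply(x$vel, `*`, factor)
    x$p <- x$p * factor
    x$speed <- x$speed * factor
    if (!is.null(x$shear_rate)) x$shear_rate <- scale_keep(x$shear_rate)
    if (!is.null(x$tau)) x$tau <- scale_keep(x$tau)
  } else if (inherits(x, "em_solution")) {
    x$V <- x$V * factor
    x$E <- lapply(x$E, `*`, factor)
    x$E_mag <- scale_keep(x$E_mag)
    x$J_mag <- scale_keep(x$J_mag)
    x$I_active <- x$I_active * factor
    x$I_ground <- x$I_ground * factor
  } else if (inherits(x, "roi_histogram")) {
    x$edges <- x$edges * factor
    x$values <- x$values * factor
    x$mean <- x$mean * factor
    x$max <- x$max * factor
  } else {
    stop("cannot rescale object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  x
}
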