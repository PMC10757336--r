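#' Labeled voxel grid
#'
#' The shared discretization for the flow and electric-field solvers: a
#' regular isotropic 3D grid in which every cell carries a material label.
#' Cell `(i, j, k)` (1-based in R) occupies the half-open box
#' `[origin + (i-1)*h, origin + i*h)` per axis, with `h = spacing` in
#' metres.
#'
#' @param labels 3D array of material labels. Either a character array or an
#'   integer array paired with `label_table`.
#' @param spacing Cell edge length in metres (isotropic).
#' @param origin Length-3 numeric, position (m) of the lower corner of cell
#'   (1,1,1).
#' @param label_table Character vector mapping integer codes to labels when
#'   `labels` is integer; `labels[i,j,k] == n` means material
#'   `label_table[n]`. Code 0 is reserved for "outside" (excluded from all
#'   physics).
#' @return An object of class `voxel_grid` with fields `labels` (integer
#'   array), `label_table`, `spacing`, `origin`, `shape`.
#' @export
voxel_grid <- function(labels, spacing, origin = c(0, 0, 0),
                       label_table = NULL) {
  stopifnot(length(dim(labels)) == 3L, spacing > 0, length(origin) == 3L)
  if (is.character(labels)) {
    label_table <- sort(unique(as.vector(labels)))
    codes <- array(match(labels, label_table), dim = dim(labels))
  } else {
    stopifnot(!is.null(label_table))
    codes <- labels
    storage.mode(codes) <- "integer"
    bad <- codes < 0L | codes > length(label_table)
    if (any(bad)) stop("label codes out of range of label_table", call. = FALSE)
  }
  structure(
    list(labels = codes, label_table = label_table,
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         shape = dim(codes)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d, h = %g um>\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing * 1e6))
  tab <- table(factor(x$labels, levels = 0:length(x$label_table),
                      labels = c("(outside)", x$label_table)))
  tab <- tab[tab > 0]
  for (nm in names(tab)) cat(sprintf("  %-12s %d cells\n", nm, tab[[nm]]))
  invisible(x)
}

#' Cell-centre coordinates along each axis
#'
#' @param grid A [voxel_grid()].
#' @return List with numeric vectors `x`, `y`, `z` of cell-centre
#'   coordinates (m).
#' @export
grid_axes <- function(grid) {
  h <- grid$spacing
  o <- grid$origin
  n <- grid$shape
  list(x = o[1] + (seq_len(n[1]) - 0.5) * h,
       y = o[2] + (seq_len(n[2]) - 0.5) * h,
       z = o[3] + (seq_len(n[3]) - 0.5) * h)
}

#' Logical mask of cells carrying a given label
#'
#' @param grid A [voxel_grid()].
#' @param label Material label (character) or vector of labels.
#' @return Logical 3D array.
#' @export
label_mask <- function(grid, label) {
  codes <- match(label, grid$label_table)
  if (anyNA(codes)) {
    stop(sprintf("label(s) not present in grid: %s",
                 paste(label[is.na(codes)], collapse = ", ")), call. = FALSE)
  }
  array(grid$labels %in% codes, dim = grid$shape)
}

#' Volume fraction of a label within the grid (outside cells excluded)
#' @param grid A [voxel_grid()].
#' @param label Material label.
#' @return Fraction in [0, 1] of non-outside cells carrying `label`.
#' @export
label_fraction <- function(grid, label) {
  inside <- grid$labels != 0L
  sum(label_mask(grid, label) & inside) / sum(inside)
}

#' Resample a grid's labels onto a new resolution
#'
#' Nearest-neighbour label lookup at the new cell centres. Used when a
#' scaffold voxelized at fine resolution is embedded into a coarser chamber
#' grid.
#'
#' @param grid A [voxel_grid()].
#' @param spacing New spacing (m).
#' @return A [voxel_grid()] covering the same box at the new spacing.
#' @export
resample_grid <- function(grid, spacing) {
  ext <- grid$shape * grid$spacing
  n2 <- pmax(1L, as.integer(round(ext / spacing)))
  ax <- list(grid$origin[1] + (seq_len(n2[1]) - 0.5) * spacing,
             grid$origin[2] + (seq_len(n2[2]) - 0.5) * spacing,
             grid$origin[3] + (seq_len(n2[3]) - 0.5) * spacing)
  idx <- lapply(1:3, function(d) {
    i <- floor((ax[[d]] - grid$origin[d]) / grid$spacing) + 1
    pmin(pmax(as.integer(i), 1L), grid$shape[d])
  })
  lab2 <- grid$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  voxel_grid(array(lab2, dim = n2), spacing, grid$origin, grid$label_table)
}
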