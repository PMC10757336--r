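#' Write cell fields to a legacy VTK image-data file
#'
#' ASCII `STRUCTURED_POINTS` with `CELL_DATA` scalars, readable by
#' standard VTK viewers. Grid spacing and origin are preserved exactly;
#' units are recorded in the header comment line.
#'
#' @param fields Named list of cell arrays (numeric; complex arrays are
#'   written as magnitude). All must match `grid$shape`.
#' @param grid A [voxel_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fields, grid, path) {
  stopifnot(is.list(fields), length(fields) >= 1, !is.null(names(fields)))
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!all(dim(f) == grid$shape)) {
      stop(sprintf("field '%s' does not match the grid shape", nm), call. = FALSE)
    }
  }
  units <- vapply(fields, function(f) {
    u <- attr(f, "units")
    if (is.null(u)) "1" else u
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  n <- grid$shape
  writeLines(c(
    "# vtk DataFile Version 3.0",
    paste0("perfustim fields; units: ",
           paste(sprintf("%s[%s]", names(fields), units), collapse = " ")),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    # point dims = cell dims + 1 so the scalars below attach to cells
    sprintf("DIMENSIONS %d %d %d", n[1] + 1L, n[2] + 1L, n[3] + 1L),
    sprintf("ORIGIN %.17g %.17g %.17g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("SPACING %.17g %.17g %.17g", grid$spacing, grid$spacing, grid$spacing),
    sprintf("CELL_DATA %d", prod(n))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.complex(f)) f <- Mod(f)
    v <- as.vector(f)
    v[is.na(v)] <- 0
    writeLines(c(sprintf("SCALARS %s double 1", gsub("[^A-Za-z0-9_]", "_", nm)),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", v), con)
  }
  invisible(path)
}

#' Read back a VTK file written by [write_vtk()]
#'
#' @param path File path.
#' @return List with `fields` (named list of arrays), `spacing`, `origin`,
#'   `shape`.
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", ln[grep("^DIMENSIONS", ln)])), " +")[[1]])
  shape <- dims - 1L
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "", ln[grep("^ORIGIN", ln)])), " +")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "", ln[grep("^SPACING", ln)])), " +")[[1]])[1]
  ncell <- prod(shape)
  starts <- grep("^SCALARS", ln)
  fields <- list()
  for (s in starts) {
    nm <- strsplit(ln[s], " +")[[1]][2]
    v <- as.numeric(ln[(s + 2):(s + 1 + ncell)])
    fields[[nm]] <- array(v, dim = shape)
  }
  list(fields = fields, spacing = spacing, origin = origin, shape = shape)
}

#' Export a label's voxel surface as ASCII STL
#'
#' Emits two triangles for every exposed face of the labeled voxel set
#' (faces shared with cells of a different label). Units are metres.
#'
#' @param grid A [voxel_grid()].
#' @param label Material label to surface.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(grid, label, path) {
  mask <- label_mask(grid, label)
  n <- grid$shape
  h <- grid$spacing
  o <- grid$origin
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", label), con)
  pad <- function(m, d, by) {
    # neighbour occupancy shifted along d; FALSE beyond the box
    out <- array(FALSE, dim = n)
    src <- dst <- lapply(n, seq_len)
    if (by > 0) { dst[[d]] <- 2:n[d]; src[[d]] <- 1:(n[d] - 1) }
    else { dst[[d]] <- 1:(n[d] - 1); src[[d]] <- 2:n[d] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  emit <- function(v1, v2, v3, nrm) {
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", v1[1], v1[2], v1[3]),
                 sprintf("      vertex %.9g %.9g %.9g", v2[1], v2[2], v2[3]),
                 sprintf("      vertex %.9g %.9g %.9g", v3[1], v3[2], v3[3]),
                 "    endloop", "  endfacet"), con)
  }
  for (d in 1:3) {
    for (s in c(-1, 1)) {
      exposed <- mask & !pad(mask, d, -s)
      idx <- which(exposed, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, ] - 1L
        lo <- o + i * h
        hi <- lo + h
        fc <- lo
        fc[d] <- if (s > 0) hi[d] else lo[d]
        a <- setdiff(1:3, d)
        p1 <- fc; p2 <- fc; p3 <- fc; p4 <- fc
        p2[a[1]] <- hi[a[1]]
        p3[a[1]] <- hi[a[1]]; p3[a[2]] <- hi[a[2]]
        p4[a[2]] <- hi[a[2]]
        nrm <- c(0, 0, 0); nrm[d] <- s
        if (s > 0) { emit(p1, p2, p3, nrm); emit(p1, p3, p4, nrm) }
        else { emit(p1, p3, p2, nrm); emit(p1, p4, p3, nrm) }
      }
    }
  }
  writeLines("endsolid", con)
  invisible(path)
}

#' Write a design report as JSON plus CSV histograms
#'
#' Produces everything needed to regenerate the dose-distribution figures:
#' one JSON summary and, per hypothesis, CSV histograms
#' `<id>_tau.csv` and `<id>_E.csv` with columns
#' `bin_lo, bin_hi, volume, normalized`.
#'
#' @param report A `design_report` from [run_design_loop()].
#' @param dir Output directory (created if needed).
#' @return Path of the JSON file, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "design_report"))
  required <- c("id", "tau_hist", "E_hist", "shear_fraction", "E_mean")
  for (r in report$results) {
    missing <- required[!required %in% names(r)]
    if (length(missing)) {
      stop("incomplete report entry '", r$id, "': missing ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in report$results) {
    for (fh in c("tau", "E")) {
      hs <- if (fh == "tau") r$tau_hist else r$E_hist
      write_histogram_csv(hs, file.path(dir, sprintf("%s_%s.csv", r$id, fh)))
    }
  }
  summary <- list(
    selected = report$selected,
    rationale = report$rationale,
    hypotheses = lapply(unname(report$results), function(r) list(
      id = r$id,
      shear_fraction = r$shear_fraction, shear_q = r$shear_q,
      shear_pass = r$shear_pass, field_fraction = r$field_fraction,
      tau_mean_Pa = r$tau_mean, tau_max_Pa = r$tau_hist$max,
      E_mean_V_per_m = r$E_mean, E_max_V_per_m = r$E_hist$max,
      roi_fluid_volume_m3 = r$tau_hist$roi_volume)),
    errors = report$errors)
  path <- file.path(dir, "design_report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Write / read a histogram CSV
#'
#' @param hist A [roi_histogram()].
#' @param path CSV path.
#' @return `read_histogram_csv` returns a data frame with
#'   `bin_lo, bin_hi, volume, normalized`.
#' @export
write_histogram_csv <- function(hist, path) {
  nb <- length(hist$volume)
  df <- data.frame(bin_lo = hist$edges[seq_len(nb)],
                   bin_hi = hist$edges[seq_len(nb) + 1L],
                   volume = hist$volume, normalized = hist$normalized)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  utils::read.csv(path)
}

#' Run configuration
#'
#' A serializable bundle of everything a run depends on: geometry
#' parameters, protocol, solver settings and the RNG seed, so that a saved
#' config reproduces a run bit-identically for the deterministic stages.
#' Lengths may be given with explicit unit suffixes (`"10mm"`, `"500um"`,
#' `"0.01m"`); all values are stored in SI.
#'
#' @param ... Named configuration entries.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  structure(list(...), class = "run_config")
}

#' Parse a length with unit suffix to metres
#' @param x Numeric (already metres) or string like `"500um"`, `"10mm"`,
#'   `"0.02m"`.
#' @return Length in metres.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([-0-9.eE+]+)\\s*(um|mm|cm|m)\\s*$", x))[[1]]
  if (length(m) != 3) stop("cannot parse length: ", x, call. = FALSE)
  as.numeric(m[2]) * c(um = 1e-6, mm = 1e-3, cm = 1e-2, m = 1)[[m[3]]]
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}
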