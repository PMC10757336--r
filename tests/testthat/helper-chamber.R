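# Chamber solves are the expensive part of the acceptance checks and are
# shared by several of them; memoize per (scaffold, holder, physics,
# spacing) within the test session. Only the ROI histogram is kept — the
# full field solutions would hold gigabytes across the session.
.chamber_cache <- new.env(parent = emptyenv())

cached_chamber_em <- function(kind, holder, spacing, tol = 1e-5) {
  key <- sprintf("em_%s_%s_%g", kind, holder, spacing)
  if (!exists(key, .chamber_cache)) {
    asm <- assemble_chamber(scaffold_spec(kind), holder,
                            electrodes = electrode_assembly(gap = 22e-3),
                            spacing = spacing)
    sol <- solve_em(asm, em_bc(V_amp = 5, f = 60e3), tol = tol)
    hist <- roi_histogram(sol$E_mag, extract_roi(asm), asm)
    rm(sol, asm)
    gc(verbose = FALSE)
    assign(key, list(hist = hist), .chamber_cache)
  }
  get(key, .chamber_cache)
}

cached_chamber_flow <- function(kind, holder, spacing, tol = 1e-4) {
  key <- sprintf("flow_%s_%s_%g", kind, holder, spacing)
  if (!exists(key, .chamber_cache)) {
    asm <- assemble_chamber(scaffold_spec(kind), holder, electrodes = NULL,
                            spacing = spacing)
    sol <- solve_flow(asm, chamber_flow_bc(asm, 0.120), tol = tol)
    sol <- shear_stress(sol)
    hist <- roi_histogram(sol$tau, extract_roi(asm), asm)
    rm(sol, asm)
    gc(verbose = FALSE)
    assign(key, list(hist = hist), .chamber_cache)
  }
  get(key, .chamber_cache)
}

# volume-weighted interdecile range of an roi_histogram
hist_idr <- function(hist) {
  q <- stats::quantile(hist$values, c(0.1, 0.9), names = FALSE)
  q[2] - q[1]
}
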