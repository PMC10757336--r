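#' Mean velocity from volumetric flow rate
#'
#' The flow-budget identity `v = Q / A`. With the maximum pump rate of
#' 50 mL/min through the 0.0254 cm^2 peristaltic hose connector this gives
#' the 0.328 m/s outlet velocity used as the channel-network boundary
#' condition.
#'
#' @param Q Volumetric flow rate, m^3/s (>= 0).
#' @param A Cross-section area, m^2 (> 0).
#' @return Mean velocity, m/s.
#' @export
velocity_from_flow <- function(Q, A) {
  if (any(A <= 0)) stop("cross-section area must be > 0", call. = FALSE)
  if (any(Q < 0)) stop("flow rate must be >= 0", call. = FALSE)
  Q / A
}

#' Outlet channel network specification
#'
#' A rooted tree of channel branches. The root is the peristaltic hose
#' connector; leaves are the scaffold holder connectors. The manifold
#' design rule requires that at every split the child cross-section areas
#' sum to the parent area, which preserves mean velocity across splits and
#' divides the outlet flow equally among the supported scaffolds (for a
#' symmetric tree).
#'
#' @param branches Data frame with columns `id`, `parent` (`NA` for the
#'   root), `length` (m) and `area` (m^2).
#' @return An object of class `channel_network`.
#' @export
channel_network <- function(branches) {
  stopifnot(is.data.frame(branches),
            all(c("id", "parent", "length", "area") %in% names(branches)))
  if (sum(is.na(branches$parent)) != 1L) stop("network needs exactly one root", call. = FALSE)
  if (any(branches$area < 0) || any(branches$length <= 0)) {
    stop("branch lengths must be > 0 and areas >= 0", call. = FALSE)
  }
  structure(list(branches = branches), class = "channel_network")
}

#' Default symmetric manifold for four scaffold holders
#'
#' Root area 2.54e-6 m^2 (0.0254 cm^2 hose connector), splitting 1 -> 2 -> 4
#' with the area-conservation rule at both levels, so each leaf has a
#' quarter of the root area and carries mean velocity equal to the root's.
#'
#' @param root_area Root cross-section, m^2.
#' @param branch_length Length of every branch, m.
#' @return A [channel_network()].
#' @export
default_manifold <- function(root_area = 2.54e-6, branch_length = 30e-3) {
  b <- data.frame(
    id = c("root", "L", "R", "L1", "L2", "R1", "R2"),
    parent = c(NA, "root", "root", "L", "L", "R", "R"),
    length = branch_length,
    area = root_area * c(1, 1 / 2, 1 / 2, 1 / 4, 1 / 4, 1 / 4, 1 / 4)
  )
  channel_network(b)
}

#' Check the area-conservation design rule
#'
#' At every split the child areas must sum to the parent area (relative
#' tolerance 1e-12).
#'
#' @param net A [channel_network()].
#' @return List with `ok` (logical) and `violations` (data frame of parent
#'   id, parent area and child-area sum for each offending split).
#' @export
check_area_rule <- function(net, tol = 1e-12) {
  b <- net$branches
  parents <- unique(stats::na.omit(b$parent))
  viol <- list()
  for (p in parents) {
    kids <- b$area[!is.na(b$parent) & b$parent == p]
    pa <- b$area[b$id == p]
    if (abs(sum(kids) - pa) > tol * max(pa, .Machine$double.xmin)) {
      viol[[length(viol) + 1L]] <- data.frame(parent = p, parent_area = pa,
                                              child_sum = sum(kids))
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(parent = character(), parent_area = numeric(), child_sum = numeric())
  list(ok = nrow(viol) == 0L, violations = viol)
}

#' Solve the lumped laminar flow split of a channel network
#'
#' Poiseuille-type lumped resistances (`R = 8 * pi * mu * L / A^2`, the
#' Hagen-Poiseuille law for a circular section written in terms of area;
#' non-circular sections use the same equivalent-area form) drive a linear
#' Kirchhoff network: flow `Q_root` is injected at the root and all leaves
#' discharge at a common reference pressure. Per-branch flows satisfy flow
#' conservation at every internal node. Networks violating the
#' area-conservation rule (for instance with a blocked leaf) are solved
#' with a warning; blocked branches carry zero flow and the rest
#' re-equilibrate.
#'
#' @param net A [channel_network()].
#' @param Q_root Injected flow rate at the root, m^3/s.
#' @param mu Dynamic viscosity, Pa s.
#' @param connector_area Optional holder-connector cross-section (m^2) used
#'   to report the leaf connector velocity; defaults to each leaf's own
#'   branch area. The physical holder connector is wider than the manifold
#'   leaf; its default in [assemble_chamber()] is calibrated so the
#'   connector velocity is 0.120 m/s at a quarter of 50 mL/min.
#' @return List with `branches` (data frame: id, Q, velocity), `leaves`
#'   (leaf subset with `connector_velocity`), `Q_root`.
#' @export
solve_split <- function(net, Q_root, mu = 6.89e-4, connector_area = NULL) {
  rule <- check_area_rule(net)
  if (!rule$ok) {
    # a violating network (e.g. a blocked leaf) is still solvable; the
    # design rule is a velocity-preservation property, not a solvability
    # requirement
    warning(paste0("area-conservation rule violated at split(s): ",
                   paste(rule$violations$parent, collapse = ", ")),
            call. = FALSE)
  }
  b <- net$branches
  nb <- nrow(b)
  root_id <- b$id[is.na(b$parent)]
  leaf_ids <- setdiff(b$id, b$parent)
  blocked <- b$area <= 0
  # node potentials: one node at the downstream end of every branch, plus the
  # source node upstream of the root; leaves grounded at p = 0.
  nodes <- b$id
  R <- ifelse(blocked, Inf, 8 * pi * mu * b$length / b$area^2)
  g <- ifelse(is.finite(R), 1 / R, 0)
  nn <- length(nodes)
  A <- matrix(0, nn, nn)
  rhs <- numeric(nn)
  for (i in seq_len(nb)) {
    di <- match(b$id[i], nodes)
    if (is.na(b$parent[i])) {
      # conductance from the source into the root's downstream node; the
      # injected flow enters that node directly
      rhs[di] <- rhs[di] + Q_root
    } else {
      ui <- match(b$parent[i], nodes)
      A[di, di] <- A[di, di] + g[i]
      A[ui, ui] <- A[ui, ui] + g[i]
      A[di, ui] <- A[di, ui] - g[i]
      A[ui, di] <- A[ui, di] - g[i]
    }
  }
  leaf_idx <- match(leaf_ids, nodes)
  # ground the leaves (Dirichlet p = 0)
  for (li in leaf_idx) {
    A[li, ] <- 0
    A[li, li] <- 1
    rhs[li] <- 0
  }
  # drop unreachable nodes (all-blocked subtrees) to keep the system regular
  diag_zero <- which(diag(A) == 0)
  for (dz in diag_zero) A[dz, dz] <- 1
  p <- tryCatch(solve(A, rhs), error = function(e) {
    stop("insufficient specification: network not solvable (", conditionMessage(e), ")",
         call. = FALSE)
  })
  Qb <- numeric(nb)
  for (i in seq_len(nb)) {
    if (is.na(b$parent[i])) {
      Qb[i] <- Q_root
    } else {
      ui <- match(b$parent[i], nodes)
      di <- match(b$id[i], nodes)
      Qb[i] <- g[i] * (p[ui] - p[di])
    }
  }
  # branch flows below a blocked branch are zero by construction (g = 0)
  v <- ifelse(b$area > 0, Qb / b$area, 0)
  out <- data.frame(id = b$id, Q = Qb, velocity = v)
  leaves <- out[out$id %in% leaf_ids, ]
  if (!is.null(connector_area)) {
    leaves$connector_velocity <- leaves$Q / connector_area
  } else {
    leaves$connector_velocity <- leaves$velocity
  }
  list(branches = out, leaves = leaves, Q_root = Q_root)
}
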