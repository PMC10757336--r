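test_that("flow budget arithmetic reproduces the outlet velocity", {
  # 50 mL/min through the 0.0254 cm^2 hose connector
  v <- velocity_from_flow(50e-6 / 60, 0.0254e-4)
  expect_equal(v, 0.328, tolerance = 0.5e-3 / 0.328)
  expect_equal(velocity_from_flow(0, 1e-6), 0)
  # velocity is preserved under the area-conservation rule
  expect_equal(velocity_from_flow(12.5e-6 / 60, 0.0254e-4 / 4), v)
  expect_error(velocity_from_flow(1e-6, 0), "> 0")
  expect_error(velocity_from_flow(-1, 1e-6), ">= 0")
})

test_that("default manifold passes the area rule and splits flow equally", {
  net <- default_manifold()
  expect_true(check_area_rule(net)$ok)
  Q <- 50e-6 / 60
  res <- solve_split(net, Q)
  expect_equal(nrow(res$leaves), 4L)
  expect_equal(res$leaves$Q, rep(Q / 4, 4))
  # leaf flows sum to the injected flow to machine precision
  expect_equal(sum(res$leaves$Q), Q, tolerance = 1e-12)
  # area rule preserves mean velocity at every branch
  expect_equal(res$branches$velocity, rep(Q / 2.54e-6, 7))
  # calibrated holder connector area gives the 0.120 m/s feed velocity
  conn <- solve_split(net, Q, connector_area = (Q / 4) / 0.120)
  expect_equal(conn$leaves$connector_velocity, rep(0.120, 4))
})

test_that("rule-violating networks are reported with the offending split", {
  b <- data.frame(id = c("root", "a", "b"), parent = c(NA, "root", "root"),
                  length = 0.03, area = c(2.54e-6, 1e-6, 1e-6))
  net <- channel_network(b)
  chk <- check_area_rule(net)
  expect_false(chk$ok)
  expect_identical(chk$violations$parent, "root")
  expect_warning(solve_split(net, 1e-6), "root")
})

test_that("a blocked leaf re-equilibrates the remaining flows", {
  net <- default_manifold()
  net$branches$area[net$branches$id == "L1"] <- 0
  Q <- 50e-6 / 60
  expect_warning(res <- solve_split(net, Q), "area-conservation")
  lv <- res$leaves
  expect_equal(lv$Q[lv$id == "L1"], 0)
  expect_equal(sum(lv$Q), Q, tolerance = 1e-12)
  # brute-force series/parallel reduction of the reduced network:
  # conductances g = A^2 / (8 pi mu L); branch L and R have area A/2,
  # leaves A/4
  cfac <- 8 * pi * 6.89e-4 * 0.03
  ghalf <- (2.54e-6 / 2)^2 / cfac
  gleaf <- (2.54e-6 / 4)^2 / cfac
  gLser <- 1 / (1 / ghalf + 1 / gleaf)       # L -> single live leaf
  gRser <- 1 / (1 / ghalf + 1 / (2 * gleaf)) # R -> two leaves in parallel
  QL_expect <- Q * gLser / (gLser + gRser)
  expect_equal(lv$Q[lv$id == "L2"], QL_expect, tolerance = 1e-10)
  expect_equal(lv$Q[lv$id == "R1"], (Q - QL_expect) / 2, tolerance = 1e-10)
})

test_that("lumped split matches the Stokes solver on a two-branch network", {
  # two parallel square channels of different areas between common
  # plenums; the lumped model predicts Q1/Q2 = (A1/A2)^2 (R ~ L/A^2),
  # and for geometrically similar sections the exact viscous resistance
  # has the same area scaling, so the split ratio is comparable even
  # though absolute resistances carry an equivalent-diameter error
  h <- 1e-4
  n1 <- 12L  # channel 1 width (cells)
  n2 <- 8L   # channel 2 width (cells)
  len <- 60L
  plen <- 10L
  ny <- n1 + n2 + 9L
  nz <- max(n1, n2) + 6L
  lab <- array("medium", dim = c(2L * plen + len, ny, nz))
  # solid block between the plenums, with two square channels carved
  lab[(plen + 1):(plen + len), , ] <- "PCL"
  lab[(plen + 1):(plen + len), 4:(3 + n1), 4:(3 + n1)] <- "medium"
  lab[(plen + 1):(plen + len), (7 + n1):(6 + n1 + n2), 4:(3 + n2)] <- "medium"
  g <- voxel_grid(lab, h)
  bc <- flow_bc(sides = list(xmin = "pressure", xmax = "velocity"),
                velocity_sides = list(xmax = 1e-3), default_side = "wall",
                open_label0 = FALSE)
  sol <- solve_flow(g, bc, tol = 1e-8)
  mid <- plen + len %/% 2
  sl <- sol$vel$x[mid, , ]
  Q1 <- sum(sl[4:(3 + n1), 4:(3 + n1)]) * h^2
  Q2 <- sum(sl[(7 + n1):(6 + n1 + n2), 4:(3 + n2)]) * h^2
  lumped <- solve_split(channel_network(data.frame(
    id = c("root", "b1", "b2"), parent = c(NA, "root", "root"),
    length = len * h, area = c((n1 * h)^2 + (n2 * h)^2, (n1 * h)^2, (n2 * h)^2))),
    Q_root = Q1 + Q2)
  ratio_lumped <- lumped$leaves$Q[lumped$leaves$id == "b1"] /
    lumped$leaves$Q[lumped$leaves$id == "b2"]
  expect_equal(Q1 / Q2, ratio_lumped, tolerance = 0.15)
})

test_that("asymmetric networks without usable lengths are refused", {
  b <- data.frame(id = c("root", "a", "b"), parent = c(NA, "root", "root"),
                  length = c(0.03, NA, 0.03), area = c(2e-6, 1e-6, 1e-6))
  expect_error(channel_network(b))
})
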