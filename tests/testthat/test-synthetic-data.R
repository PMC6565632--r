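test_that("womersley shear painted on a tube drives the indicator limits", {
  tube <- make_tube(16, 100, 6, 8)
  steady <- womersley_case(0.016, 0.8, 2)
  s1 <- womersley_wss_on_tube(tube, steady, n_samples = 16)
  idx1 <- compute_wss_indices(tube, s1)
  expect_true(all(idx1$osi == 0))
  expect_true(all(abs(idx1$tawss - 2 * 0.016 / 2) < 1e-12))
  # zero-mean single harmonic: purely oscillatory shear everywhere
  osc <- womersley_case(0.016, 0.8, c(0, 2))
  s2 <- womersley_wss_on_tube(tube, osc, n_samples = 64)
  idx2 <- compute_wss_indices(tube, s2)
  expect_true(all(abs(idx2$osi - 0.5) < 1e-6))
  # exact tangency without projection
  expect_lt(max(abs(s2$wss[, , 1]), abs(s2$wss[, , 2])), 1e-15)
})

test_that("prescribed-OSI fields round-trip their targets exactly", {
  tube <- make_tube(16, 60, 5, 20) # 100 nodes
  set.seed(5)
  targets <- runif(nrow(tube$nodes), 0, 0.5)
  series <- prescribed_osi_field(tube, targets, scale = 2, seed = 8)
  idx <- compute_wss_indices(tube, series)
  expect_lt(max(abs(idx$osi - targets)), 1e-12)
  expect_lt(max(abs(idx$tawss - 2)), 1e-12)
  # boundary targets
  s0 <- prescribed_osi_field(tube, 0, scale = 1.5)
  expect_lt(max(compute_wss_indices(tube, s0)$osi), 1e-12)
  s5 <- prescribed_osi_field(tube, 0.5, scale = 1.5)
  expect_lt(max(abs(compute_wss_indices(tube, s5)$osi - 0.5)), 1e-15)
  expect_error(prescribed_osi_field(tube, 0.6), "\\[0, 0.5\\]")
})

test_that("jet impingement produces a connected high zone that washes as told", {
  tube <- make_tube(16, 100, 20, 28)
  series <- jet_impingement_field(tube, z0 = 50, theta0 = 0, strength = 15,
                                  spread = 8, mode = "circumferential")
  idx <- compute_wss_indices(tube, series, axial = c(0, 0, 1))
  high <- which(idx$zone == "high")
  expect_gt(length(high), 3)
  # high zone is connected on the mesh graph
  tri <- tube$triangles
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  keep <- edges[, 1] %in% high & edges[, 2] %in% high
  g <- igraph::graph_from_edgelist(
    matrix(match(edges[keep, ], high), ncol = 2), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  # impingement ring nodes (same axial station, off the point) wash
  # circumferentially
  ring <- which(abs(tube$nodes[, 3] - 50) < 1e-9 &
                  abs(atan2(tube$nodes[, 2], tube$nodes[, 1])) > 0.3 &
                  idx$valid)
  expect_true(all(idx$washing[ring] == "circumferential"))
  # zero strength: all-zero field, OSI invalid everywhere
  s0 <- jet_impingement_field(tube, z0 = 50, strength = 0)
  idx0 <- compute_wss_indices(tube, s0)
  expect_true(all(!idx0$valid))
  expect_error(jet_impingement_field(tube, z0 = 150), "off the tube")
})

test_that("branched tubes realize and recover the requested angles", {
  ca <- iaa_collateral_geometry()
  for (i in seq_len(nrow(ca))) {
    bt <- make_branched_tube(alpha_deg = ca$alpha_deg[i],
                             beta_deg = ca$beta_deg[i])
    ang <- branch_angles(bt$geometry)
    expect_lt(abs(ang$alpha_deg - ca$alpha_deg[i]), 1e-9)
    expect_lt(abs(ang$beta_deg - ca$beta_deg[i]), 1e-9)
  }
  # alpha = 90: branch along the wall normal
  bt90 <- make_branched_tube(alpha_deg = 90, beta_deg = 90)
  expect_lt(max(abs(bt90$geometry$branch_axis - c(1, 0, 0))), 1e-12)
  expect_error(make_branched_tube(alpha_deg = 30, beta_deg = 0), "\\(0, 90\\]")
  # mesh-based re-estimation within 1 degree: branch axis from the stub
  # ring centroids, wall normal from recomputed normals near the point
  bt <- make_branched_tube(alpha_deg = 58.57, beta_deg = 39.80,
                           n_branch_axial = 10, n_branch_circ = 24)
  stub <- bt$mesh$nodes[bt$branch_nodes, ]
  pc <- stats::prcomp(stub)
  axis_est <- pc$rotation[, 1]
  if (sum(axis_est * bt$geometry$branch_axis) < 0) axis_est <- -axis_est
  nrm <- compute_node_normals(bt$mesh$nodes, bt$mesh$triangles)
  k <- which.min(colSums((t(bt$mesh$nodes[-bt$branch_nodes, ]) -
                            bt$geometry$point)^2))
  bg_est <- branch_geometry(axis_est, nrm[k, ], bt$geometry$main_axis,
                            bt$geometry$point)
  ang_est <- branch_angles(bg_est)
  expect_lt(abs(ang_est$alpha_deg - 58.57), 1)
  expect_lt(abs(ang_est$beta_deg - 39.80), 1)
})

test_that("generators are bit-reproducible for a fixed seed", {
  tube <- make_tube(16, 60, 6, 10)
  a <- random_wss_series(tube, seed = 42)
  b <- random_wss_series(tube, seed = 42)
  expect_identical(a$wss, b$wss)
  c_ <- random_wss_series(tube, seed = 43)
  expect_false(identical(a$wss, c_$wss))
  sc1 <- generate_scenario("prescribed_osi", seed = 7)
  sc2 <- generate_scenario("prescribed_osi", seed = 7)
  expect_identical(sc1$series$wss, sc2$series$wss)
  # every generated series passes tangency without projection
  for (nm in c("womersley_tube", "jet_axial", "prescribed_osi")) {
    sc <- generate_scenario(nm, seed = 3, n_axial = 6, n_circ = 8,
                            n_samples = 8)
    for (j in seq_along(sc$series$times)) {
      expect_lt(max(abs(rowSums(sc$series$wss[, j, ] * sc$mesh$normals))),
                1e-9)
    }
  }
})
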