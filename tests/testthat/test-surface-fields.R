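test_that("generated tube meshes satisfy the surface invariants", {
  tube <- make_tube(16, 100, 12, 16)
  expect_equal(nrow(tube$nodes), 12 * 16)
  expect_equal(nrow(tube$triangles), 2 * 11 * 16)
  # normals exactly radial
  radial <- cbind(tube$nodes[, 1], tube$nodes[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_lt(max(abs(rowSums(tube$normals * radial) - 1)), 1e-12)
  # open cylinder: V - E + F = 0
  tri <- tube$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  n_edges <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  expect_equal(nrow(tube$nodes) - n_edges + nrow(tri), 0)
})

test_that("mesh validation rejects bad connectivity and bad normals", {
  tube <- make_tube(5, 20, 6, 8)
  bad_tri <- tube$triangles
  bad_tri[1, 1] <- nrow(tube$nodes) + 5L
  expect_error(surface_mesh(tube$nodes, bad_tri, tube$normals),
               "non-existent node")
  bad_n <- tube$normals
  bad_n[3, ] <- bad_n[3, ] * 2
  expect_error(surface_mesh(tube$nodes, tube$triangles, bad_n),
               "unit length")
  flipped <- tube$triangles
  flipped[1, ] <- flipped[1, c(1, 3, 2)]
  expect_error(surface_mesh(tube$nodes, flipped, tube$normals),
               "orientation")
})

test_that("area-weighted normal recomputation is radial on a cylinder", {
  tube <- make_tube(16, 100, 14, 24)
  rec <- compute_node_normals(tube$nodes, tube$triangles)
  interior <- tube$nodes[, 3] > 0 & tube$nodes[, 3] < 100
  dev <- abs(rowSums(rec * tube$normals) - 1)
  expect_lt(max(dev[interior]), 1e-6)
})

test_that("tangency projection removes normal components", {
  tube <- make_tube(8, 40, 8, 12)
  set.seed(42)
  n <- nrow(tube$nodes)
  w <- array(rnorm(n * 5 * 3), c(n, 5, 3))
  times <- seq(0, 0.8, length.out = 6)[-6]
  series <- wss_series(times, w, 0.8)
  proj <- project_to_tangent(series, tube)
  for (j in 1:5) {
    expect_lt(max(abs(rowSums(proj$wss[, j, ] * tube$normals))), 1e-12)
  }
  # pure-normal vectors project to zero, tangent vectors are untouched
  w2 <- array(0, c(n, 2, 3))
  w2[, 1, ] <- tube$normals
  tang <- cbind(0, 0, rep(1.5, n))
  w2[, 2, ] <- tang
  p2 <- project_to_tangent(wss_series(c(0, 0.4), w2, 0.8), tube)
  expect_lt(max(abs(p2$wss[, 1, ])), 1e-12)
  expect_lt(max(abs(p2$wss[, 2, ] - tang)), 1e-12)
})

test_that("archive round-trip preserves arrays to full precision", {
  tube <- make_tube(16, 100, 8, 12)
  series <- random_wss_series(tube, n_samples = 7, seed = 9)
  dir <- withr::local_tempdir()
  write_surface_series(tube, series, dir)
  back <- read_surface_series(dir, project = FALSE)
  expect_identical(back$mesh$nodes, unname(tube$nodes))
  expect_identical(back$mesh$triangles, unname(tube$triangles))
  expect_identical(back$series$times, series$times)
  expect_identical(back$series$period, series$period)
  expect_identical(back$series$wss, series$wss)
})

test_that("VTK snapshot series load and reject topology mismatches", {
  tube <- make_tube(10, 30, 6, 9)
  small <- make_tube(10, 30, 6, 8)
  dir <- withr::local_tempdir()
  times <- c(0, 0.2, 0.4)
  paths <- file.path(dir, sprintf("snap%d.vtk", 1:3))
  for (i in 1:3) {
    vec <- cbind(0, 0, rep(i, nrow(tube$nodes)))
    write_vtk_polydata(tube, paths[i], vectors = vec)
  }
  got <- read_surface_series(paths, period = 0.8, times = times)
  expect_equal(length(got$series$times), 3)
  expect_equal(got$series$wss[1, 2, 3], 2)
  # corrupt snapshot 3 with a different node count
  write_vtk_polydata(small, paths[3],
                     vectors = matrix(0, nrow(small$nodes), 3))
  expect_error(read_surface_series(paths, period = 0.8, times = times),
               "topology mismatch")
})

test_that("probing matches nodes, interpolates linearly, and falls back", {
  tube <- make_tube(16, 100, 10, 16)
  field <- tube$nodes[, 3] + 2 * tube$nodes[, 1] # linear field
  # probe exactly at a node
  k <- 37L
  probes <- tibble::tibble(label = "at_node",
                           x = tube$nodes[k, 1], y = tube$nodes[k, 2],
                           z = tube$nodes[k, 3])
  for (mode in c("nearest_node", "barycentric")) {
    got <- probe_values(field, tube, probes, mode = mode)
    expect_equal(got$value, field[k], tolerance = 1e-12)
  }
  # triangle centroid of a linear field -> mean of the 3 node values
  tri <- tube$triangles[5, ]
  centroid <- colMeans(tube$nodes[tri, ])
  probes2 <- tibble::tibble(label = "centroid", x = centroid[1],
                            y = centroid[2], z = centroid[3])
  got2 <- probe_values(field, tube, probes2, mode = "barycentric")
  expect_equal(got2$value, mean(field[tri]), tolerance = 1e-9)
  # 1 mm off-surface within tolerance: interpolation at the foot point
  # matches the nearest-node value found by brute-force search
  q <- tube$nodes[k, ] + 1 * tube$normals[k, ]
  probes3 <- tibble::tibble(label = "off", x = q[1], y = q[2], z = q[3])
  got3 <- probe_values(field, tube, probes3, mode = "nearest_node")
  brute <- which.min(colSums((t(tube$nodes) - q)^2))
  expect_equal(got3$value, field[brute])
  # far outside the expanded bounding box -> error
  probes4 <- tibble::tibble(label = "lost", x = 500, y = 500, z = 500)
  expect_error(probe_values(field, tube, probes4), "bounding box")
})
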