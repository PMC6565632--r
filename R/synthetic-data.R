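#' Structured triangulated cylinder surface
#'
#' Builds an open tube of the given radius and length along the z axis,
#' triangulated on a structured axial x circumferential grid, with exactly
#' radial outward normals. The tube carries its chart parameters so
#' downstream generators can work in the exact unrolled (axial position,
#' arc length) coordinates.
#'
#' @param radius tube radius (mm).
#' @param length tube length (mm).
#' @param n_axial axial node count (>= 3).
#' @param n_circ circumferential node count (>= 3).
#' @return a [surface_mesh()] with extra class `tube_mesh` and attributes
#'   `radius`, `length`, `n_axial`, `n_circ`.
#' @export
make_tube <- function(radius = 16, length = 100, n_axial = 24, n_circ = 32) {
  if (radius <= 0 || length <= 0) stop("radius and length must be positive")
  if (n_axial < 3 || n_circ < 3) stop("resolutions must be at least 3")
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  z <- seq(0, length, length.out = n_axial)
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  nodes <- cbind(
    radius * rep(cos(theta), times = n_axial),
    radius * rep(sin(theta), times = n_axial),
    rep(z, each = n_circ)
  )
  normals <- cbind(rep(cos(theta), times = n_axial),
                   rep(sin(theta), times = n_axial), 0)
  tris <- matrix(0L, 2L * (n_axial - 1L) * n_circ, 3L)
  r <- 1L
  for (i in seq_len(n_axial - 1L)) {
    for (j in seq_len(n_circ)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      tris[r, ] <- c(a, b, c_); tris[r + 1L, ] <- c(a, c_, d)
      r <- r + 2L
    }
  }
  mesh <- surface_mesh(nodes, tris, normals)
  class(mesh) <- c("tube_mesh", class(mesh))
  attr(mesh, "radius") <- radius
  attr(mesh, "length") <- length
  attr(mesh, "n_axial") <- n_axial
  attr(mesh, "n_circ") <- n_circ
  mesh
}

tube_chart <- function(mesh) {
  if (!inherits(mesh, "tube_mesh")) stop("mesh was not generated by make_tube")
  r <- attr(mesh, "radius")
  list(z = mesh$nodes[, 3],
       theta = atan2(mesh$nodes[, 2], mesh$nodes[, 1]),
       radius = r,
       axial = cbind(0, 0, rep(1, nrow(mesh$nodes))),
       circum = cbind(-mesh$nodes[, 2] / r, mesh$nodes[, 1] / r, 0))
}

#' Exact Womersley wall shear series on a tube surface
#'
#' Paints the analytic wall shear stress of a pulsatile tube-flow case onto
#' every node of a generated tube, directed along (+/-) the tube axis:
#' spatially uniform, exactly tangent, and periodic by construction. This
#' ties the surface-field machinery to a physically exact WSS signal.
#'
#' @param tube a [make_tube()] mesh.
#' @param case a [womersley_case()].
#' @param n_samples time samples per cycle (uniform on `[0, T)`).
#' @param direction `+1` (default) or `-1`: sign of the axial direction.
#' @return a [wss_series()].
#' @export
womersley_wss_on_tube <- function(tube, case, n_samples = 64, direction = 1) {
  if (!inherits(tube, "tube_mesh")) stop("mesh was not generated by make_tube")
  stopifnot(direction %in% c(-1, 1))
  t <- seq(0, case$period, length.out = n_samples + 1L)[seq_len(n_samples)]
  tau <- analytic_wall_shear(case, t)
  n <- nrow(tube$nodes)
  w <- array(0, c(n, n_samples, 3))
  w[, , 3] <- outer(rep(direction, n), tau)
  wss_series(t, w, case$period)
}

#' Two-phase WSS series realizing prescribed OSI targets
#'
#' Inverse-designs a per-node WSS series whose computed OSI equals the
#' requested target exactly and whose TAWSS equals `scale`. Each node
#' carries a two-sample series `+a e` (first half-cycle) and `-b e`
#' (second), with `a = 2 scale (1 - target)` and `b = 2 scale target`;
#' under the period-closing trapezoidal rule this yields
#' `OSI = b / (a + b) = target` and `TAWSS = (a + b) / 2 = scale`
#' identically, for any target in `[0, 0.5]`.
#'
#' @param mesh a [surface_mesh()].
#' @param targets per-node OSI targets in `[0, 0.5]` (recycled if scalar).
#' @param scale TAWSS of every node (Pa, default 1).
#' @param period cycle period (s, default 0.8).
#' @param seed seed for the random tangent directions (default 1).
#' @return a [wss_series()].
#' @export
prescribed_osi_field <- function(mesh, targets, scale = 1, period = 0.8,
                                 seed = 1L) {
  n <- nrow(mesh$nodes)
  targets <- rep_len(targets, n)
  if (any(targets < 0 | targets > 0.5)) stop("OSI targets must lie in [0, 0.5]")
  e <- withr::with_seed(seed, random_tangent_directions(mesh$normals))
  a <- 2 * scale * (1 - targets)
  b <- 2 * scale * targets
  w <- array(0, c(n, 2L, 3L))
  w[, 1, ] <- a * e
  w[, 2, ] <- -b * e
  wss_series(c(0, period / 2), w, period)
}

random_tangent_directions <- function(normals) {
  n <- nrow(normals)
  v <- matrix(stats::rnorm(3L * n), n, 3)
  v <- v - rowSums(v * normals) * normals
  len <- sqrt(rowSums(v^2))
  # regenerate the (measure-zero) degenerate draws
  while (any(len < 1e-12)) {
    bad <- len < 1e-12
    v[bad, ] <- matrix(stats::rnorm(3L * sum(bad)), ncol = 3)
    v[bad, ] <- v[bad, , drop = FALSE] -
      rowSums(v[bad, , drop = FALSE] * normals[bad, , drop = FALSE]) *
      normals[bad, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
  }
  v / len
}

#' Pulsatile jet-impingement WSS pattern on a tube
#'
#' Phenomenological emulation of a collateral jet striking the wall of a
#' larger vessel: WSS magnitude decays as a Gaussian of the unrolled
#' (axial, arc-length) distance from the impingement point, the direction
#' radiates away from the point and is then biased axially or
#' circumferentially, and the whole field pulses with an inflow-waveform
#' envelope normalized to unit cycle mean (so TAWSS at the impingement
#' point equals `strength`).
#'
#' @param tube a [make_tube()] mesh.
#' @param z0 axial position of the impingement point (mm).
#' @param theta0 circumferential position (rad).
#' @param strength peak TAWSS of the pattern (Pa).
#' @param spread Gaussian spread of the footprint (mm).
#' @param mode washing mode: `"axial"` or `"circumferential"`.
#' @param waveform pulsatility envelope, an [inflow_waveform()]; default the
#'   synthesized aortic-like waveform.
#' @param n_samples time samples per cycle.
#' @param bias blend weight toward the mode axis (0 = purely radiating,
#'   1 = purely axial/circumferential; default 0.8).
#' @return a [wss_series()].
#' @export
jet_impingement_field <- function(tube, z0, theta0 = 0, strength = 10,
                                  spread = 10,
                                  mode = c("axial", "circumferential"),
                                  waveform = NULL, n_samples = 32,
                                  bias = 0.8) {
  mode <- match.arg(mode)
  ch <- tube_chart(tube)
  L <- attr(tube, "length")
  if (z0 < 0 || z0 > L) stop("impingement point lies off the tube surface")
  if (is.null(waveform)) waveform <- synthesize_waveform()
  period <- waveform$period
  t <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  env <- pmax(evaluate_waveform(waveform, t), 0)
  env_mean <- cycle_mean(t, env, period)
  env <- if (env_mean > 0) env / env_mean else env
  dz <- ch$z - z0
  dth <- ((ch$theta - theta0 + pi) %% (2 * pi)) - pi
  dc <- ch$radius * dth
  dist2 <- dz^2 + dc^2
  mag <- strength * exp(-dist2 / (2 * spread^2))
  d <- sqrt(dist2)
  rad <- cbind(ifelse(d > 0, dz / d, 1), ifelse(d > 0, dc / d, 0))
  axis2 <- if (mode == "axial") cbind(sign(dz), 0) else cbind(0, sign(dc))
  dir2 <- (1 - bias) * rad + bias * axis2
  # nodes exactly on the mode axis keep the radiating direction
  zero <- rowSums(dir2^2) < 1e-20
  dir2[zero, ] <- rad[zero, ]
  dir2 <- dir2 / sqrt(rowSums(dir2^2))
  dir3 <- dir2[, 1] * ch$axial + dir2[, 2] * ch$circum
  n <- nrow(tube$nodes)
  w <- array(0, c(n, n_samples, 3))
  for (k in 1:3) w[, , k] <- outer(mag * dir3[, k], env)
  wss_series(t, w, period)
}

#' Tube with an attached branch stub at prescribed angles
#'
#' Generates a main tube plus a branch stub whose axis realizes the
#' requested branch angles exactly, returning the exact
#' [branch_geometry()] as ground truth for recovery tests. When
#' `beta >= alpha` the main-axis reference is the tube axis itself (the
#' branch azimuth is rotated to realize beta); when `beta < alpha` - which
#' is impossible against an in-plane axis - the reference axis is tilted
#' out of the tangent plane, as happens when beta is measured against the
#' centerline of a curved main vessel.
#'
#' @param main_radius,branch_radius radii (mm), `branch_radius < main_radius`.
#' @param alpha_deg,beta_deg requested angles in `(0, 90]` degrees.
#' @param main_length main tube length (mm).
#' @param branch_length branch stub length (mm).
#' @param n_axial,n_circ main tube resolution.
#' @param n_branch_axial,n_branch_circ branch stub resolution.
#' @return list with `mesh` (combined [surface_mesh()]), `geometry` (exact
#'   [branch_geometry()]), and `branch_nodes` (indices of stub nodes in the
#'   combined mesh).
#' @export
make_branched_tube <- function(main_radius = 16, branch_radius = 3,
                               alpha_deg, beta_deg, main_length = 100,
                               branch_length = 15, n_axial = 24, n_circ = 32,
                               n_branch_axial = 8, n_branch_circ = 16) {
  if (alpha_deg <= 0 || alpha_deg > 90 || beta_deg <= 0 || beta_deg > 90) {
    stop("branch angles must lie in (0, 90] degrees")
  }
  if (branch_radius >= main_radius) {
    stop("branch radius must be smaller than the main radius")
  }
  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  main <- make_tube(main_radius, main_length, n_axial, n_circ)
  p <- c(main_radius, 0, main_length / 2)
  nhat <- c(1, 0, 0)
  if (beta_deg >= alpha_deg - 1e-12) {
    # rotate the branch azimuth about the normal until the angle to the
    # (in-plane) tube axis equals beta; alpha is azimuth-independent
    cphi <- min(max(cos(b) / cos(a), -1), 1)
    phi <- acos(cphi)
    d <- c(sin(a), cos(a) * sin(phi), cos(a) * cos(phi))
    v <- c(0, 0, 1)
  } else {
    # beta < alpha: unreachable against any in-plane axis; tilt the
    # reference axis out of the plane (curved-centerline reading)
    d <- c(sin(a), 0, cos(a))
    v <- rotate_about(d, c(0, 1, 0), b)
  }
  d <- d / sqrt(sum(d^2))
  v <- v / sqrt(sum(v^2))
  stub <- tube_along_axis(branch_radius, branch_length, d, p,
                          n_branch_axial, n_branch_circ)
  offset <- nrow(main$nodes)
  mesh <- surface_mesh(rbind(main$nodes, stub$nodes),
                       rbind(main$triangles, stub$triangles + offset),
                       rbind(main$normals, stub$normals))
  list(mesh = mesh,
       geometry = branch_geometry(d, nhat, v, p),
       branch_nodes = offset + seq_len(nrow(stub$nodes)))
}

# open tube of given radius/length along an arbitrary unit axis from base
tube_along_axis <- function(radius, length, axis, base, n_axial, n_circ) {
  axis <- axis / sqrt(sum(axis^2))
  seed <- diag(3)[which.min(abs(axis)), ]
  e1 <- seed - sum(seed * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  s <- seq(0, length, length.out = n_axial)
  ring_dir <- outer(cos(theta), e1) + outer(sin(theta), e2)
  nodes <- do.call(rbind, lapply(s, function(si) {
    matrix(base, n_circ, 3, byrow = TRUE) + si *
      matrix(axis, n_circ, 3, byrow = TRUE) + radius * ring_dir
  }))
  normals <- do.call(rbind, rep(list(ring_dir), n_axial))
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  tris <- matrix(0L, 2L * (n_axial - 1L) * n_circ, 3L)
  r <- 1L
  for (i in seq_len(n_axial - 1L)) {
    for (j in seq_len(n_circ)) {
      aa <- idx(i, j); bb <- idx(i, j + 1L)
      cc <- idx(i + 1L, j + 1L); dd <- idx(i + 1L, j)
      tris[r, ] <- c(aa, bb, cc); tris[r + 1L, ] <- c(aa, cc, dd)
      r <- r + 2L
    }
  }
  list(nodes = nodes, triangles = tris, normals = normals)
}

#' Random seeded WSS series for property checks
#'
#' Generates per-node periodic WSS series with random tangent-plane vectors
#' (independent Gaussian components projected to the tangent plane, scaled
#' by a random positive magnitude), used for bound and invariance checks on
#' the cycle-averaged indicators.
#'
#' @param mesh a [surface_mesh()]; defaults to a single-node degenerate
#'   "mesh" facing +z if `normals` is given instead.
#' @param n_samples time samples per cycle.
#' @param period cycle period (s).
#' @param seed RNG seed.
#' @param normals optional n x 3 normal matrix (used without a mesh).
#' @return a [wss_series()].
#' @export
random_wss_series <- function(mesh = NULL, n_samples = 32, period = 0.8,
                              seed = 1L, normals = NULL) {
  if (is.null(normals)) normals <- mesh$normals
  n <- nrow(normals)
  w <- withr::with_seed(seed, {
    arr <- array(stats::rnorm(n * n_samples * 3), c(n, n_samples, 3))
    scale <- matrix(stats::rexp(n * n_samples, rate = 1), n, n_samples)
    for (j in seq_len(n_samples)) {
      vj <- arr[, j, , drop = FALSE]
      dim(vj) <- c(n, 3)
      vj <- vj - rowSums(vj * normals) * normals
      arr[, j, ] <- vj * scale[, j]
    }
    arr
  })
  t <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  wss_series(t, w, period)
}

#' Generate a named synthetic scenario
#'
#' One-call front end over the individual generators, as used by the
#' pipeline: `"womersley_tube"` (exact pulsatile shear on a tube),
#' `"steady_tube"` (steady Poiseuille shear), `"oscillatory_tube"`
#' (zero-mean single harmonic), `"jet_axial"` / `"jet_circumferential"`
#' (impingement patterns), `"prescribed_osi"` (random OSI targets).
#'
#' @param scenario scenario name.
#' @param seed RNG seed fixing all random choices.
#' @param n_axial,n_circ tube resolution.
#' @param n_samples time samples per cycle.
#' @return list with `mesh`, `series`, and `truth` (generator parameters).
#' @export
generate_scenario <- function(scenario = c("womersley_tube", "steady_tube",
                                           "oscillatory_tube", "jet_axial",
                                           "jet_circumferential",
                                           "prescribed_osi"),
                              seed = 1L, n_axial = 16, n_circ = 24,
                              n_samples = 48) {
  scenario <- match.arg(scenario)
  tube <- make_tube(16, 100, n_axial, n_circ)
  truth <- list(scenario = scenario, seed = seed, radius_mm = 16,
                length_mm = 100, n_axial = n_axial, n_circ = n_circ,
                n_samples = n_samples)
  series <- switch(
    scenario,
    womersley_tube = {
      case <- womersley_case(0.016, 0.8, c(1.5, 1 + 0.5i, 0.3 - 0.2i))
      truth$case <- "steady + 2 harmonics, R = 16 mm, T = 0.8 s"
      womersley_wss_on_tube(tube, case, n_samples)
    },
    steady_tube = {
      case <- womersley_case(0.016, 0.8, 2)
      truth$case <- "steady forcing 2 Pa/m"
      womersley_wss_on_tube(tube, case, n_samples)
    },
    oscillatory_tube = {
      case <- womersley_case(0.016, 0.8, c(0, 2))
      truth$case <- "zero-mean single harmonic"
      womersley_wss_on_tube(tube, case, n_samples)
    },
    jet_axial = jet_impingement_field(tube, z0 = 50, strength = 12,
                                      spread = 12, mode = "axial",
                                      n_samples = n_samples),
    jet_circumferential = jet_impingement_field(tube, z0 = 50, strength = 12,
                                                spread = 12,
                                                mode = "circumferential",
                                                n_samples = n_samples),
    prescribed_osi = {
      targets <- withr::with_seed(seed, stats::runif(nrow(tube$nodes), 0, 0.5))
      truth$targets <- targets
      prescribed_osi_field(tube, targets, scale = 2, seed = seed)
    }
  )
  list(mesh = tube, series = series, truth = truth)
}
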