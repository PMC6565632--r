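#' Triangulated vessel surface
#'
#' Container for a triangulated vessel wall: node coordinates (mm), triangle
#' connectivity (1-based node index triples) and outward unit normals. When
#' normals are not supplied they are recomputed by area-weighted averaging of
#' incident triangle normals.
#'
#' @param nodes numeric matrix, n x 3, coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based node indices with a
#'   consistent (outward) orientation.
#' @param normals optional numeric matrix, n x 3, outward unit normals.
#' @param validate check mesh invariants (indices in range, unit normals,
#'   consistent orientation across interior edges).
#' @return an object of class `surface_mesh`.
#' @seealso [make_tube()], [compute_node_normals()]
#' @export
surface_mesh <- function(nodes, triangles, normals = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (is.null(normals)) {
    normals <- compute_node_normals(nodes, triangles)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
  }
  mesh <- structure(
    list(nodes = nodes, triangles = triangles, normals = normals),
    class = "surface_mesh"
  )
  if (validate) validate_surface_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d nodes, %d triangles (coordinates in mm)\n",
    nrow(x$nodes), nrow(x$triangles)
  ))
  invisible(x)
}

validate_surface_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  tri <- mesh$triangles
  if (any(tri < 1L) || any(tri > n)) {
    stop("triangle connectivity references a non-existent node")
  }
  nrm <- sqrt(rowSums(mesh$normals^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("node normals must have unit length (within 1e-9)")
  }
  # orientation consistency: each interior (twice-used) edge must be
  # traversed once in each direction
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key)) {
    stop("inconsistent triangle orientation: a directed edge appears twice")
  }
  und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(und)
  if (any(cnt > 2)) stop("non-manifold edge: shared by more than 2 triangles")
  invisible(mesh)
}

#' Recompute outward node normals by area-weighted averaging
#'
#' Each triangle contributes its (area-scaled) face normal to its three
#' nodes; the sums are normalized to unit length. On a structured cylinder
#' the tangential contributions cancel at interior nodes and the result is
#' radial to machine precision.
#'
#' @param nodes n x 3 coordinate matrix (mm).
#' @param triangles m x 3 connectivity.
#' @return n x 3 matrix of unit normals.
#' @export
compute_node_normals <- function(nodes, triangles) {
  a <- nodes[triangles[, 1], , drop = FALSE]
  b <- nodes[triangles[, 2], , drop = FALSE]
  c_ <- nodes[triangles[, 3], , drop = FALSE]
  fn <- cross3(b - a, c_ - a) # magnitude = 2 * area
  acc <- matrix(0, nrow(nodes), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc[, d] <- acc[, d] +
        as.vector(tapply_sum(fn[, d], triangles[, k], nrow(nodes)))
    }
  }
  len <- sqrt(rowSums(acc^2))
  if (any(len == 0)) stop("isolated node: cannot compute a normal")
  acc / len
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

cross3 <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

#' Time-resolved wall shear stress series on a surface
#'
#' Stores one WSS 3-vector (Pa) per node and time sample, together with the
#' sample times and the heartbeat period T. The series is interpreted as
#' T-periodic; sample times lie in `[0, T)` and may be non-uniform.
#'
#' @param times numeric vector of sample times (s), strictly increasing in
#'   `[0, period)`, length >= 2.
#' @param wss numeric array `n_nodes x n_times x 3` of WSS vectors (Pa).
#' @param period heartbeat period T (s).
#' @return an object of class `wss_series`.
#' @export
wss_series <- function(times, wss, period) {
  if (length(dim(wss)) != 3L || dim(wss)[3] != 3L) {
    stop("wss must be an n_nodes x n_times x 3 array")
  }
  if (dim(wss)[2] != length(times)) {
    stop("number of time samples does not match the wss array")
  }
  cycle_weights(times, period) # validates times
  structure(
    list(times = as.double(times), period = as.double(period),
         wss = unname(wss)),
    class = "wss_series"
  )
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf(
    "<wss_series> %d nodes x %d samples, period %.4g s (WSS in Pa)\n",
    dim(x$wss)[1], dim(x$wss)[2], x$period
  ))
  invisible(x)
}

#' @method as_tibble wss_series
#' @export
as_tibble.wss_series <- function(x, ...) {
  d <- dim(x$wss)
  tibble::tibble(
    node = rep(seq_len(d[1]), times = d[2]),
    time = rep(x$times, each = d[1]),
    wx = as.vector(x$wss[, , 1]),
    wy = as.vector(x$wss[, , 2]),
    wz = as.vector(x$wss[, , 3])
  )
}

#' Project WSS vectors into the local tangent plane
#'
#' Wall shear stress is tangential by definition, but discrete CFD exports
#' carry small normal components; this removes them, replacing each vector v
#' by `v - (v . n) n` with n the node's outward normal.
#'
#' @param series a [wss_series()].
#' @param mesh the [surface_mesh()] carrying the node normals.
#' @return a `wss_series` whose vectors are tangent to working precision.
#' @export
project_to_tangent <- function(series, mesh) {
  d <- dim(series$wss)
  if (d[1] != nrow(mesh$nodes)) stop("series and mesh node counts differ")
  w <- series$wss
  nn <- mesh$normals
  for (j in seq_len(d[2])) {
    vj <- w[, j, ]
    dot <- rowSums(vj * nn)
    w[, j, ] <- vj - dot * nn
  }
  wss_series(series$times, w, series$period)
}

max_normal_residual <- function(series, mesh) {
  d <- dim(series$wss)
  worst <- 0
  for (j in seq_len(d[2])) {
    vj <- series$wss[, j, ]
    dot <- abs(rowSums(vj * mesh$normals))
    rel <- dot / (sqrt(rowSums(vj^2)) + 1)
    worst <- max(worst, max(rel))
  }
  worst
}

#' Probe a per-node scalar map at arbitrary wall points
#'
#' Looks up per-node scalar values at probe locations (e.g. tear projection
#' zones). `barycentric` interpolates linearly inside the nearest triangle,
#' falling back to the nearest node when the probe lies farther from the
#' surface than `fallback_tol`; `nearest_node` always snaps to the closest
#' node.
#'
#' @param values numeric vector, one value per mesh node.
#' @param mesh a [surface_mesh()].
#' @param probes tibble/data frame with columns `label`, `x`, `y`, `z` (mm).
#' @param mode `"barycentric"` (default) or `"nearest_node"`.
#' @param fallback_tol off-surface distance (mm) beyond which barycentric
#'   probing falls back to the nearest node (default 2 mm).
#' @param bbox_tol probes outside the mesh bounding box expanded by this
#'   margin (mm) are rejected.
#' @return tibble with columns `label`, `value`, `distance_mm`, `method`.
#' @export
probe_values <- function(values, mesh, probes, mode = c("barycentric", "nearest_node"),
                         fallback_tol = 2, bbox_tol = 10) {
  mode <- match.arg(mode)
  stopifnot(length(values) == nrow(mesh$nodes))
  p <- as.matrix(probes[, c("x", "y", "z")])
  lo <- apply(mesh$nodes, 2, min) - bbox_tol
  hi <- apply(mesh$nodes, 2, max) + bbox_tol
  out_of_box <- apply(p, 1, function(q) any(q < lo | q > hi))
  if (any(out_of_box)) {
    stop(sprintf("probe '%s' lies outside the expanded mesh bounding box",
                 probes$label[which(out_of_box)[1]]))
  }
  res <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    q <- p[i, ]
    d2 <- colSums((t(mesh$nodes) - q)^2)
    nearest <- which.min(d2)
    if (mode == "nearest_node") {
      return(tibble::tibble(label = probes$label[i], value = values[nearest],
                            distance_mm = sqrt(d2[nearest]),
                            method = "nearest_node"))
    }
    hit <- closest_triangle_point(q, mesh)
    if (hit$distance <= fallback_tol) {
      tri <- mesh$triangles[hit$triangle, ]
      val <- sum(hit$bary * values[tri])
      tibble::tibble(label = probes$label[i], value = val,
                     distance_mm = hit$distance, method = "barycentric")
    } else {
      tibble::tibble(label = probes$label[i], value = values[nearest],
                     distance_mm = sqrt(d2[nearest]),
                     method = "nearest_node_fallback")
    }
  })
  res
}

# closest point on any triangle of the mesh to query q; returns the triangle
# index, clamped barycentric coordinates and the distance
closest_triangle_point <- function(q, mesh) {
  tri <- mesh$triangles
  a <- mesh$nodes[tri[, 1], , drop = FALSE]
  b <- mesh$nodes[tri[, 2], , drop = FALSE]
  c_ <- mesh$nodes[tri[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  aq <- matrix(q, nrow(a), 3, byrow = TRUE) - a
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  d20 <- rowSums(aq * ab); d21 <- rowSums(aq * ac)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  # clamp to the triangle (projection onto edges when outside)
  v <- pmin(pmax(v, 0), 1)
  w <- pmin(pmax(w, 0), 1)
  s <- v + w
  over <- s > 1
  v[over] <- v[over] / s[over]
  w[over] <- w[over] / s[over]
  pt <- a + v * ab + w * ac
  d2 <- rowSums((pt - matrix(q, nrow(a), 3, byrow = TRUE))^2)
  k <- which.min(d2)
  list(triangle = k, bary = c(1 - v[k] - w[k], v[k], w[k]),
       distance = sqrt(d2[k]))
}

#' Read probe points from CSV
#'
#' Expects columns `label,x,y,z` with coordinates in mm.
#' @param path CSV file path.
#' @return tibble of probe points.
#' @export
read_probe_points <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), z = readr::col_double()
  ))
}
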