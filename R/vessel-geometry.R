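#' Vessel centerline
#'
#' Ordered polyline of centerline points (mm) with unit tangents by centered
#' finite differences (one-sided at the ends).
#'
#' @param points n x 3 matrix of ordered points (mm), consecutive points
#'   distinct.
#' @return object of class `centerline` with `points`, `tangents`,
#'   `arc_length` (cumulative, mm).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L) {
    stop("a centerline needs at least two 3-D points")
  }
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0)) stop("consecutive centerline points must be distinct")
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- seg[1, ]
  tang[n, ] <- seg[n - 1L, ]
  if (n > 2L) tang[2:(n - 1L), ] <- points[3:n, ] - points[1:(n - 2L), ]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, tangents = tang,
                 arc_length = c(0, cumsum(seglen))),
            class = "centerline")
}

#' Parallel-transported orthonormal frames along a centerline
#'
#' Builds a right-handed orthonormal triad (tangent, two transverse
#' directions) at every centerline point; the transverse pair is carried
#' along by parallel transport (rotation taking each tangent to the next),
#' which avoids the frame flips a Frenet frame suffers at inflections.
#'
#' @param cl a [centerline()].
#' @return list of matrices `tangent`, `normal`, `binormal` (n x 3 each).
#' @export
centerline_frames <- function(cl) {
  tang <- cl$tangents
  n <- nrow(tang)
  nor <- matrix(0, n, 3)
  # seed: least-aligned coordinate axis, orthogonalized
  seed <- diag(3)[which.min(abs(tang[1, ])), ]
  v <- seed - sum(seed * tang[1, ]) * tang[1, ]
  nor[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    t0 <- tang[i - 1L, ]; t1 <- tang[i, ]
    ax <- c(t0[2] * t1[3] - t0[3] * t1[2],
            t0[3] * t1[1] - t0[1] * t1[3],
            t0[1] * t1[2] - t0[2] * t1[1])
    s <- sqrt(sum(ax^2))
    cth <- min(max(sum(t0 * t1), -1), 1)
    if (s < 1e-14) {
      w <- nor[i - 1L, ]
    } else {
      ax <- ax / s
      th <- atan2(s, cth)
      w <- rotate_about(nor[i - 1L, ], ax, th)
    }
    w <- w - sum(w * t1) * t1 # re-orthogonalize against drift
    nor[i, ] <- w / sqrt(sum(w^2))
  }
  bin <- cross3(tang, nor)
  list(tangent = tang, normal = nor, binormal = bin)
}

rotate_about <- function(v, axis, theta) {
  v * cos(theta) +
    c(axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

#' Local orthonormal frame at an arc position
#'
#' Returns the parallel-transported triad at the centerline sample nearest
#' to the requested arc-length position.
#'
#' @param cl a [centerline()].
#' @param s arc-length position (mm) within the polyline span.
#' @return list with unit vectors `tangent`, `normal`, `binormal`.
#' @export
local_frame <- function(cl, s) {
  L <- cl$arc_length
  if (s < L[1] || s > L[length(L)]) {
    stop("arc position lies outside the centerline span")
  }
  fr <- centerline_frames(cl)
  i <- which.min(abs(L - s))
  list(tangent = fr$tangent[i, ], normal = fr$normal[i, ],
       binormal = fr$binormal[i, ])
}

#' Branch geometry at an anastomosis
#'
#' Houses the vectors needed for the two branch angles: alpha, between the
#' branch axis and the wall tangent plane, and beta, between the branch
#' axis and the main-vessel reference axis (centerline direction or
#' vertical axis - both conventions occur; the reference vector is taken as
#' given input).
#'
#' @param branch_axis unit vector along the branch (collateral) axis.
#' @param plane_normal outward unit normal of the wall tangent plane at the
#'   anastomosis.
#' @param main_axis unit reference axis of the main vessel.
#' @param point anastomosis point (mm).
#' @return object of class `branch_geometry`.
#' @export
branch_geometry <- function(branch_axis, plane_normal, main_axis,
                            point = c(0, 0, 0)) {
  unitize <- function(v, nm) {
    l <- sqrt(sum(v^2))
    if (l == 0) stop(sprintf("%s must be a nonzero vector", nm))
    v / l
  }
  structure(list(branch_axis = unitize(branch_axis, "branch_axis"),
                 plane_normal = unitize(plane_normal, "plane_normal"),
                 main_axis = unitize(main_axis, "main_axis"),
                 point = as.double(point)),
            class = "branch_geometry")
}

#' Branch angles alpha and beta
#'
#' alpha = 90 deg minus the angle between the branch axis and the tangent
#' plane normal (i.e. the elevation of the branch axis above the wall
#' plane); beta = the angle between the branch axis and the main-vessel
#' reference axis. Both are folded into `[0, 90]` degrees, matching the
#' range in which clinical branch-angle tables are reported.
#'
#' @param bg a [branch_geometry()].
#' @return tibble with columns `alpha_deg`, `beta_deg`.
#' @export
branch_angles <- function(bg) {
  fold_acos <- function(c_) acos(min(max(abs(c_), 0), 1)) * 180 / pi
  alpha <- 90 - fold_acos(sum(bg$branch_axis * bg$plane_normal))
  beta <- fold_acos(sum(bg$branch_axis * bg$main_axis))
  tibble::tibble(alpha_deg = alpha, beta_deg = beta)
}

#' Planar lumen cross-section
#'
#' A simple closed polygon in its section plane, with shoelace area and
#' perimeter.
#'
#' @param vertices n x 2 matrix of in-plane vertex coordinates (mm),
#'   unclosed (first vertex not repeated).
#' @param check_simple verify the polygon is non-self-intersecting.
#' @return object of class `cross_section` with `vertices`, `area_mm2`,
#'   `perimeter_mm`.
#' @export
cross_section <- function(vertices, check_simple = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) {
    stop("a cross-section needs at least 3 in-plane vertices")
  }
  if (check_simple && !is_simple_polygon(v)) {
    stop("cross-section polygon is self-intersecting")
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  if (area <= 0 || per <= 0) stop("degenerate polygon")
  structure(list(vertices = v, area_mm2 = area, perimeter_mm = per),
            class = "cross_section")
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1), ]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Hydraulic diameter of a cross-section
#'
#' `D_h = 4 A / P`; equals the diameter for a circle and the side for a
#' square.
#'
#' @param section a [cross_section()].
#' @return hydraulic diameter (mm).
#' @export
hydraulic_diameter <- function(section) {
  4 * section$area_mm2 / section$perimeter_mm
}

#' Mean equivalent-area diameter over branch cross-sections
#'
#' Averages `2 sqrt(A / pi)` over the supplied sections - the convention
#' behind reported mean branch diameters.
#'
#' @param sections list of [cross_section()] objects (at least one).
#' @return mean diameter (mm).
#' @export
mean_branch_diameter <- function(sections) {
  if (!length(sections)) stop("at least one cross-section is required")
  mean(vapply(sections, function(s) 2 * sqrt(s$area_mm2 / pi), numeric(1)))
}

#' Read a centerline polyline from CSV (columns x,y,z in mm)
#' @param path CSV file path.
#' @return a [centerline()].
#' @export
read_centerline <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  centerline(as.matrix(df[, c("x", "y", "z")]))
}
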