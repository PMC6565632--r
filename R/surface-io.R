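#' Write a surface WSS series as a plain-text archive
#'
#' The archive is a directory holding `nodes.csv`, `triangles.csv`,
#' `normals.csv`, `times.csv`, `wss.csv` (long format: node, sample, wx, wy,
#' wz) and `meta.json` with the period and unit metadata (mm / Pa / s).
#' Doubles are written with full round-trip precision.
#'
#' @param mesh a [surface_mesh()].
#' @param series a [wss_series()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_surface_series <- function(mesh, series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_csv17(tibble::as_tibble(mesh$nodes, .name_repair = ~ c("x", "y", "z")),
              file.path(dir, "nodes.csv"))
  readr::write_csv(tibble::as_tibble(mesh$triangles, .name_repair = ~ c("a", "b", "c")),
                   file.path(dir, "triangles.csv"))
  write_csv17(tibble::as_tibble(mesh$normals, .name_repair = ~ c("nx", "ny", "nz")),
              file.path(dir, "normals.csv"))
  write_csv17(tibble::tibble(time = series$times), file.path(dir, "times.csv"))
  d <- dim(series$wss)
  long <- tibble::tibble(
    node = rep(seq_len(d[1]), times = d[2]),
    sample = rep(seq_len(d[2]), each = d[1]),
    wx = as.vector(series$wss[, , 1]),
    wy = as.vector(series$wss[, , 2]),
    wz = as.vector(series$wss[, , 3])
  )
  write_csv17(long, file.path(dir, "wss.csv"))
  jsonlite::write_json(
    list(period_s = series$period,
         units = list(length = "mm", wss = "Pa", time = "s"),
         n_nodes = d[1], n_samples = d[2]),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# 17-significant-digit decimal form round-trips IEEE doubles exactly
write_csv17 <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        ~ sprintf("%.17g", .x)))
  readr::write_csv(df, path)
}

#' Read a surface WSS series
#'
#' Accepts either an archive directory written by [write_surface_series()]
#' or an ordered character vector of legacy-ASCII VTK polydata files (one
#' snapshot per time sample, identical topology, WSS stored as a point-data
#' vector field).
#'
#' @param path archive directory, or vector of VTK file paths.
#' @param period heartbeat period (s); required for VTK input, read from
#'   metadata for archives.
#' @param times sample times for VTK input (defaults to a uniform grid on
#'   `[0, period)`).
#' @param field name of the VTK point-data vector field (default "WSS").
#' @param project project vectors to the tangent plane on load (default TRUE).
#' @return list with elements `mesh` and `series`.
#' @export
read_surface_series <- function(path, period = NULL, times = NULL,
                                field = "WSS", project = TRUE) {
  if (length(path) == 1L && dir.exists(path)) {
    out <- read_series_archive(path)
  } else {
    if (is.null(period)) stop("period must be supplied for VTK series input")
    out <- read_series_vtk(path, period, times, field)
  }
  if (project) out$series <- project_to_tangent(out$series, out$mesh)
  out
}

read_series_archive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  # parse via strtod (correctly rounded) for bit-exact round-trips
  num <- function(f) {
    df <- readr::read_csv(file.path(dir, f),
                          col_types = readr::cols(.default = readr::col_character()))
    vapply(df, as.numeric, numeric(nrow(df)))
  }
  nodes <- unname(num("nodes.csv"))
  tris <- unname(as.matrix(readr::read_csv(file.path(dir, "triangles.csv"),
                                           col_types = readr::cols(.default = readr::col_integer()))))
  normals <- unname(num("normals.csv"))
  times <- num("times.csv")[, 1]
  long <- readr::read_csv(file.path(dir, "wss.csv"),
                          col_types = readr::cols(
                            node = readr::col_integer(),
                            sample = readr::col_integer(),
                            .default = readr::col_character()))
  long <- dplyr::mutate(long, dplyr::across(c("wx", "wy", "wz"), as.numeric))
  n <- meta$n_nodes; m <- meta$n_samples
  if (nrow(long) != n * m) stop("wss.csv row count does not match metadata")
  w <- array(0, c(n, m, 3))
  ord <- order(long$sample, long$node)
  w[, , 1] <- long$wx[ord]; w[, , 2] <- long$wy[ord]; w[, , 3] <- long$wz[ord]
  mesh <- surface_mesh(nodes, tris, normals)
  list(mesh = mesh, series = wss_series(times, w, meta$period_s))
}

read_series_vtk <- function(paths, period, times, field) {
  snaps <- lapply(paths, read_vtk_polydata, field = field)
  first <- snaps[[1]]
  for (i in seq_along(snaps)[-1]) {
    s <- snaps[[i]]
    if (nrow(s$nodes) != nrow(first$nodes) ||
        nrow(s$triangles) != nrow(first$triangles) ||
        any(s$triangles != first$triangles)) {
      stop(sprintf("topology mismatch: snapshot %d differs from snapshot 1", i))
    }
    if (is.null(s$field)) stop(sprintf("snapshot %d lacks the '%s' field", i, field))
  }
  if (is.null(first$field)) stop(sprintf("snapshot 1 lacks the '%s' field", field))
  if (is.null(times)) {
    times <- seq(0, period, length.out = length(paths) + 1L)[seq_along(paths)]
  }
  n <- nrow(first$nodes)
  w <- array(0, c(n, length(paths), 3))
  for (i in seq_along(snaps)) w[, i, ] <- snaps[[i]]$field
  mesh <- surface_mesh(first$nodes, first$triangles)
  list(mesh = mesh, series = wss_series(times, w, period))
}

#' Write a legacy-ASCII VTK polydata file
#'
#' Emits POINTS / POLYGONS plus optional point data: a named list of scalar
#' vectors and/or one 3-column vector field. Intended for inspection in
#' ParaView; the plain-text archive is the lossless interchange format.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file (.vtk).
#' @param scalars named list of per-node numeric vectors.
#' @param vectors optional n x 3 matrix written as a VECTORS field.
#' @param vectors_name name of the vector field (default "WSS").
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path, scalars = list(), vectors = NULL,
                               vectors_name = "WSS") {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hemowss surface (units: mm, Pa, s)",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  if (length(scalars) || !is.null(vectors)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", scalars[[nm]]), con)
    }
    if (!is.null(vectors)) {
      writeLines(sprintf("VECTORS %s double", vectors_name), con)
      writeLines(apply(vectors, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    }
  }
  invisible(path)
}

# minimal legacy-ASCII polydata reader covering the subset the writer emits
read_vtk_polydata <- function(path, field = "WSS") {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- grep("^POINTS", lines)[1]
  if (is.na(i)) stop("not a polydata file: no POINTS block")
  n <- as.integer(toks(lines[i])[2])
  pts <- scan(text = lines[(i + 1):length(lines)], n = 3L * n, quiet = TRUE)
  nodes <- matrix(pts, n, 3, byrow = TRUE)
  j <- grep("^POLYGONS", lines)[1]
  m <- as.integer(toks(lines[j])[2])
  raw <- scan(text = lines[(j + 1):length(lines)], n = 4L * m, quiet = TRUE)
  raw <- matrix(raw, m, 4, byrow = TRUE)
  if (any(raw[, 1] != 3)) stop("only triangle polygons are supported")
  tris <- raw[, 2:4, drop = FALSE] + 1L
  vec <- NULL
  k <- grep(sprintf("^VECTORS %s ", field), lines)
  if (length(k)) {
    v <- scan(text = lines[(k[1] + 1):length(lines)], n = 3L * n, quiet = TRUE)
    vec <- matrix(v, n, 3, byrow = TRUE)
  }
  list(nodes = nodes, triangles = tris, field = vec)
}
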