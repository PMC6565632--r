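#' Time-averaged wall shear stress at one node
#'
#' TAWSS = (1/T) * integral over one cycle of |WSS(t)|, evaluated with the
#' period-closing trapezoidal rule ([cycle_integral()]).
#'
#' @param wss either an `n_t x 3` matrix of WSS vectors (Pa) or a numeric
#'   vector of signed magnitudes along a fixed direction.
#' @param times sample times (s), strictly increasing in `[0, period)`.
#' @param period heartbeat period T (s).
#' @return TAWSS in Pa (scalar, >= 0).
#' @export
tawss <- function(wss, times, period) {
  cycle_mean(times, wss_magnitudes(wss), period)
}

wss_magnitudes <- function(wss) {
  if (is.matrix(wss)) sqrt(rowSums(wss^2)) else abs(wss)
}

wss_mean_vector <- function(wss, times, period) {
  if (is.matrix(wss)) {
    cycle_mean(times, wss, period)
  } else {
    cycle_mean(times, wss, period) # signed scalar along the fixed direction
  }
}

#' Oscillatory shear index at one node
#'
#' OSI = 0.5 * (1 - |cycle-mean WSS vector| / cycle-mean |WSS|). Zero for
#' unidirectional shear, 0.5 for purely oscillatory (zero-mean) shear.
#' A node whose cycle-mean |WSS| vanishes has no defined OSI and yields
#' `NA` (flagged invalid downstream, never an error).
#'
#' @inheritParams tawss
#' @return OSI in `[0, 0.5]`, or `NA` where undefined.
#' @export
osi <- function(wss, times, period) {
  denom <- tawss(wss, times, period)
  if (denom <= 0) return(NA_real_)
  m <- wss_mean_vector(wss, times, period)
  num <- if (length(m) == 3L) sqrt(sum(m^2)) else abs(m)
  val <- 0.5 * (1 - num / denom)
  min(max(val, 0), 0.5)
}

#' Relative residence time
#'
#' RRT is proportional to `1 / ((1 - 2 OSI) * TAWSS)`, a surrogate for the
#' residence time of particles near the wall. The proportionality constant
#' `k` defaults to 1 (bare reciprocal); see [calibrate_rrt_constant()] for
#' matching a reported RRT column that uses an unstated normalization.
#' Nodes at the oscillatory singularity (`osi >= 0.5 - eps`) or with zero
#' TAWSS return `NA` rather than infinities.
#'
#' @param tawss TAWSS values (Pa), vectorized.
#' @param osi OSI values, vectorized.
#' @param k proportionality constant (default 1).
#' @param eps guard band below the OSI = 0.5 singularity (default 1e-9).
#' @return RRT values; `NA` where undefined.
#' @export
rrt <- function(tawss, osi, k = 1, eps = 1e-9) {
  out <- k / ((1 - 2 * osi) * tawss)
  bad <- is.na(tawss) | is.na(osi) | osi >= 0.5 - eps | tawss <= 0
  out[bad] <- NA_real_
  out
}

#' Calibrate the RRT proportionality constant from a reference row
#'
#' Given one reference wall location with known TAWSS, OSI and reported RRT,
#' returns `k = rrt * (1 - 2 osi) * tawss` so that [rrt()] with this `k`
#' reproduces the reported value there.
#'
#' @param tawss,osi,rrt reference values (scalars).
#' @return the constant k.
#' @export
calibrate_rrt_constant <- function(tawss, osi, rrt) {
  if (any(is.na(tawss) | is.na(osi) | is.na(rrt)) ||
      any(tawss <= 0) || any(osi >= 0.5)) {
    stop("invalid reference row for RRT calibration")
  }
  rrt * (1 - 2 * osi) * tawss
}

#' Transverse wall shear stress at one node
#'
#' TransWSS = (1/T) * integral of `|WSS(t) . (n x e_m)|` where `n` is the
#' outward wall normal and `e_m` the unit cycle-mean WSS direction: the
#' cycle-average of the WSS component perpendicular to the mean flow
#' direction within the tangent plane. Captures multidirectional
#' (cross-flow) shear that OSI misses. Undefined (NA) when the cycle-mean
#' WSS vector vanishes.
#'
#' @param wss `n_t x 3` matrix of WSS vectors (Pa).
#' @param times,period as in [tawss()].
#' @param normal outward unit wall normal at the node.
#' @return TransWSS in Pa, within `[0, tawss]`; `NA` where undefined.
#' @export
transwss <- function(wss, times, period, normal) {
  stopifnot(is.matrix(wss), length(normal) == 3L)
  m <- cycle_mean(times, wss, period)
  mn <- sqrt(sum(m^2))
  if (mn <= .Machine$double.eps * max(wss_magnitudes(wss), 1)) return(NA_real_)
  e_m <- m / mn
  p <- c(normal[2] * e_m[3] - normal[3] * e_m[2],
         normal[3] * e_m[1] - normal[1] * e_m[3],
         normal[1] * e_m[2] - normal[2] * e_m[1])
  cycle_mean(times, abs(as.vector(wss %*% p)), period)
}

#' Normalized transverse WSS
#'
#' OSItr = TransWSS / TAWSS, in `[0, 1]`: 0 for purely axial (unidirectional
#' in the mean direction) shear, approaching 1 when most of the shear acts
#' across the mean flow direction.
#'
#' @param transwss,tawss values (vectorized).
#' @return OSItr; `NA` where TAWSS is zero or TransWSS undefined.
#' @export
ositr <- function(transwss, tawss) {
  out <- transwss / tawss
  out[!is.na(out)] <- pmin(pmax(out[!is.na(out)], 0), 1)
  out[is.na(transwss) | is.na(tawss) | tawss <= 0] <- NA_real_
  out
}

#' Classify wall zones by TAWSS threshold
#'
#' Labels nodes `low` where TAWSS is strictly below `low` (default 0.4 Pa),
#' `high` strictly above `high` (default 5 Pa), `normal` otherwise; values
#' exactly at a threshold are `normal`.
#'
#' @param tawss numeric vector of TAWSS values (Pa).
#' @param low,high thresholds in Pa, `0 < low < high`.
#' @return factor with levels low/normal/high.
#' @export
classify_zones <- function(tawss, low = 0.4, high = 5) {
  if (!(is.finite(low) && is.finite(high) && 0 < low && low < high)) {
    stop("thresholds must satisfy 0 < low < high")
  }
  z <- ifelse(tawss < low, "low", ifelse(tawss > high, "high", "normal"))
  factor(z, levels = c("low", "normal", "high"))
}

#' Axial vs circumferential wall washing
#'
#' Operationalizes whether the near-wall flow washes the wall along the
#' vessel axis or around it: the angle between the cycle-mean WSS direction
#' and the local axial direction, `arccos(|e_m . a|)` folded into
#' `[0, 90]` degrees, labelled `circumferential` when it exceeds the
#' threshold (default 45 degrees) and `axial` otherwise (boundary = axial).
#'
#' @param wss `n_t x 3` WSS matrix (Pa) at the node.
#' @param times,period as in [tawss()].
#' @param axial local axial unit vector, tangent to the wall at the node.
#' @param threshold_deg label threshold in degrees (default 45).
#' @return list with `angle_deg` and `label`; angle `NA` and label `NA` when
#'   the cycle-mean WSS is degenerate.
#' @export
washing_direction <- function(wss, times, period, axial, threshold_deg = 45) {
  m <- cycle_mean(times, wss, period)
  mn <- sqrt(sum(m^2))
  if (mn <= .Machine$double.eps * max(wss_magnitudes(wss), 1)) {
    return(list(angle_deg = NA_real_, label = NA_character_))
  }
  a <- axial / sqrt(sum(axial^2))
  cosang <- min(max(abs(sum(m / mn * a)), 0), 1)
  ang <- acos(cosang) * 180 / pi
  list(angle_deg = ang,
       label = if (ang > threshold_deg) "circumferential" else "axial")
}

#' Compute all cycle-averaged WSS indicators for a surface series
#'
#' Evaluates TAWSS, OSI, RRT, TransWSS and OSItr at every node of a
#' [wss_series()] over one heartbeat, classifies low/normal/high zones, and
#' flags nodes where an indicator is undefined (vanishing mean shear). All
#' time integrals use the period-closing trapezoidal rule.
#'
#' @param mesh a [surface_mesh()].
#' @param series a [wss_series()] on that mesh.
#' @param rrt_k RRT proportionality constant (default 1).
#' @param low,high zone thresholds in Pa (defaults 0.4 and 5).
#' @param axial optional `n x 3` matrix (or single vector) of local axial
#'   directions; when supplied, washing angle/label columns are added.
#' @return a tibble of class `hemo_indices` with columns `node`, `tawss`,
#'   `osi`, `rrt`, `transwss`, `ositr`, `zone`, `valid` (and `washing_deg`,
#'   `washing` when `axial` is given).
#' @export
compute_wss_indices <- function(mesh, series, rrt_k = 1, low = 0.4, high = 5,
                                axial = NULL) {
  d <- dim(series$wss)
  if (d[1] != nrow(mesh$nodes)) stop("series and mesh node counts differ")
  w <- cycle_weights(series$times, series$period)
  t_ <- series$period
  mags <- sqrt(series$wss[, , 1]^2 + series$wss[, , 2]^2 + series$wss[, , 3]^2)
  if (is.null(dim(mags))) mags <- matrix(mags, d[1], d[2])
  tawss_v <- as.vector(mags %*% w) / t_
  mvec <- sapply(1:3, function(k) as.vector(series$wss[, , k] %*% w) / t_)
  if (d[1] == 1L) mvec <- matrix(mvec, 1, 3)
  mnorm <- sqrt(rowSums(mvec^2))
  osi_v <- ifelse(tawss_v > 0,
                  pmin(pmax(0.5 * (1 - mnorm / tawss_v), 0), 0.5), NA_real_)
  # transverse component: |WSS . (n x e_m)| averaged over the cycle
  degen <- mnorm <= .Machine$double.eps * pmax(apply(mags, 1, max), 1)
  e_m <- mvec / ifelse(mnorm > 0, mnorm, 1)
  p <- cbind(mesh$normals[, 2] * e_m[, 3] - mesh$normals[, 3] * e_m[, 2],
             mesh$normals[, 3] * e_m[, 1] - mesh$normals[, 1] * e_m[, 3],
             mesh$normals[, 1] * e_m[, 2] - mesh$normals[, 2] * e_m[, 1])
  perp <- abs(series$wss[, , 1] * p[, 1] + series$wss[, , 2] * p[, 2] +
                series$wss[, , 3] * p[, 3])
  if (d[1] == 1L) perp <- matrix(perp, 1, d[2])
  trans_v <- as.vector(perp %*% w) / t_
  trans_v[degen] <- NA_real_
  ositr_v <- ositr(trans_v, tawss_v)
  rrt_v <- rrt(tawss_v, osi_v, k = rrt_k)
  out <- tibble::tibble(
    node = seq_len(d[1]),
    tawss = tawss_v,
    osi = osi_v,
    rrt = rrt_v,
    transwss = trans_v,
    ositr = ositr_v,
    zone = classify_zones(tawss_v, low, high),
    valid = !degen & tawss_v > 0
  )
  if (!is.null(axial)) {
    if (is.null(dim(axial))) axial <- matrix(axial, d[1], 3, byrow = TRUE)
    alen <- sqrt(rowSums(axial^2))
    cosang <- pmin(pmax(abs(rowSums(e_m * axial / alen)), 0), 1)
    ang <- acos(cosang) * 180 / pi
    ang[degen] <- NA_real_
    out$washing_deg <- ang
    out$washing <- ifelse(is.na(ang), NA_character_,
                          ifelse(ang > 45, "circumferential", "axial"))
  }
  attr(out, "thresholds") <- c(low = low, high = high)
  attr(out, "rrt_k") <- rrt_k
  attr(out, "period") <- series$period
  class(out) <- c("hemo_indices", class(out))
  out
}

#' @method tidy hemo_indices
#' @export
tidy.hemo_indices <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = c("tawss", "osi", "rrt", "transwss", "ositr"),
                      names_to = "index", values_to = "value")
}

#' @method glance hemo_indices
#' @export
glance.hemo_indices <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::tibble(
    n_nodes = nrow(x),
    n_valid = sum(x$valid),
    mean_tawss = mean(x$tawss),
    max_tawss = max(x$tawss),
    mean_osi = mean(x$osi, na.rm = TRUE),
    max_ositr = suppressWarnings(max(x$ositr, na.rm = TRUE)),
    frac_low = mean(x$zone == "low"),
    frac_high = mean(x$zone == "high"),
    low_threshold = thr[["low"]],
    high_threshold = thr[["high"]]
  )
}
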