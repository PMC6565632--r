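#' Blood fluid properties
#'
#' Density and dynamic viscosity of blood treated as an isotropic,
#' homogeneous, incompressible Newtonian fluid. Defaults are the standard
#' whole-blood values rho = 1050 kg/m^3 and mu = 3.5e-3 kg/(m s).
#'
#' @param rho density (kg/m^3), > 0.
#' @param mu dynamic viscosity (kg/(m s)), > 0.
#' @return list of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1050, mu = 3.5e-3) {
  if (rho <= 0 || mu <= 0) stop("rho and mu must be strictly positive")
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Pulsatile tube-flow case (Womersley problem)
#'
#' Fully developed unsteady flow of a Newtonian fluid in a rigid straight
#' circular tube driven by a periodic axial pressure gradient. The forcing
#' is `-dp/dx = Re{ sum_k G_k exp(i k w t) }` with `w = 2 pi / T`; harmonic
#' 0 is the steady part (real). The convective term vanishes identically in
#' this unidirectional reduction and incompressibility holds by
#' construction, so the axial momentum balance reduces to a radial
#' diffusion equation with exact Bessel-function solutions.
#'
#' @param radius tube radius R (m), > 0.
#' @param period cycle period T (s), > 0.
#' @param harmonics complex vector of pressure-gradient amplitudes G_k
#'   (Pa/m), element 1 = harmonic 0 (steady), element 2 = harmonic 1, ...
#'   At least the steady harmonic must be present.
#' @param fluid a [fluid_properties()].
#' @return list of class `womersley_case`.
#' @export
womersley_case <- function(radius, period, harmonics,
                           fluid = fluid_properties()) {
  if (radius <= 0 || period <= 0) stop("radius and period must be positive")
  if (length(harmonics) < 1L) stop("at least the steady harmonic is required")
  harmonics <- as.complex(harmonics)
  structure(list(radius = radius, period = period,
                 harmonics = harmonics, fluid = fluid),
            class = "womersley_case")
}

#' Read a pulsatile tube-flow case from YAML or JSON
#'
#' Expected keys: `radius_m`, `period_s`, `fluid: {rho, mu}` and
#' `harmonics`: a list of `{k, amplitude_pa_per_m, phase_deg}` entries.
#'
#' @param path file path (.yaml/.yml/.json).
#' @return a [womersley_case()].
#' @export
read_womersley_case <- function(path) {
  spec <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  ks <- vapply(spec$harmonics, function(h) as.integer(h$k), integer(1))
  g <- complex(modulus = vapply(spec$harmonics,
                                function(h) as.numeric(h$amplitude_pa_per_m),
                                numeric(1)),
               argument = vapply(spec$harmonics,
                                 function(h) as.numeric(h$phase_deg %||% 0),
                                 numeric(1)) * pi / 180)
  harm <- complex(real = numeric(max(ks) + 1L))
  harm[ks + 1L] <- g
  fl <- fluid_properties(spec$fluid$rho %||% 1050, spec$fluid$mu %||% 3.5e-3)
  womersley_case(spec$radius_m, spec$period_s, harm, fl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Womersley number of harmonic k
#'
#' `alpha_k = R sqrt(k w rho / mu)` with `w = 2 pi / T`: the ratio of the
#' tube radius to the oscillatory (Stokes) boundary-layer thickness of
#' harmonic k.
#'
#' @param case a [womersley_case()].
#' @param k harmonic index, >= 1.
#' @return dimensionless Womersley number.
#' @export
womersley_number <- function(case, k = 1) {
  if (any(k < 1)) stop("the Womersley number is defined for harmonics k >= 1")
  omega <- 2 * pi / case$period
  case$radius * sqrt(k * omega * case$fluid$rho / case$fluid$mu)
}

# J0 and J1 of complex argument by the ascending power series; adequate for
# the |z| <~ 40 reached at aortic scale (the argument lies on the 135-degree
# ray where J0 grows, so the series does not cancel catastrophically)
besselJ0_c <- function(z) {
  term <- rep(1 + 0i, length(z))
  s <- term
  q <- (z / 2)^2
  for (m in 1:250) {
    term <- -term * q / m^2
    s <- s + term
    if (all(Mod(term) < 1e-18 * (Mod(s) + 1e-300))) break
  }
  s
}

besselJ1_c <- function(z) {
  term <- z / 2
  s <- term
  q <- (z / 2)^2
  for (m in 1:250) {
    term <- -term * q / (m * (m + 1))
    s <- s + term
    if (all(Mod(term) < 1e-18 * (Mod(s) + 1e-300))) break
  }
  s
}

#' Exact axial velocity of pulsatile tube flow
#'
#' The steady harmonic contributes the parabolic Poiseuille profile
#' `G0 (R^2 - r^2) / (4 mu)`; each harmonic k >= 1 contributes the classical
#' Womersley profile `Re{ G_k / (i rho k w) (1 - J0(L r/R)/J0(L)) e^{ikwt} }`
#' with `L = i^{3/2} alpha_k`.
#'
#' @param case a [womersley_case()].
#' @param r radial positions (m) in `[0, R]`.
#' @param t times (s).
#' @return matrix `length(r) x length(t)` of axial velocities (m/s).
#' @export
analytic_velocity <- function(case, r, t) {
  R <- case$radius
  if (any(r < 0 | r > R)) stop("radial positions must lie in [0, R]")
  mu <- case$fluid$mu; rho <- case$fluid$rho
  omega <- 2 * pi / case$period
  g <- case$harmonics
  u <- outer(Re(g[1]) * (R^2 - r^2) / (4 * mu), rep(1, length(t)))
  for (k in seq_len(length(g) - 1L)) {
    if (g[k + 1L] == 0) next
    lam <- womersley_number(case, k) * exp(3i * pi / 4)
    prof <- g[k + 1L] / (1i * rho * k * omega) *
      (1 - besselJ0_c(lam * r / R) / besselJ0_c(lam))
    u <- u + Re(outer(prof, exp(1i * k * omega * t)))
  }
  u
}

#' Exact wall shear stress of pulsatile tube flow
#'
#' `tau_w(t) = -mu du/dr` at `r = R`: the steady part is `G0 R / 2` (the
#' force balance on the tube), harmonic k contributes
#' `Re{ G_k (R / L) J1(L) / J0(L) e^{ikwt} }` with `L = i^{3/2} alpha_k`.
#' Positive values point along the (forward) pressure-gradient direction.
#'
#' @param case a [womersley_case()].
#' @param t times (s).
#' @return numeric vector of signed wall shear stress (Pa).
#' @export
analytic_wall_shear <- function(case, t) {
  R <- case$radius
  omega <- 2 * pi / case$period
  g <- case$harmonics
  tau <- rep(Re(g[1]) * R / 2, length(t))
  for (k in seq_len(length(g) - 1L)) {
    if (g[k + 1L] == 0) next
    lam <- womersley_number(case, k) * exp(3i * pi / 4)
    amp <- g[k + 1L] * (R / lam) * besselJ1_c(lam) / besselJ0_c(lam)
    tau <- tau + Re(amp * exp(1i * k * omega * t))
  }
  tau
}

#' Crank-Nicolson solver for pulsatile tube flow
#'
#' Independent finite-difference solution of the radial diffusion equation
#' `du/dt = G(t)/rho + nu (u'' + u'/r)` with symmetry at the axis and
#' no-slip at the wall, marched from rest until the start-up transient has
#' decayed. Second order in both `dr` and `dt`; wall shear from a one-sided
#' second-order gradient stencil. Serves as the numerical oracle for
#' [analytic_velocity()] / [analytic_wall_shear()].
#'
#' @param case a [womersley_case()].
#' @param n_r number of radial intervals (>= 8); the grid has `n_r + 1`
#'   points including axis and wall.
#' @param n_t time steps per cycle.
#' @param cycles number of cycles marched (>= 3); the final cycle is
#'   returned.
#' @param stability_tol relative growth of cycle kinetic energy beyond
#'   which the march is declared unstable.
#' @return list of class `womersley_fd` with `r`, `times` (within `[0, T)`),
#'   `u` (matrix `(n_r + 1) x n_t`), `wss` (Pa, per time), and
#'   `periodicity_residual` (relative L2 change between the last two
#'   cycles).
#' @export
fd_solver <- function(case, n_r = 64, n_t = 256, cycles = 5,
                      stability_tol = 10) {
  if (n_r < 8) stop("radial resolution must be at least 8 intervals")
  if (cycles < 3) stop("run at least 3 cycles to shed the initial transient")
  R <- case$radius; T_ <- case$period
  nu <- case$fluid$mu / case$fluid$rho
  rho <- case$fluid$rho
  dr <- R / n_r
  dt <- T_ / n_t
  r <- seq(0, R, length.out = n_r + 1L)
  # unknowns u_0 .. u_{n_r-1}; u_{n_r} = 0 (no-slip)
  n <- n_r
  main <- numeric(n); lower <- numeric(n - 1); upper <- numeric(n - 1)
  # L matrix of nu * (u'' + u'/r); axis row uses the r -> 0 limit 4(u1-u0)/dr^2
  main[1] <- -4 * nu / dr^2
  upper[1] <- 4 * nu / dr^2
  for (i in 2:n) {
    ri <- r[i]
    main[i] <- -2 * nu / dr^2
    lower[i - 1] <- nu / dr^2 - nu / (2 * ri * dr)
    if (i < n) upper[i] <- nu / dr^2 + nu / (2 * ri * dr)
  }
  band <- function(scale) {
    Matrix::bandSparse(n, n, k = -1:1,
                       diagonals = list(lower * scale, 1 + main * scale,
                                        upper * scale))
  }
  A <- band(-dt / 2)           # I - dt/2 L
  B <- band(+dt / 2)           # I + dt/2 L
  luA <- Matrix::lu(methods::as(A, "CsparseMatrix"))
  forcing <- function(t) {
    g <- case$harmonics
    omega <- 2 * pi / T_
    val <- Re(g[1])
    for (k in seq_len(length(g) - 1L)) {
      val <- val + Re(g[k + 1L] * exp(1i * k * omega * t))
    }
    val / rho
  }
  u <- numeric(n)
  prev_cycle <- NULL
  energy0 <- NA_real_
  store <- matrix(0, n + 1L, n_t)
  for (cy in seq_len(cycles)) {
    for (j in seq_len(n_t)) {
      t0 <- (cy - 1) * T_ + (j - 1) * dt
      b <- as.vector(B %*% u) + dt / 2 * (forcing(t0) + forcing(t0 + dt))
      u <- as.vector(Matrix::solve(luA, b))
      if (!all(is.finite(u))) stop("finite-difference march became unstable")
      if (cy == cycles) store[, j] <- c(u, 0)
    }
    en <- sum(u^2)
    if (cy == 1) energy0 <- max(en, .Machine$double.xmin)
    if (en > stability_tol^2 * energy0 && cy > 1) {
      stop("finite-difference march became unstable (energy growth)")
    }
    if (cy == cycles - 1L) prev_cycle <- u
  }
  resid <- if (!is.null(prev_cycle)) {
    sqrt(sum((u - prev_cycle)^2) / max(sum(u^2), .Machine$double.xmin))
  } else NA_real_
  # stored sample j holds u at time j*dt of the final cycle; report times
  # within [0, T) by wrapping the t = T sample to t = 0
  times <- (seq_len(n_t) %% n_t) * dt
  ord <- order(times)
  store <- store[, ord, drop = FALSE]
  times <- times[ord]
  wss <- -case$fluid$mu *
    (3 * store[n + 1L, ] - 4 * store[n, ] + store[n - 1L, ]) / (2 * dr)
  structure(list(r = r, times = times, u = store, wss = wss,
                 periodicity_residual = resid, case = case),
            class = "womersley_fd")
}

#' @method glance womersley_fd
#' @export
glance.womersley_fd <- function(x, ...) {
  tibble::tibble(
    n_r = length(x$r) - 1L,
    n_t = length(x$times),
    periodicity_residual = x$periodicity_residual,
    peak_wss = max(abs(x$wss)),
    mean_wss = mean(x$wss)
  )
}

#' @method tidy womersley_fd
#' @export
tidy.womersley_fd <- function(x, ...) {
  tibble::tibble(time = x$times, wss = x$wss,
                 centerline_velocity = x$u[1, ])
}
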