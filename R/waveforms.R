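#' Inflow waveform as a truncated Fourier series
#'
#' Represents the cross-section mean inlet velocity over one cardiac cycle
#' as `v(t) = Re{ sum_k c_k exp(i k w t) }`, `w = 2 pi / T`, with `c_0` the
#' (real) cycle mean. Carries named analysis instants; the defaults are the
#' four instants used throughout the analysis (early/mid/late systole and
#' early diastole).
#'
#' @param period cycle period T (s).
#' @param coefficients complex vector, element 1 = harmonic 0 (real mean).
#' @param time_points named numeric vector of analysis instants in
#'   `[0, period)`.
#' @return object of class `inflow_waveform`.
#' @export
inflow_waveform <- function(period, coefficients,
                            time_points = c(T1 = 0.11, T2 = 0.22,
                                            T3 = 0.36, T4 = 0.58)) {
  if (period <= 0) stop("period must be positive")
  if (any(time_points < 0 | time_points >= period)) {
    stop("named time points must lie within [0, period)")
  }
  coefficients <- as.complex(coefficients)
  coefficients[1] <- complex(real = Re(coefficients[1]))
  structure(list(period = period, coefficients = coefficients,
                 time_points = time_points),
            class = "inflow_waveform")
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf(
    "<inflow_waveform> period %.3g s, %d harmonics, mean %.5g m/s\n",
    x$period, length(x$coefficients) - 1L, Re(x$coefficients[1])
  ))
  invisible(x)
}

#' Evaluate an inflow waveform
#'
#' @param waveform an [inflow_waveform()].
#' @param t times (s); evaluated modulo the period.
#' @return cross-section mean velocity (m/s) at each time.
#' @export
evaluate_waveform <- function(waveform, t) {
  omega <- 2 * pi / waveform$period
  cs <- waveform$coefficients
  v <- rep(Re(cs[1]), length(t))
  for (k in seq_len(length(cs) - 1L)) {
    v <- v + Re(cs[k + 1L] * exp(1i * k * omega * t))
  }
  v
}

# aortic-like template on [0, T): raised-sine systolic pulse peaking near
# T/4, small dicrotic dip, low diastolic baseline; returned as Fourier
# coefficients fitted from a dense uniform sampling
aortic_template_coefficients <- function(period, n_harmonics = 12) {
  n <- 512L
  t <- seq(0, period, length.out = n + 1L)[-(n + 1L)]
  ts <- 0.45 * period                       # systolic duration: peak at ~T/4
  v <- 0.12 + ifelse(t < ts, sin(pi * t / ts)^2, 0) -
    0.10 * ifelse(t >= ts & t < ts + 0.12 * period,
                  sin(pi * (t - ts) / (0.12 * period))^2, 0)
  fit_fourier(v, period, n_harmonics)
}

fit_fourier <- function(samples, period, n_harmonics) {
  n <- length(samples)
  X <- stats::fft(samples)
  ks <- seq_len(n_harmonics)
  c(complex(real = Re(X[1]) / n), 2 * X[ks + 1L] / n)
}

#' Fit Fourier coefficients to uniformly sampled waveform values
#'
#' @param samples values on a uniform grid `t_j = j T / n`, `j = 0..n-1`.
#' @param period cycle period (s).
#' @param n_harmonics number of harmonics retained (`< n/2`).
#' @return an [inflow_waveform()].
#' @export
fit_waveform <- function(samples, period, n_harmonics) {
  if (n_harmonics >= length(samples) / 2) {
    stop("n_harmonics must be below half the sample count")
  }
  inflow_waveform(period, fit_fourier(samples, period, n_harmonics))
}

#' Synthesize an aortic-like inflow waveform with a prescribed mean
#'
#' Rescales a band-limited aortic-like template (systolic peak near T/4,
#' low diastolic flow, brief dicrotic reverse dip) so its cycle mean equals
#' `target_mean`. The default target is the mean velocity that closes the
#' inlet Reynolds-number balance Re = rho U D / mu = 1090 for the default
#' 32 mm inlet, i.e. about 0.11354 m/s.
#'
#' @param target_mean desired cycle-mean velocity (m/s), > 0.
#' @param period cycle period (s), default 0.8.
#' @param n_harmonics harmonics retained in the template (default 12).
#' @param inlet an [inlet_spec()] used only to derive the default target.
#' @return an [inflow_waveform()] whose cycle mean equals `target_mean`.
#' @export
synthesize_waveform <- function(target_mean = NULL, period = 0.8,
                                n_harmonics = 12, inlet = inlet_spec()) {
  if (is.null(target_mean)) {
    target_mean <- 1090 * inlet$fluid$mu / (inlet$fluid$rho * inlet$diameter)
  }
  if (target_mean <= 0) stop("target mean velocity must be positive")
  cs <- aortic_template_coefficients(period, n_harmonics)
  scale <- target_mean / Re(cs[1])
  inflow_waveform(period, cs * scale)
}

#' Inlet specification
#'
#' @param diameter inlet diameter D (m), default 0.032 (32 mm aorta).
#' @param fluid a [fluid_properties()].
#' @return object of class `inlet_spec`.
#' @export
inlet_spec <- function(diameter = 0.032, fluid = fluid_properties()) {
  if (diameter <= 0) stop("inlet diameter must be positive")
  structure(list(diameter = diameter, fluid = fluid), class = "inlet_spec")
}

#' Inlet Reynolds number
#'
#' `Re = rho U D / mu` from the cycle-mean inlet velocity and the inlet
#' diameter.
#'
#' @param mean_velocity cycle-mean velocity U (m/s), > 0.
#' @param inlet an [inlet_spec()].
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(mean_velocity, inlet = inlet_spec()) {
  if (mean_velocity <= 0) stop("mean velocity must be positive")
  inlet$fluid$rho * mean_velocity * inlet$diameter / inlet$fluid$mu
}

#' Waveform values at the named analysis instants
#'
#' @param waveform an [inflow_waveform()].
#' @param labels which named instants to sample (default: all).
#' @return tibble with columns `label`, `time_s`, `velocity`.
#' @export
sample_time_points <- function(waveform, labels = NULL) {
  tp <- waveform$time_points
  if (is.null(labels)) labels <- names(tp)
  missing <- setdiff(labels, names(tp))
  if (length(missing)) {
    stop(sprintf("undefined time point label(s): %s",
                 paste(missing, collapse = ", ")))
  }
  tt <- tp[labels]
  tibble::tibble(label = labels, time_s = unname(tt),
                 velocity = evaluate_waveform(waveform, unname(tt)))
}

#' Export a sampled waveform as CSV
#'
#' @param waveform an [inflow_waveform()].
#' @param path output CSV.
#' @param n number of uniform samples over one period.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path, n = 200) {
  t <- seq(0, waveform$period, length.out = n + 1L)[-(n + 1L)]
  readr::write_csv(tibble::tibble(time_s = t,
                                  velocity = evaluate_waveform(waveform, t)),
                   path)
  invisible(path)
}

#' @method autoplot inflow_waveform
#' @export
autoplot.inflow_waveform <- function(object, n = 400, ...) {
  t <- seq(0, object$period, length.out = n)
  df <- tibble::tibble(time = t, velocity = evaluate_waveform(object, t))
  pts <- sample_time_points(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$velocity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$time_s, y = .data$velocity),
                        colour = "red", size = 2) +
    ggplot2::geom_text(data = pts,
                       ggplot2::aes(x = .data$time_s, y = .data$velocity,
                                    label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "time (s)", y = "mean inlet velocity (m/s)",
                  title = "Inflow waveform with analysis instants")
}
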