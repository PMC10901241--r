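#' Band-limited excitation pulses
#'
#' Two pulse shapes cover the two modalities. The photoacoustic pulse is
#' bipolar (the reconstruction chain applies no envelope detection or
#' non-negativity, so the N-shaped pressure transient survives into the
#' image): it is the time derivative of a Gaussian-modulated cosine, with the
#' modulation frequency and envelope width calibrated so that the spectral
#' magnitude peaks at the stated center frequency and the -6 dB fractional
#' bandwidth matches the stated value. The pulse-echo ultrasound pulse is a
#' plain Gaussian-modulated cosine at the transducer center frequency.
#'
#' @param center_frequency Spectral peak frequency in Hz.
#' @param fractional_bandwidth -6 dB bandwidth / center frequency.
#' @param shape `"derivative_gaussian"` (PA) or
#'   `"gaussian_modulated_cosine"` (US).
#' @return A `pa_wavelet`: a list with a vectorized evaluator `fun(t)`
#'   (peak |amplitude| 1, centered at t = 0), the spectral parameters, and
#'   the half-support `t_half` beyond which the pulse is negligible.
#' @export
make_wavelet <- function(center_frequency = 5e6, fractional_bandwidth = 0.7,
                         shape = c("derivative_gaussian",
                                   "gaussian_modulated_cosine")) {
  shape <- match.arg(shape)
  fc <- center_frequency
  bw <- fractional_bandwidth
  if (fc <= 0) stop("center_frequency must be positive", call. = FALSE)
  if (bw <= 0 || bw >= 2) stop("fractional_bandwidth must be in (0, 2)", call. = FALSE)
  if (shape == "gaussian_modulated_cosine") {
    sigma_f <- bw * fc / (2 * sqrt(2 * log(2)))
    sigma_t <- 1 / (2 * pi * sigma_f)
    fun <- function(t) cos(2 * pi * fc * t) * exp(-t^2 / (2 * sigma_t^2))
    params <- list(fm = fc, sigma_t = sigma_t)
  } else {
    params <- calibrate_deriv_gaussian(fc, bw)
    sigma_t <- params$sigma_t
    fm <- params$fm
    raw <- function(t) {
      env <- exp(-t^2 / (2 * sigma_t^2))
      (-2 * pi * fm * sin(2 * pi * fm * t) - t / sigma_t^2 *
         cos(2 * pi * fm * t)) * env
    }
    tt <- seq(-6 * sigma_t, 6 * sigma_t, length.out = 4096)
    pk <- max(abs(raw(tt)))
    fun <- function(t) raw(t) / pk
  }
  structure(list(fun = fun, center_frequency = fc,
                 fractional_bandwidth = bw, shape = shape,
                 t_half = 6 * params$sigma_t, params = params),
            class = "pa_wavelet")
}

# Two-sided spectral magnitude of d/dt[cos(2 pi fm t) * gaussian(sigma_t)],
# up to a constant factor.
deriv_gauss_spectrum <- function(f, fm, sigma_t) {
  g <- function(u) exp(-2 * pi^2 * sigma_t^2 * u^2)
  2 * pi * abs(f) * (g(f - fm) + g(f + fm)) / 2
}

# Solve for (fm, sigma_t) so the spectral peak sits at fc and the -6 dB full
# width equals bw * fc. Ignoring the negative-frequency mirror term (down by
# exp(-2 fc fm / sigma_f^2), negligible at the bandwidths of interest), the
# one-sided spectrum f * exp(-(f - fm)^2 / (2 sigma_f^2)) peaks at fc exactly
# when fm = fc - sigma_f^2 / fc; the envelope width then follows from a
# single deterministic root find on the full two-sided spectrum.
calibrate_deriv_gaussian <- function(fc, bw) {
  width_at <- function(sigma_f) {
    fm <- fc - sigma_f^2 / fc
    sigma_t <- 1 / (2 * pi * sigma_f)
    mpk <- deriv_gauss_spectrum(fc, fm, sigma_t)
    half <- function(f) deriv_gauss_spectrum(f, fm, sigma_t) - mpk / 2
    f_lo <- stats::uniroot(half, interval = c(fc * 1e-9, fc),
                           tol = fc * 1e-10)$root
    f_hi <- stats::uniroot(half, interval = c(fc, fc * 8),
                           tol = fc * 1e-10)$root
    f_hi - f_lo
  }
  # keep fm > 0: sigma_f < fc, and the width is monotone in sigma_f
  sf <- stats::uniroot(function(sf) width_at(sf) - bw * fc,
                       interval = c(0.02 * bw * fc, min(0.9 * fc, bw * fc)),
                       tol = fc * 1e-10)$root
  list(fm = fc - sf^2 / fc, sigma_t = 1 / (2 * pi * sf))
}

#' Acquisition parameters
#'
#' Defaults: 40 MHz sampling, 2048 samples (covers ~38 mm one-way at
#' 1500 m/s), time origin at the laser pulse / transmit event.
#'
#' @param sampling_rate Samples per second.
#' @param n_samples Record length per channel.
#' @param t0 Time of the first sample relative to excitation, seconds.
#' @param speed_of_sound Medium sound speed used for propagation, m/s.
#' @return A `pa_acquisition` object.
#' @export
acquisition_params <- function(sampling_rate = 40e6, n_samples = 2048L,
                               t0 = 0, speed_of_sound = 1500) {
  if (sampling_rate <= 0 || n_samples < 1L)
    stop("sampling_rate and n_samples must be positive", call. = FALSE)
  if (speed_of_sound <= 0) stop("speed_of_sound must be positive", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 n_samples = as.integer(n_samples),
                 t0 = t0, speed_of_sound = speed_of_sound),
            class = "pa_acquisition")
}

new_channel_data <- function(samples, sampling_rate, t0, modality, geometry) {
  structure(list(samples = samples, sampling_rate = sampling_rate, t0 = t0,
                 modality = modality, geometry = geometry),
            class = "pa_channels")
}

#' @export
print.pa_channels <- function(x, ...) {
  cat(sprintf("<pa_channels> %s, %d elements x %d samples @ %.3g MHz\n",
              x$modality, nrow(x$samples), ncol(x$samples),
              x$sampling_rate / 1e6))
  invisible(x)
}

# Shared propagation kernel. Each source contributes a delayed copy of the
# pulse on each channel: amp * (r_ref / r)^spread_exp * w(t - tau_factor*r/c).
# The pulse has finite support, so only the sample window around each arrival
# is evaluated; accumulation uses rowsum over flattened (source, sample)
# pairs.
propagate <- function(src_xyz, src_amp, geometry, acq, wavelet,
                      tau_factor, spread_exp, r_ref = 1e-2) {
  fs <- acq$sampling_rate
  nyq_need <- 2 * geometry$center_frequency * (1 + geometry$fractional_bandwidth)
  if (fs <= nyq_need)
    stop("sampling_rate too low for the array passband", call. = FALSE)
  n_el <- n_elements(geometry)
  ns <- acq$n_samples
  out <- matrix(0, n_el, ns)
  if (nrow(src_xyz) == 0L) return(out)
  c0 <- acq$speed_of_sound
  Lw <- 2L * as.integer(ceiling(wavelet$t_half * fs)) + 2L
  offs <- 0:(Lw - 1L)
  for (i in seq_len(n_el)) {
    dx <- src_xyz[, 1] - geometry$element_positions[i, 1]
    dy <- src_xyz[, 2]
    dz <- src_xyz[, 3] - geometry$element_positions[i, 2]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r == 0))
      stop("source coincides with an element (zero distance)", call. = FALSE)
    tau <- tau_factor * r / c0
    a <- src_amp * (r_ref / r)^spread_exp
    if (!is.null(geometry$elevation_sigma))
      a <- a * exp(-dy^2 / (2 * geometry$elevation_sigma^2))^tau_factor
    idx0 <- as.integer(floor((tau - wavelet$t_half - acq$t0) * fs))
    idx <- outer(idx0, offs, "+")                  # 0-based sample indices
    arg <- (idx / fs + acq$t0) - tau               # tau recycles down columns
    val <- a * wavelet$fun(arg)
    ind <- as.vector(idx) + 1L
    val <- as.vector(val)
    keep <- ind >= 1L & ind <= ns
    if (any(keep)) {
      acc <- rowsum(val[keep], ind[keep])
      out[i, as.integer(rownames(acc))] <- acc
    }
  }
  out
}

warn_if_behind <- function(src_xyz, geometry) {
  ctr <- colMeans(geometry$element_positions)
  nrm <- colMeans(geometry$element_normals)
  nrm <- nrm / sqrt(sum(nrm^2))
  proj <- (src_xyz[, 1] - ctr[1]) * nrm[1] + (src_xyz[, 3] - ctr[2]) * nrm[2]
  if (any(proj < 0))
    warning("some sources lie behind the array face; included without occlusion",
            call. = FALSE)
}

#' Simulate photoacoustic channel data
#'
#' Each absorber emits the bipolar PA pulse at t = 0; element i records
#' \eqn{s_i(t) = \sum_k A_k \Phi(z_k) (r_{ref}/r_{ik}) w(t - r_{ik}/c)} with
#' 1/r spherical spreading and depth-dependent optical fluence
#' \eqn{\Phi(z) = e^{-\mu_{eff} z}} (surface fluence applied at z <= 0). The
#' model is exactly linear in absorber amplitudes; acoustic attenuation and
#' occlusion are not modeled. The reference distance r_ref = 1 cm makes
#' amplitudes dimensionless.
#'
#' @param phantom A `pa_phantom`.
#' @param geometry A `pa_array`.
#' @param acq A `pa_acquisition`.
#' @param wavelet Optional `pa_wavelet`; defaults to the bipolar PA pulse at
#'   the array's center frequency and bandwidth.
#' @return A `pa_channels` with modality `"PA"`.
#' @export
simulate_pa_channels <- function(phantom, geometry, acq = acquisition_params(),
                                 wavelet = NULL) {
  stopifnot(inherits(phantom, "pa_phantom"), inherits(geometry, "pa_array"),
            inherits(acq, "pa_acquisition"))
  if (is.null(wavelet))
    wavelet <- make_wavelet(geometry$center_frequency,
                            geometry$fractional_bandwidth,
                            "derivative_gaussian")
  ab <- phantom$absorbers
  src <- cbind(ab$x, ab$y, ab$z)
  if (nrow(ab)) {
    warn_if_behind(src, geometry)
    amp <- ab$amplitude * fluence_at(phantom$optics, pmax(ab$z, 0))
  } else amp <- numeric()
  samples <- propagate(src, amp, geometry, acq, wavelet,
                       tau_factor = 1, spread_exp = 1)
  new_channel_data(samples, acq$sampling_rate, acq$t0, "PA", geometry)
}

#' Simulate monostatic pulse-echo ultrasound channel data
#'
#' Per-element monostatic model: element i transmits at t = 0 and records
#' \eqn{s_i(t) = \sum_k R_k (r_{ref}/r_{ik})^2 w_{us}(t - 2 r_{ik}/c)} —
#' round-trip delay and two-way 1/r^2 spreading.
#'
#' @inheritParams simulate_pa_channels
#' @return A `pa_channels` with modality `"US"`.
#' @export
simulate_us_channels <- function(phantom, geometry, acq = acquisition_params(),
                                 wavelet = NULL) {
  stopifnot(inherits(phantom, "pa_phantom"), inherits(geometry, "pa_array"),
            inherits(acq, "pa_acquisition"))
  if (is.null(wavelet))
    wavelet <- make_wavelet(geometry$center_frequency,
                            geometry$fractional_bandwidth,
                            "gaussian_modulated_cosine")
  sc <- phantom$scatterers
  src <- cbind(sc$x, sc$y, sc$z)
  if (nrow(sc)) warn_if_behind(src, geometry)
  samples <- propagate(src, sc$reflectivity, geometry, acq, wavelet,
                       tau_factor = 2, spread_exp = 2)
  new_channel_data(samples, acq$sampling_rate, acq$t0, "US", geometry)
}

#' Noise and RF interference specification
#'
#' Models the two disturbances seen on real channel data: independent
#' Gaussian electronic noise per sample, and pulsed RF pickup appearing as a
#' common-mode burst — an identical short wavelet-shaped transient added to
#' every channel at each burst time, which beamforms into a sharp horizontal
#' line across the image.
#'
#' @param burst_times Times (seconds) of common-mode bursts.
#' @param burst_amplitude Peak amplitude of each burst (>= 0).
#' @param noise_std Standard deviation of the i.i.d. Gaussian noise (>= 0).
#' @param seed Integer seed for reproducibility.
#' @return A `pa_interference` object.
#' @export
interference_spec <- function(burst_times = numeric(), burst_amplitude = 0,
                              noise_std = 0, seed = 1L) {
  if (burst_amplitude < 0 || noise_std < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(burst_times = burst_times, burst_amplitude = burst_amplitude,
                 noise_std = noise_std, seed = as.integer(seed)),
            class = "pa_interference")
}

#' Add Gaussian noise and common-mode bursts to channel data
#'
#' @param channels A `pa_channels`.
#' @param spec A `pa_interference`.
#' @return The corrupted `pa_channels`. With zero amplitudes the input is
#'   returned bitwise unchanged.
#' @export
add_noise_and_interference <- function(channels, spec) {
  stopifnot(inherits(channels, "pa_channels"), inherits(spec, "pa_interference"))
  s <- channels$samples
  fs <- channels$sampling_rate
  ns <- ncol(s)
  t_axis <- channels$t0 + (0:(ns - 1)) / fs
  if (spec$burst_amplitude > 0 && length(spec$burst_times)) {
    w <- make_wavelet(channels$geometry$center_frequency,
                      channels$geometry$fractional_bandwidth,
                      "derivative_gaussian")
    for (bt in spec$burst_times) {
      if (bt < t_axis[1] || bt > t_axis[ns]) {
        warning(sprintf("burst time %g s outside record; ignored", bt),
                call. = FALSE)
        next
      }
      burst <- spec$burst_amplitude * w$fun(t_axis - bt)
      s <- s + matrix(burst, nrow(s), ns, byrow = TRUE)
    }
  }
  if (spec$noise_std > 0) {
    s <- s + withr::with_seed(spec$seed,
      matrix(stats::rnorm(length(s), sd = spec$noise_std), nrow(s), ns))
  }
  channels$samples <- s
  channels
}

#' Remove common-mode interference by across-channel mean subtraction
#'
#' A signal identical on all channels is eliminated exactly; a localized
#' source contributes to each channel at a different delay, so its energy is
#' nearly untouched for a large element count.
#'
#' @param channels A `pa_channels` with at least 2 elements.
#' @return The cleaned `pa_channels`.
#' @export
suppress_common_mode <- function(channels) {
  stopifnot(inherits(channels, "pa_channels"))
  if (nrow(channels$samples) < 2L)
    stop("need >= 2 elements to estimate the common mode", call. = FALSE)
  cm <- colMeans(channels$samples)
  channels$samples <- sweep(channels$samples, 2L, cm)
  channels
}

#' Zero-phase high-pass filtering of channel data
#'
#' 4th-order Butterworth high-pass applied forward-backward
#' (`signal::filtfilt`), removing low-frequency noise without shifting pulse
#' arrival times. Default cutoff 0.5 MHz.
#'
#' @param channels A `pa_channels`.
#' @param cutoff Cutoff frequency in Hz, in (0, Nyquist).
#' @param order Butterworth order (applied twice by filtfilt).
#' @return The filtered `pa_channels`.
#' @export
highpass_filter <- function(channels, cutoff = 0.5e6, order = 4L) {
  stopifnot(inherits(channels, "pa_channels"))
  nyq <- channels$sampling_rate / 2
  if (cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must be in (0, Nyquist)", call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  n <- ncol(channels$samples)
  # odd-reflection padding so filter transients decay outside the record
  np <- min(n - 1L, as.integer(ceiling(3 * channels$sampling_rate / cutoff)))
  channels$samples <- t(apply(channels$samples, 1L, function(row) {
    head_pad <- 2 * row[1] - row[(np + 1L):2L]
    tail_pad <- 2 * row[n] - row[(n - 1L):(n - np)]
    out <- signal::filtfilt(bf, c(head_pad, row, tail_pad))
    out[(np + 1L):(np + n)]
  }))
  channels
}
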