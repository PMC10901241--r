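test_that("pulse spectra peak at fc with the stated -6 dB bandwidth", {
  fs <- 200e6
  n <- 16384
  tt <- (seq_len(n) - n / 2) / fs
  fr <- (0:(n / 2 - 1)) * fs / n
  for (shape in c("derivative_gaussian", "gaussian_modulated_cosine")) {
    w <- make_wavelet(5e6, 0.7, shape)
    sp <- Mod(stats::fft(w$fun(tt)))[1:(n / 2)]
    f_peak <- fr[which.max(sp)]
    expect_lt(abs(f_peak - 5e6) / 5e6, 0.02)
    width <- diff(range(fr[sp >= max(sp) / 2]))
    expect_lt(abs(width / 5e6 - 0.7) / 0.7, 0.05)
  }
  # the PA pulse is bipolar and antisymmetric: zero at its center
  wpa <- make_wavelet(5e6, 0.7, "derivative_gaussian")
  expect_equal(wpa$fun(0), 0)
  expect_equal(wpa$fun(1e-7), -wpa$fun(-1e-7), tolerance = 1e-12)
})

test_that("PA channels encode time of flight, spreading and superposition", {
  arr <- make_linear_array(n_elements = 1L)
  acq <- acquisition_params()

  empty <- make_phantom()
  expect_true(all(simulate_pa_channels(empty, arr, acq)$samples == 0))

  ph <- point_phantom(z = 15e-3)
  ch <- simulate_pa_channels(ph, arr, acq)
  s <- ch$samples[1, ]
  # bipolar pulse centered at t = r/c = 10 us: zero crossing between the
  # extrema lies within one sample of 10 us
  i_hi <- which.max(s); i_lo <- which.min(s)
  t_cross <- mean(c(i_hi, i_lo) - 1) / acq$sampling_rate
  expect_lt(abs(t_cross - 10e-6), 1 / acq$sampling_rate)

  # linearity: doubling amplitudes doubles every sample exactly
  ph2 <- point_phantom(z = 15e-3, amplitude = 2)
  expect_identical(simulate_pa_channels(ph2, arr, acq)$samples, 2 * ch$samples)

  # superposition: two co-distant absorbers = exactly twice one absorber
  two <- make_phantom(data.frame(x = c(5e-3, -5e-3), y = 0, z = 15e-3,
                                 amplitude = 1, radius = 0),
                      optics = optical_model(0))
  expect_equal(simulate_pa_channels(two, arr, acq)$samples[1, ],
               2 * simulate_pa_channels(point_phantom(5e-3, 15e-3), arr,
                                        acq)$samples[1, ],
               tolerance = 1e-12)

  # absorber order is irrelevant
  sc <- make_phantom(data.frame(x = c(1e-3, -2e-3, 0), y = 0,
                                z = c(10e-3, 20e-3, 30e-3),
                                amplitude = c(1, 2, 3), radius = 0),
                     optics = optical_model(0))
  sc_rev <- make_phantom(sc$absorbers[3:1, ], optics = optical_model(0))
  expect_identical(simulate_pa_channels(sc, arr, acq)$samples,
                   simulate_pa_channels(sc_rev, arr, acq)$samples)

  # 1/r spreading against the closed form
  near <- max(abs(simulate_pa_channels(point_phantom(z = 10e-3), arr, acq)$samples))
  far <- max(abs(simulate_pa_channels(point_phantom(z = 30e-3), arr, acq)$samples))
  expect_equal(near / far, 3, tolerance = 0.01)

  expect_error(simulate_pa_channels(point_phantom(z = 0), arr, acq), "distance")
  behind <- make_phantom(data.frame(x = 0, y = 0, z = -5e-3, amplitude = 1,
                                    radius = 0), optics = optical_model(0))
  expect_warning(simulate_pa_channels(behind, arr, acq), "behind")
})

test_that("US channels are monostatic: round-trip delay and 1/r^2 spreading", {
  arr <- make_linear_array(n_elements = 1L)
  acq <- acquisition_params()
  expect_true(all(simulate_us_channels(make_phantom(), arr, acq)$samples == 0))

  ph <- make_phantom(scatterers = data.frame(x = 0, y = 0, z = 20e-3,
                                             reflectivity = 1),
                     optics = optical_model(0))
  ch <- simulate_us_channels(ph, arr, acq)
  expect_identical(ch$modality, "US")
  s <- ch$samples[1, ]
  t_echo <- (which.max(abs(s)) - 1) / acq$sampling_rate
  expect_lt(abs(t_echo - 2 * 20e-3 / 1500), 1 / acq$sampling_rate)

  ph3 <- make_phantom(scatterers = transform(ph$scatterers, reflectivity = 3),
                      optics = optical_model(0))
  expect_identical(simulate_us_channels(ph3, arr, acq)$samples, 3 * ch$samples)

  near <- max(abs(simulate_us_channels(
    make_phantom(scatterers = data.frame(x = 0, y = 0, z = 10e-3,
                                         reflectivity = 1),
                 optics = optical_model(0)), arr, acq)$samples))
  expect_equal(near / max(abs(s)), 4, tolerance = 0.01)
})

test_that("forward model is linear in phantom amplitude mixtures", {
  arr <- make_linear_array(n_elements = 8L)
  acq <- acquisition_params(n_samples = 1024L)
  base <- data.frame(x = c(0, 2e-3), y = 0, z = c(12e-3, 18e-3),
                     amplitude = c(1, 0.5), radius = 0)
  mix <- function(a, b) make_phantom(transform(base, amplitude = a * c(1, 0) +
                                                 b * c(0, 0.5)),
                                     optics = optical_model(0))
  s_a <- simulate_pa_channels(mix(1, 0), arr, acq)$samples
  s_b <- simulate_pa_channels(mix(0, 1), arr, acq)$samples
  s_mix <- simulate_pa_channels(mix(2, 3), arr, acq)$samples
  expect_equal(s_mix, 2 * s_a + 3 * s_b, tolerance = 1e-12)
})

test_that("noise and common-mode interference behave as specified", {
  arr <- make_linear_array(n_elements = 16L)
  acq <- acquisition_params(n_samples = 1024L)
  ch <- simulate_pa_channels(point_phantom(), arr, acq)

  # zero spec leaves data bitwise unchanged
  expect_identical(add_noise_and_interference(ch, interference_spec())$samples,
                   ch$samples)

  # a pure common-mode burst is identical on every channel
  zero <- ch; zero$samples[] <- 0
  bursty <- add_noise_and_interference(
    zero, interference_spec(burst_times = 10e-6, burst_amplitude = 1))
  expect_gt(max(abs(bursty$samples)), 0)
  diffs <- apply(bursty$samples, 2, function(col) diff(range(col)))
  expect_true(all(diffs == 0))

  # seeded noise has the requested standard deviation (>= 1e5 samples)
  big <- acquisition_params(n_samples = 8192L)
  zch <- simulate_pa_channels(make_phantom(), make_linear_array(16L), big)
  noisy <- add_noise_and_interference(
    zch, interference_spec(noise_std = 0.3, seed = 7L))
  expect_lt(abs(stats::sd(noisy$samples) - 0.3) / 0.3, 0.05)
  again <- add_noise_and_interference(
    zch, interference_spec(noise_std = 0.3, seed = 7L))
  expect_identical(noisy$samples, again$samples)

  expect_warning(
    add_noise_and_interference(
      ch, interference_spec(burst_times = 1, burst_amplitude = 1)),
    "outside")
})

test_that("common-mode suppression removes exactly the across-channel mean", {
  arr <- make_linear_array(n_elements = 16L)
  acq <- acquisition_params(n_samples = 512L)
  zero <- simulate_pa_channels(make_phantom(), arr, acq)
  bursty <- add_noise_and_interference(
    zero, interference_spec(burst_times = 8e-6, burst_amplitude = 2))
  cleaned <- suppress_common_mode(bursty)
  expect_true(all(abs(cleaned$samples) < 1e-12))

  ch <- simulate_pa_channels(point_phantom(), arr, acq)
  resid <- suppress_common_mode(ch)
  expect_lt(max(abs(colMeans(resid$samples))), 1e-12)

  single <- simulate_pa_channels(point_phantom(), make_linear_array(1L), acq)
  expect_error(suppress_common_mode(single), "2 elements")
})

test_that("high-pass filter kills DC, passes the band, and is zero-phase", {
  arr <- make_linear_array(n_elements = 2L)
  acq <- acquisition_params(n_samples = 2048L)
  fs <- acq$sampling_rate
  t <- (0:2047) / fs
  base <- simulate_pa_channels(make_phantom(), arr, acq)

  dc <- base; dc$samples[] <- 1
  expect_lt(max(abs(highpass_filter(dc, 0.5e6)$samples)), 1e-3)

  tone <- base
  tone$samples[1, ] <- sin(2 * pi * 5e6 * t)
  tone$samples[2, ] <- sin(2 * pi * 5e6 * t)
  out <- highpass_filter(tone, 0.5e6)$samples[1, 500:1500]
  gain_db <- 20 * log10(max(abs(out)))
  expect_lt(abs(gain_db), 1)

  # zero phase: the peak of a band-limited pulse does not move
  ch <- simulate_pa_channels(point_phantom(), arr, acq)
  pk_before <- which.max(abs(ch$samples[1, ]))
  pk_after <- which.max(abs(highpass_filter(ch, 0.5e6)$samples[1, ]))
  expect_lte(abs(pk_after - pk_before), 1L)

  expect_error(highpass_filter(ch, 25e6), "Nyquist")
  expect_error(highpass_filter(ch, 0), "Nyquist")
})
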