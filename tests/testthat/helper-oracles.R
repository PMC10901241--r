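# Independent oracles, kept deliberately naive: plain per-pixel, per-element
# loops with no vectorization, written directly from the delay-and-sum
# definition. They validate the package's vectorized implementations.

# Naive DAS: I(p) = sum_i w_i s_i(tau_i) / sum_i w_i, linear interpolation,
# cos^q angular weight with hard cutoff.
das_naive <- function(channels, grid, speed_of_sound, weights) {
  tau_factor <- if (channels$modality == "US") 2 else 1
  geom <- channels$geometry
  s <- channels$samples
  ns <- ncol(s)
  fs <- channels$sampling_rate
  out <- matrix(0, grid$nz, grid$nx)
  cos_max <- cos(weights$max_angle)
  for (iz in seq_len(grid$nz)) {
    for (ix in seq_len(grid$nx)) {
      num <- 0; den <- 0
      for (i in seq_len(nrow(s))) {
        dx <- grid$x[ix] - geom$element_positions[i, 1]
        dz <- grid$z[iz] - geom$element_positions[i, 2]
        r <- sqrt(dx^2 + dz^2)
        if (r == 0) r <- .Machine$double.eps
        cth <- (dx * geom$element_normals[i, 1] +
                dz * geom$element_normals[i, 2]) / r
        if (cth < cos_max) next
        w <- cth^weights$angular_exponent
        f <- (tau_factor * r / speed_of_sound - channels$t0) * fs + 1
        i0 <- floor(f)
        if (i0 >= 1 && i0 < ns) {
          frac <- f - i0
          num <- num + w * ((1 - frac) * s[i, i0] + frac * s[i, i0 + 1])
        }
        den <- den + w
      }
      out[iz, ix] <- if (den > 0) num / den else 0
    }
  }
  out
}

# Small default scene builders shared across tests.
point_phantom <- function(x = 0, z = 20e-3, amplitude = 1) {
  make_phantom(data.frame(x = x, y = 0, z = z, amplitude = amplitude,
                          radius = 0),
               optics = optical_model(mu_eff = 0))
}

expect_rel_equal <- function(a, b, tol) {
  scale <- max(abs(b))
  expect_lt(max(abs(a - b)) / scale, tol)
}
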