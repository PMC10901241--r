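#' Delay-and-sum image reconstruction
#'
#' Per-pixel delay-and-sum with angular (apodization) weights:
#' \deqn{I(p) = \frac{\sum_i w_i(p)\, s_i(\tau_i(p))}{\sum_i w_i(p)},\qquad
#'       \tau_i(p) = \frac{|p - r_i|}{c} \ (\mathrm{PA}),\quad
#'       \frac{2|p - r_i|}{c} \ (\mathrm{US}),}
#' with linear interpolation between time samples and
#' \eqn{w_i(p) = \cos^q\theta_i} for \eqn{\theta_i \le \theta_{max}} (else 0),
#' where \eqn{\theta_i} is the angle between element i's normal and the
#' direction to the pixel. Images remain bipolar: no envelope detection or
#' non-negativity is applied to PA images.
#'
#' @name reconstruct
NULL

#' Reconstruction pixel grid
#'
#' Pixel (1, 1) is centered at (x_min, z_min); centers advance by
#' `pixel_spacing` along each axis. Image matrices are [nz x nx] (depth in
#' rows).
#'
#' @param x_min,x_max,z_min,z_max Grid bounds in meters.
#' @param pixel_spacing Pixel pitch in meters.
#' @return A `pa_grid` object with precomputed center coordinates.
#' @export
image_grid <- function(x_min, x_max, z_min, z_max, pixel_spacing) {
  if (x_max <= x_min || z_max <= z_min || pixel_spacing <= 0)
    stop("degenerate grid", call. = FALSE)
  x <- seq(x_min, x_max + pixel_spacing / 2, by = pixel_spacing)
  x <- x[x <= x_max + 1e-12]
  z <- seq(z_min, z_max + pixel_spacing / 2, by = pixel_spacing)
  z <- z[z <= z_max + 1e-12]
  structure(list(x_min = x_min, x_max = x_max, z_min = z_min, z_max = z_max,
                 pixel_spacing = pixel_spacing, x = x, z = z,
                 nx = length(x), nz = length(z)),
            class = "pa_grid")
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$z, b$z))
}

new_image <- function(values, grid, modality) {
  structure(list(values = values, grid = grid, modality = modality),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image> %s, %d x %d px, range [%.3g, %.3g]\n",
              x$modality, x$grid$nz, x$grid$nx, min(x$values), max(x$values)))
  invisible(x)
}

#' Angular weighting specification
#'
#' Receive apodization for the delay-and-sum beamformer: weight cos^q(theta)
#' with a hard acceptance cutoff at `max_angle`. Defaults: q = 1, cutoff 60
#' degrees.
#'
#' @param angular_exponent Exponent q >= 0.
#' @param max_angle Acceptance half-angle in radians, in (0, pi/2].
#' @return A `pa_weights` object.
#' @export
weighting_spec <- function(angular_exponent = 1, max_angle = pi / 3) {
  if (angular_exponent < 0) stop("angular_exponent must be >= 0", call. = FALSE)
  if (max_angle <= 0 || max_angle > pi / 2)
    stop("max_angle must be in (0, pi/2]", call. = FALSE)
  structure(list(angular_exponent = angular_exponent, max_angle = max_angle),
            class = "pa_weights")
}

#' Delay-and-sum reconstruction
#'
#' Vectorized per-element back-projection onto the pixel grid. Delays use the
#' one-way time of flight for PA data and the round trip for US data; samples
#' are linearly interpolated; out-of-record delays contribute zero. Weights
#' are normalized per pixel by their sum, which flattens aperture-coverage
#' falloff so that depth-amplitude trends reflect physics (spreading,
#' fluence) rather than geometry; pixels with zero total weight are set to 0.
#'
#' @param channels A `pa_channels` (modality PA or US).
#' @param grid A `pa_grid`.
#' @param speed_of_sound Reconstruction sound speed in m/s (adjustable
#'   independently of the true medium speed).
#' @param weights A `pa_weights`.
#' @return A `pa_image` with modality `"PA"` or `"US_rf"`.
#' @export
das_reconstruct <- function(channels, grid, speed_of_sound = 1500,
                            weights = weighting_spec()) {
  stopifnot(inherits(channels, "pa_channels"), inherits(grid, "pa_grid"),
            inherits(weights, "pa_weights"))
  if (speed_of_sound <= 0) stop("speed_of_sound must be positive", call. = FALSE)
  tau_factor <- if (channels$modality == "US") 2 else 1
  geom <- channels$geometry
  s <- channels$samples
  ns <- ncol(s)
  fs <- channels$sampling_rate
  px <- rep(grid$x, each = grid$nz)    # column-major [nz x nx]
  pz <- rep(grid$z, times = grid$nx)
  num <- numeric(length(px))
  den <- numeric(length(px))
  den_live <- numeric(length(px))
  cos_max <- cos(weights$max_angle)
  q <- weights$angular_exponent
  for (i in seq_len(n_elements(geom))) {
    dx <- px - geom$element_positions[i, 1]
    dz <- pz - geom$element_positions[i, 2]
    r <- sqrt(dx^2 + dz^2)
    r[r == 0] <- .Machine$double.eps
    cth <- (dx * geom$element_normals[i, 1] +
            dz * geom$element_normals[i, 2]) / r
    w <- ifelse(cth >= cos_max, cth^q, 0)
    tau <- tau_factor * r / speed_of_sound
    f <- (tau - channels$t0) * fs + 1
    i0 <- floor(f)
    frac <- f - i0
    valid <- i0 >= 1 & i0 < ns
    i0v <- ifelse(valid, i0, 1L)
    si <- s[i, ]
    samp <- (1 - frac) * si[i0v] + frac * si[i0v + 1L]
    samp[!valid] <- 0
    num <- num + w * samp
    den <- den + w
    den_live <- den_live + w * valid
  }
  if (any(den > 0 & den_live == 0))
    warning("some pixels lie beyond the recorded time window for every element",
            call. = FALSE)
  vals <- ifelse(den > 0, num / den, 0)
  modality <- if (channels$modality == "US") "US_rf" else "PA"
  new_image(matrix(vals, grid$nz, grid$nx), grid, modality)
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones. Used for the B-mode envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' B-mode post-processing of an RF ultrasound image
#'
#' Per-column envelope detection (magnitude of the analytic signal along
#' depth), normalization to the image maximum, log compression over
#' `dynamic_range` dB with `gain` dB applied before clipping to [0, 1].
#'
#' @param image A `pa_image` with modality `"US_rf"`.
#' @param dynamic_range Displayed dynamic range in dB (> 0).
#' @param gain Gain in dB added before clipping.
#' @param ref_max Optional envelope normalization reference; defaults to the
#'   image's own envelope maximum. Pass a shared value to put several B-mode
#'   images on a comparable brightness scale.
#' @return A `pa_image` with modality `"US_bmode"`, values in [0, 1].
#' @export
us_bmode <- function(image, dynamic_range = 40, gain = 0, ref_max = NULL) {
  stopifnot(inherits(image, "pa_image"))
  if (image$modality != "US_rf")
    stop("us_bmode expects a US_rf image", call. = FALSE)
  if (dynamic_range <= 0) stop("dynamic_range must be positive", call. = FALSE)
  env <- apply(image$values, 2L, function(col) Mod(analytic_signal(col)))
  env <- matrix(env, nrow(image$values), ncol(image$values))
  mx <- if (is.null(ref_max)) max(env) else ref_max
  if (mx == 0) return(new_image(env * 0, image$grid, "US_bmode"))
  db <- 20 * log10(pmax(env / mx, 1e-12))
  vals <- (db + gain + dynamic_range) / dynamic_range
  vals <- pmin(pmax(vals, 0), 1)
  new_image(vals, image$grid, "US_bmode")
}

#' Maximum of the RF image envelope
#'
#' The largest per-column analytic-signal magnitude of a `US_rf` image —
#' the reference a group of B-mode images can share (via the `ref_max`
#' argument of [us_bmode()]) so their brightnesses are comparable.
#'
#' @param image A `pa_image` with modality `"US_rf"`.
#' @return A scalar envelope maximum.
#' @export
us_envelope_max <- function(image) {
  stopifnot(inherits(image, "pa_image"))
  if (image$modality != "US_rf")
    stop("us_envelope_max expects a US_rf image", call. = FALSE)
  max(apply(image$values, 2L, function(col) Mod(analytic_signal(col))))
}

#' Multi-angle joint reconstruction
#'
#' Coherently combines several acquisitions of the same scene taken at
#' different array poses (rotations/translations of the half-ring array):
#' each view's geometry is posed into the common frame, the posed element
#' sets are concatenated, and a single delay-and-sum runs over the union —
#' amplitude-domain (coherent) summation, normalized by the total weight.
#'
#' @param views A list; each entry a list with elements `channels`
#'   (`pa_channels`) and `pose` (`pa_pose`).
#' @inheritParams das_reconstruct
#' @return A `pa_image`.
#' @export
multi_view_reconstruct <- function(views, grid, speed_of_sound = 1500,
                                   weights = weighting_spec()) {
  if (length(views) == 0) stop("need at least one view", call. = FALSE)
  ch0 <- views[[1]]$channels
  geoms <- lapply(views, function(v) apply_pose(v$channels$geometry, v$pose))
  for (v in views) {
    if (v$channels$sampling_rate != ch0$sampling_rate ||
        ncol(v$channels$samples) != ncol(ch0$samples) ||
        v$channels$t0 != ch0$t0 || v$channels$modality != ch0$modality)
      stop("all views must share sampling parameters and modality", call. = FALSE)
  }
  combined_geom <- geoms[[1]]
  combined_geom$element_positions <- do.call(rbind, lapply(geoms, `[[`, "element_positions"))
  combined_geom$element_normals <- do.call(rbind, lapply(geoms, `[[`, "element_normals"))
  combined <- new_channel_data(
    do.call(rbind, lapply(views, function(v) v$channels$samples)),
    ch0$sampling_rate, ch0$t0, ch0$modality, combined_geom)
  das_reconstruct(combined, grid, speed_of_sound, weights)
}

#' Stack per-slice multi-view reconstructions into a volume
#'
#' Each elevational position y is reconstructed independently in its (x, z)
#' plane via [multi_view_reconstruct()] and the slices are stacked into a
#' [ny x nz x nx] volume — the scan-and-rotate acquisition of the half-ring
#' system.
#'
#' @param per_slice_views A list; each entry a list with `y` (slice position,
#'   meters; strictly increasing across entries) and `views` (as in
#'   [multi_view_reconstruct()]).
#' @inheritParams das_reconstruct
#' @return A `pa_volume`: values [ny x nz x nx] plus grid and y positions.
#' @export
reconstruct_volume <- function(per_slice_views, grid, speed_of_sound = 1500,
                               weights = weighting_spec()) {
  if (length(per_slice_views) == 0) stop("need at least one slice", call. = FALSE)
  ys <- vapply(per_slice_views, `[[`, numeric(1), "y")
  if (any(duplicated(ys))) stop("duplicate y positions", call. = FALSE)
  if (is.unsorted(ys, strictly = TRUE))
    stop("y positions must be strictly increasing", call. = FALSE)
  slices <- lapply(per_slice_views, function(sl)
    multi_view_reconstruct(sl$views, grid, speed_of_sound, weights)$values)
  vol <- array(0, dim = c(length(ys), grid$nz, grid$nx))
  for (k in seq_along(slices)) vol[k, , ] <- slices[[k]]
  structure(list(values = vol, grid = grid, y = ys), class = "pa_volume")
}

#' Locate the image peak with sub-pixel refinement
#'
#' Finds the maximum of |values|; ties are broken deterministically toward
#' the smallest z, then the smallest x. A 3-point quadratic fit along each
#' axis refines the location to sub-pixel precision (offsets clamped to half
#' a pixel; skipped at image borders).
#'
#' @param image A `pa_image`.
#' @return A list with `x`, `z` (meters) and `amplitude` (signed value at the
#'   integer peak).
#' @export
locate_peak <- function(image) {
  stopifnot(inherits(image, "pa_image"))
  v <- abs(image$values)
  mx <- max(v)
  if (mx == 0) stop("all-zero image: no peak", call. = FALSE)
  hits <- which(v == mx, arr.ind = TRUE)
  # rows index z, columns x; order favors smallest z then smallest x
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  iz <- hits[1, 1]; ix <- hits[1, 2]
  refine <- function(m1, m0, p1) {
    d <- m1 - 2 * m0 + p1
    if (d >= 0) return(0)
    off <- 0.5 * (m1 - p1) / d
    max(-0.5, min(0.5, off))
  }
  dz <- if (iz > 1 && iz < nrow(v)) refine(v[iz - 1, ix], v[iz, ix], v[iz + 1, ix]) else 0
  dx <- if (ix > 1 && ix < ncol(v)) refine(v[iz, ix - 1], v[iz, ix], v[iz, ix + 1]) else 0
  sp <- image$grid$pixel_spacing
  list(x = image$grid$x[ix] + dx * sp,
       z = image$grid$z[iz] + dz * sp,
       amplitude = image$values[iz, ix])
}

#' Lateral full width at half maximum at the image peak
#'
#' Measures the width of the contiguous |amplitude| >= half-maximum run
#' through the peak along the lateral (x) axis, with linear interpolation of
#' the half-maximum crossings — the conventional resolution metric for a
#' point-target image.
#'
#' @param image A `pa_image`.
#' @return FWHM in meters.
#' @export
lateral_fwhm <- function(image) {
  stopifnot(inherits(image, "pa_image"))
  v <- abs(image$values)
  if (max(v) == 0) stop("all-zero image: no peak", call. = FALSE)
  pk <- which(v == max(v), arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE]
  prof <- v[pk[1, 1], ]
  h <- max(prof) / 2
  ip <- pk[1, 2]
  iL <- ip; while (iL > 1 && prof[iL - 1] >= h) iL <- iL - 1
  iR <- ip; while (iR < length(prof) && prof[iR + 1] >= h) iR <- iR + 1
  xl <- if (iL > 1) iL - (prof[iL] - h) / (prof[iL] - prof[iL - 1]) else iL
  xr <- if (iR < length(prof)) iR + (prof[iR] - h) / (prof[iR] - prof[iR + 1]) else iR
  (xr - xl) * image$grid$pixel_spacing
}

#' Extent of the feature containing the image peak
#'
#' Thresholds |values| at `threshold_fraction` of the global |peak|, labels
#' connected components (4-connectivity), and returns the bounding-box
#' extents of the component containing the peak. A single-pixel feature has
#' extent one pixel spacing in each axis. Quantifies how an elongated marker
#' collapses toward a point under limited-view conditions.
#'
#' @param image A `pa_image`.
#' @param threshold_fraction Fraction of the peak in (0, 1); default 0.5.
#' @return Named numeric `c(dx = , dz = )` in meters.
#' @export
feature_extent <- function(image, threshold_fraction = 0.5) {
  stopifnot(inherits(image, "pa_image"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  v <- abs(image$values)
  mx <- max(v)
  if (mx == 0) stop("all-zero image: no feature", call. = FALSE)
  mask <- v >= threshold_fraction * mx
  # EBImage::bwlabel labels 4-connected components of a binary matrix
  lab <- EBImage::bwlabel(mask * 1)
  pk <- which(v == mx, arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE]
  comp <- lab[pk[1, 1], pk[1, 2]]
  idx <- which(lab == comp, arr.ind = TRUE)
  sp <- image$grid$pixel_spacing
  c(dx = (diff(range(idx[, 2])) + 1) * sp,
    dz = (diff(range(idx[, 1])) + 1) * sp)
}
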