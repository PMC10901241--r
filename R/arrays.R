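#' Transducer array geometries
#'
#' Constructors for the two detection geometries used throughout the package:
#' a handheld linear array (2D limited-view imaging) and a half-ring arc array
#' (multi-angle tomographic imaging). Elements are modeled as ideal points in
#' the imaging (x, z) plane: x is lateral, z is depth (positive into tissue),
#' y is the elevation/scan axis. All lengths are in meters, times in seconds.
#'
#' @name arrays
NULL

new_array_geometry <- function(kind, positions, normals, center_frequency,
                               fractional_bandwidth, pitch_or_radius,
                               elevation_sigma = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 2L,
            is.matrix(normals), ncol(normals) == 2L,
            nrow(positions) == nrow(normals))
  structure(
    list(kind = kind,
         element_positions = positions,
         element_normals = normals,
         center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         pitch_or_radius = pitch_or_radius,
         elevation_sigma = elevation_sigma),
    class = "pa_array")
}

#' @export
print.pa_array <- function(x, ...) {
  cat(sprintf("<pa_array> %s, %d elements, fc = %.3g MHz, bw = %.0f%%\n",
              x$kind, nrow(x$element_positions),
              x$center_frequency / 1e6, 100 * x$fractional_bandwidth))
  invisible(x)
}

n_elements <- function(geometry) nrow(geometry$element_positions)

#' Linear transducer array
#'
#' Elements are collinear along x, equally spaced at `pitch`, centered on the
#' origin, lying on the array face z = 0 with normals along +z (into tissue).
#' Defaults follow the handheld dual-modality probe: 128 elements, 5 MHz
#' center frequency, 70% fractional bandwidth (-6 dB). The pitch default of
#' 0.3 mm gives a ~38 mm aperture, consistent with the 40 mm illumination
#' width on the skin.
#'
#' @param n_elements Number of elements (>= 1).
#' @param pitch Element spacing in meters.
#' @param center_frequency Center frequency in Hz.
#' @param fractional_bandwidth -6 dB bandwidth divided by center frequency,
#'   in (0, 2).
#' @param elevation_sigma Standard deviation (meters) of an optional Gaussian
#'   elevational sensitivity representing the acoustic lens focus; `NULL`
#'   (default) models ideal point elements sensitive at any elevation.
#' @return A `pa_array` object.
#' @export
#' @examples
#' arr <- make_linear_array()
#' range(arr$element_positions[, 1])  # +/- 19.05 mm
make_linear_array <- function(n_elements = 128L, pitch = 0.3e-3,
                              center_frequency = 5e6,
                              fractional_bandwidth = 0.7,
                              elevation_sigma = NULL) {
  if (n_elements < 1L) stop("n_elements must be >= 1", call. = FALSE)
  if (pitch <= 0) stop("pitch must be positive", call. = FALSE)
  if (center_frequency <= 0) stop("center_frequency must be positive", call. = FALSE)
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional_bandwidth must be in (0, 2)", call. = FALSE)
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  positions <- cbind(x = x, z = rep(0, n_elements))
  normals <- cbind(x = rep(0, n_elements), z = rep(1, n_elements))
  new_array_geometry("linear", positions, normals, center_frequency,
                     fractional_bandwidth, pitch, elevation_sigma)
}

#' Arc (half-ring) transducer array
#'
#' Elements lie on a circle of the stated radius centered at the origin,
#' equally spaced in angle over `span_deg`, symmetric about the +z axis; the
#' middle of the arc sits at (0, -radius) so element normals point toward the
#' arc center (the imaging region). Defaults follow the half-ring tomographic
#' probe: 178 degrees, 55 mm radius, 128 elements.
#'
#' @param radius Arc radius in meters.
#' @param span_deg Angular span in degrees, in (0, 360].
#' @param n_elements Number of elements (>= 1).
#' @inheritParams make_linear_array
#' @return A `pa_array` object.
#' @export
make_arc_array <- function(radius = 55e-3, span_deg = 178,
                           n_elements = 128L, center_frequency = 5e6,
                           fractional_bandwidth = 0.7,
                           elevation_sigma = NULL) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (span_deg <= 0 || span_deg > 360)
    stop("span_deg must be in (0, 360]", call. = FALSE)
  if (n_elements < 1L) stop("n_elements must be >= 1", call. = FALSE)
  if (center_frequency <= 0) stop("center_frequency must be positive", call. = FALSE)
  span <- span_deg * pi / 180
  phi <- if (n_elements == 1L) 0 else seq(-span / 2, span / 2, length.out = n_elements)
  # phi measured from the -z axis; arc opens toward +z
  positions <- cbind(x = radius * sin(phi), z = -radius * cos(phi))
  normals <- -positions / radius
  new_array_geometry("arc", positions, normals, center_frequency,
                     fractional_bandwidth, radius, elevation_sigma)
}

#' Rigid pose of an array
#'
#' A rotation about the elevation (y) axis followed by a translation. The
#' translation is a 3-vector (x, y, z); the y component is carried for slice
#' bookkeeping but does not move in-plane element positions.
#'
#' @param rotation_angle Rotation angle in radians (counterclockwise in the
#'   x-z plane).
#' @param translation Numeric length-3 translation (x, y, z) in meters.
#' @return A `pa_pose` object.
#' @export
make_pose <- function(rotation_angle = 0, translation = c(0, 0, 0)) {
  if (!is.finite(rotation_angle)) stop("rotation_angle must be finite", call. = FALSE)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be a finite length-3 vector", call. = FALSE)
  structure(list(rotation_angle = rotation_angle, translation = translation),
            class = "pa_pose")
}

rotmat2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Invert a pose
#'
#' `pose_compose(pose, pose_inverse(pose))` is the identity pose.
#'
#' @param pose A `pa_pose`.
#' @return The inverse `pa_pose`.
#' @export
pose_inverse <- function(pose) {
  Rinv <- rotmat2(-pose$rotation_angle)
  txz <- as.numeric(Rinv %*% pose$translation[c(1, 3)])
  make_pose(-pose$rotation_angle, c(-txz[1], -pose$translation[2], -txz[2]))
}

#' Compose two poses
#'
#' Applying the result equals applying `first`, then `second`.
#'
#' @param second,first `pa_pose` objects.
#' @return The composed `pa_pose`.
#' @export
pose_compose <- function(second, first) {
  R2 <- rotmat2(second$rotation_angle)
  txz <- as.numeric(R2 %*% first$translation[c(1, 3)]) + second$translation[c(1, 3)]
  make_pose(second$rotation_angle + first$rotation_angle,
            c(txz[1], first$translation[2] + second$translation[2], txz[2]))
}

#' Apply a rigid pose to an array geometry
#'
#' Element positions are rotated then translated; normals are rotated only.
#' All other geometry fields are preserved, so inter-element distances are
#' unchanged (rigidity).
#'
#' @param geometry A `pa_array`.
#' @param pose A `pa_pose`.
#' @return The posed `pa_array`.
#' @export
apply_pose <- function(geometry, pose) {
  stopifnot(inherits(geometry, "pa_array"), inherits(pose, "pa_pose"))
  R <- rotmat2(pose$rotation_angle)
  pos <- geometry$element_positions %*% t(R)
  pos[, 1] <- pos[, 1] + pose$translation[1]
  pos[, 2] <- pos[, 2] + pose$translation[3]
  nrm <- geometry$element_normals %*% t(R)
  colnames(pos) <- colnames(nrm) <- c("x", "z")
  out <- geometry
  out$element_positions <- pos
  out$element_normals <- nrm
  out
}
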