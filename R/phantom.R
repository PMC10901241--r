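#' Synthetic phantoms: marker clips, vessels, scattering tissue
#'
#' The phantom module generates the in-silico counterparts of the agar and
#' meat phantom experiments: a titanium marker clip (1 mm diameter x 3 mm
#' length cylinder with an optional hook) at a chosen depth and orientation,
#' blood-vessel-like point absorbers, a uniform field of ultrasound
#' scatterers, all inside an optically attenuating medium.
#'
#' Absorbers generate photoacoustic signal (relative initial pressure);
#' scatterers generate pulse-echo ultrasound signal (relative reflectivity).
#' Positions are 3D (x lateral, y elevation, z depth), in meters.
#'
#' @name phantom
NULL

#' Optical attenuation model
#'
#' One-dimensional exponential fluence decay with depth,
#' \eqn{\Phi(z) = \Phi_0 e^{-\mu_{eff} z}}. The default effective attenuation
#' coefficient 0.4 cm^-1 (40 m^-1) matches a 3% agarose / 1% Intralipid
#' phantom.
#'
#' @param mu_eff Effective attenuation coefficient in 1/m (>= 0).
#' @param surface_fluence Relative fluence at the surface (z = 0).
#' @return A `pa_optics` object.
#' @export
optical_model <- function(mu_eff = 40, surface_fluence = 1) {
  if (mu_eff < 0) stop("mu_eff must be >= 0", call. = FALSE)
  structure(list(mu_eff = mu_eff, surface_fluence = surface_fluence),
            class = "pa_optics")
}

#' Relative fluence at depth
#'
#' @param optics A `pa_optics` model.
#' @param depth Depth in meters (>= 0); vectorized.
#' @return Relative fluence, monotone non-increasing in depth.
#' @export
#' @examples
#' fluence_at(optical_model(mu_eff = 40), 25e-3)  # exp(-1)
fluence_at <- function(optics, depth) {
  stopifnot(inherits(optics, "pa_optics"))
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  optics$surface_fluence * exp(-optics$mu_eff * depth)
}

#' Normalized source amplitude presets
#'
#' Relative photoacoustic signal intensities at 1064 nm, normalized to the
#' titanium marker material: titanium 1.0, highly oxygenated blood 0.91
#' (titanium ~1.09x blood).
#'
#' @param material `"titanium"` or `"blood"`.
#' @return A dimensionless amplitude.
#' @export
amplitude_preset <- function(material = c("titanium", "blood")) {
  material <- match.arg(material)
  c(titanium = 1.0, blood = 0.91)[[material]]
}

#' Marker clip specification
#'
#' @param depth Depth of the marker centroid below the array face, meters.
#' @param orientation One of `"in_plane_parallel"` (long axis along x, i.e.
#'   along the linear array), `"perpendicular_to_plane"` (long axis along y,
#'   out of the imaging plane) or `"in_plane_vertical"` (long axis along z,
#'   the depth axis).
#' @param length Cylinder length, meters (default 3 mm).
#' @param diameter Cylinder diameter, meters (default 1 mm).
#' @param with_hook If `TRUE`, add the hooked wire tail at one end (a
#'   quarter-circle of radius 0.5 mm).
#' @param sample_spacing Lattice spacing of the discretized absorber cloud,
#'   meters; must satisfy 0 < sample_spacing <= length.
#' @return A `pa_marker_spec` object.
#' @export
marker_spec <- function(depth,
                        orientation = c("in_plane_parallel",
                                        "perpendicular_to_plane",
                                        "in_plane_vertical"),
                        length = 3e-3, diameter = 1e-3,
                        with_hook = FALSE, sample_spacing = 1e-4) {
  orientation <- match.arg(orientation)
  if (length <= 0 || diameter <= 0)
    stop("length and diameter must be positive", call. = FALSE)
  if (sample_spacing <= 0 || sample_spacing > length)
    stop("sample_spacing must be in (0, length]", call. = FALSE)
  structure(list(depth = depth, orientation = orientation, length = length,
                 diameter = diameter, with_hook = with_hook,
                 sample_spacing = sample_spacing),
            class = "pa_marker_spec")
}

# Canonical marker cloud: cylinder axis along x, centered at origin, hook (if
# any) curving from the +x end into +z. Points sit on axial rings on the
# cylinder surface plus the axis itself, at sample_spacing resolution.
marker_cloud_canonical <- function(spec) {
  h <- spec$sample_spacing
  s <- seq(-spec$length / 2, spec$length / 2, by = h)
  if (s[base::length(s)] < spec$length / 2 - 1e-12)
    s <- c(s, spec$length / 2)
  rad <- spec$diameter / 2
  n_circ <- max(3L, as.integer(round(2 * pi * rad / h)))
  ang <- seq(0, 2 * pi, length.out = n_circ + 1L)[seq_len(n_circ)]
  ring <- cbind(y = rad * cos(ang), z = rad * sin(ang))
  surf <- cbind(x = rep(s, each = n_circ),
                y = rep(ring[, 1], times = base::length(s)),
                z = rep(ring[, 2], times = base::length(s)))
  axis_pts <- cbind(x = s, y = 0, z = 0)
  pts <- rbind(surf, axis_pts)
  if (spec$with_hook) {
    hr <- 0.5e-3
    n_h <- max(2L, as.integer(round((pi / 2) * hr / h)))
    th <- seq(0, pi / 2, length.out = n_h)
    hook <- cbind(x = spec$length / 2 + hr * sin(th),
                  y = 0,
                  z = hr * (1 - cos(th)))
    pts <- rbind(pts, hook)
  }
  pts
}

orientation_rotation <- function(orientation) {
  switch(orientation,
         in_plane_parallel = diag(3),
         # x -> y: rotate +90 deg about z
         perpendicular_to_plane = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
         # x -> z: rotate -90 deg about y
         in_plane_vertical = matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3))
}

#' Discretize a marker clip into point absorbers
#'
#' Builds a lattice of point absorbers on the surface and axis of the marker
#' cylinder (plus the hook tail when requested), rotates it into the requested
#' orientation as a rigid body, and places the cylinder centroid at
#' (0, 0, depth). All orientations are rigid rotations of the same canonical
#' cloud, so absorber count and total amplitude are orientation-invariant.
#' Amplitudes use the titanium preset.
#'
#' @param spec A `pa_marker_spec`.
#' @return A data.frame with columns `x`, `y`, `z`, `amplitude`, `radius`
#'   (radius 0 = ideal point).
#' @export
make_marker <- function(spec) {
  stopifnot(inherits(spec, "pa_marker_spec"))
  pts <- marker_cloud_canonical(spec)
  R <- orientation_rotation(spec$orientation)
  pts <- pts %*% t(R)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3] + spec$depth,
             amplitude = amplitude_preset("titanium"),
             radius = 0)
}

#' Marker surface scatterers for pulse-echo ultrasound
#'
#' The smooth titanium surface reflects specularly: in a monostatic geometry
#' the echo returns only from surface patches whose outward normal faces the
#' transducer. Each cylinder-surface lattice point becomes a scatterer with
#' reflectivity \eqn{\max(0, -n_z)^p}, where \eqn{n} is the outward surface
#' normal after orientation and \eqn{p} controls how specular the surface is.
#' A marker lying parallel to the array thus returns a bright line from its
#' top surface, while a vertical marker (all normals horizontal) returns
#' almost nothing — the orientation-dependent US visibility seen on real
#' clips. The hook and axis points are omitted (wire-scale scattering is not
#' modeled).
#'
#' @param spec A `pa_marker_spec`.
#' @param specular_exponent Directivity exponent p >= 0 (default 4; higher is
#'   more mirror-like).
#' @return A data.frame with columns `x`, `y`, `z`, `reflectivity`.
#' @export
marker_scatterers <- function(spec, specular_exponent = 4) {
  stopifnot(inherits(spec, "pa_marker_spec"))
  if (specular_exponent < 0)
    stop("specular_exponent must be >= 0", call. = FALSE)
  h <- spec$sample_spacing
  s <- seq(-spec$length / 2, spec$length / 2, by = h)
  if (s[base::length(s)] < spec$length / 2 - 1e-12)
    s <- c(s, spec$length / 2)
  rad <- spec$diameter / 2
  n_circ <- max(3L, as.integer(round(2 * pi * rad / h)))
  ang <- seq(0, 2 * pi, length.out = n_circ + 1L)[seq_len(n_circ)]
  pts <- cbind(x = rep(s, each = n_circ),
               y = rad * rep(cos(ang), times = base::length(s)),
               z = rad * rep(sin(ang), times = base::length(s)))
  nrm <- cbind(x = 0, y = rep(cos(ang), times = base::length(s)),
               z = rep(sin(ang), times = base::length(s)))
  R <- orientation_rotation(spec$orientation)
  pts <- pts %*% t(R)
  nrm <- nrm %*% t(R)
  # the array looks down +z; echo returns from normals facing it (-z)
  refl <- pmax(0, -nrm[, 3])^specular_exponent
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3] + spec$depth,
             reflectivity = refl)
}

#' Assemble a phantom
#'
#' @param absorbers Data.frame of photoacoustic sources (`x`, `y`, `z`,
#'   `amplitude`, optionally `radius`), or `NULL` for none.
#' @param scatterers Data.frame of ultrasound scatterers (`x`, `y`, `z`,
#'   `reflectivity`), or `NULL` for none.
#' @param optics A `pa_optics` model.
#' @param speed_of_sound Medium sound speed in m/s.
#' @return A `pa_phantom` object.
#' @export
make_phantom <- function(absorbers = NULL, scatterers = NULL,
                         optics = optical_model(), speed_of_sound = 1500) {
  if (speed_of_sound <= 0) stop("speed_of_sound must be positive", call. = FALSE)
  empty_abs <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          amplitude = numeric(), radius = numeric())
  empty_sca <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          reflectivity = numeric())
  if (is.null(absorbers)) absorbers <- empty_abs
  if (is.null(scatterers)) scatterers <- empty_sca
  if (nrow(absorbers) && any(absorbers$amplitude < 0))
    stop("absorber amplitudes must be >= 0", call. = FALSE)
  if (nrow(scatterers) && any(scatterers$reflectivity < 0))
    stop("reflectivities must be >= 0", call. = FALSE)
  structure(list(absorbers = absorbers, scatterers = scatterers,
                 optics = optics, speed_of_sound = speed_of_sound),
            class = "pa_phantom")
}

#' @export
print.pa_phantom <- function(x, ...) {
  cat(sprintf("<pa_phantom> %d absorbers, %d scatterers, c = %g m/s, mu_eff = %g /m\n",
              nrow(x$absorbers), nrow(x$scatterers), x$speed_of_sound,
              x$optics$mu_eff))
  invisible(x)
}

#' Marker phantoms at a series of depths
#'
#' One phantom per depth, identical except for the marker depth — the
#' in-silico analogue of burying markers under agar blocks of increasing
#' thickness (5, 15, 25, 35 mm in the reference experiment).
#'
#' @param depths Depths in meters, all > 0.
#' @param orientation Marker orientation (see [marker_spec()]).
#' @param optics Optical model shared by all phantoms.
#' @param speed_of_sound Sound speed shared by all phantoms.
#' @param ... Further arguments passed to [marker_spec()].
#' @return A list of `pa_phantom` objects, one per depth.
#' @export
make_depth_series <- function(depths = c(5, 15, 25, 35) * 1e-3,
                              orientation = "in_plane_parallel",
                              optics = optical_model(),
                              speed_of_sound = 1500, ...) {
  if (length(depths) == 0) stop("depths must be non-empty", call. = FALSE)
  if (any(depths <= 0)) stop("all depths must be > 0", call. = FALSE)
  lapply(depths, function(d) {
    make_phantom(absorbers = make_marker(marker_spec(depth = d,
                                                     orientation = orientation,
                                                     ...)),
                 optics = optics, speed_of_sound = speed_of_sound)
  })
}

#' Vessel-like absorbers and scattering tissue background
#'
#' Blood vessels in cross-section are modeled as point absorbers with the
#' blood amplitude preset (the "point features" a marker can be confused
#' with); tissue echogenicity as uniformly random point scatterers with unit
#' mean reflectivity. The scatterer count is Poisson with mean
#' density x area. Fully reproducible for a fixed seed.
#'
#' @param region List with numeric ranges `x` and `z` (meters); vessels and
#'   scatterers are drawn uniformly in this box at y = 0.
#' @param vessel_count Number of vessel cross-sections.
#' @param scatterer_density Scatterers per square meter of the (x, z) region.
#' @param seed Integer seed governing all randomness.
#' @param optics,speed_of_sound Passed to [make_phantom()].
#' @return A `pa_phantom`.
#' @export
make_tissue_background <- function(region = list(x = c(-19e-3, 19e-3),
                                                 z = c(1e-3, 38e-3)),
                                   vessel_count = 5L,
                                   scatterer_density = 2e6,
                                   seed = 1L,
                                   optics = optical_model(),
                                   speed_of_sound = 1500) {
  if (scatterer_density < 0) stop("scatterer_density must be >= 0", call. = FALSE)
  if (vessel_count < 0) stop("vessel_count must be >= 0", call. = FALSE)
  dx <- diff(region$x); dz <- diff(region$z)
  if (dx <= 0 || dz <= 0) stop("region must be non-degenerate", call. = FALSE)
  withr::with_seed(seed, {
    nv <- as.integer(vessel_count)
    vessels <- data.frame(
      x = stats::runif(nv, region$x[1], region$x[2]),
      y = rep(0, nv),
      z = stats::runif(nv, region$z[1], region$z[2]),
      amplitude = rep(amplitude_preset("blood"), nv),
      radius = rep(0, nv))
    ns <- stats::rpois(1, scatterer_density * dx * dz)
    scat <- data.frame(
      x = stats::runif(ns, region$x[1], region$x[2]),
      y = rep(0, ns),
      z = stats::runif(ns, region$z[1], region$z[2]),
      reflectivity = stats::rexp(ns, rate = 1))
    make_phantom(absorbers = vessels, scatterers = scat, optics = optics,
                 speed_of_sound = speed_of_sound)
  })
}

#' Export phantom sources as a delimited table
#'
#' Writes one row per source (`x`, `y`, `z`, `amplitude` or `reflectivity`)
#' as tab-separated text.
#'
#' @param phantom A `pa_phantom`.
#' @param path Output file path.
#' @param what `"absorbers"` or `"scatterers"`.
#' @return `path`, invisibly.
#' @export
write_sources <- function(phantom, path, what = c("absorbers", "scatterers")) {
  what <- match.arg(what)
  utils::write.table(phantom[[what]], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
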