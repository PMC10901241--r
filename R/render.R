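#' Display mapping and dual-modality fusion
#'
#' Bipolar PA images are displayed on a symmetric gray colormap (black = most
#' negative pressure, mid-gray = zero, white = most positive); volumes are
#' summarized by a negative-clipped maximum intensity projection; the fused
#' dual-modality display renders US in purple and PA in cyan, with overlap
#' blending to white.
#'
#' @name render_fuse
NULL

#' Display specification
#'
#' @param pa_percentile_clip Percentile of |PA| used for normalization
#'   (robust to single-pixel outliers), in (0, 100].
#' @param us_dynamic_range US log-compression dynamic range in dB.
#' @param gain US gain in dB.
#' @return A `pa_display` object.
#' @export
display_spec <- function(pa_percentile_clip = 99.9, us_dynamic_range = 40,
                         gain = 0) {
  if (pa_percentile_clip <= 0 || pa_percentile_clip > 100)
    stop("pa_percentile_clip must be in (0, 100]", call. = FALSE)
  structure(list(pa_percentile_clip = pa_percentile_clip,
                 us_dynamic_range = us_dynamic_range, gain = gain),
            class = "pa_display")
}

pa_normalizer <- function(values, spec) {
  a <- stats::quantile(abs(values), spec$pa_percentile_clip / 100,
                       names = FALSE, type = 7)
  if (a == 0) a <- max(abs(values))
  a
}

#' Symmetric bipolar gray colormap for PA images
#'
#' Maps the most negative pressure to black, zero to mid-gray (0.5, 0.5,
#' 0.5) and the most positive to white; normalization by the stated
#' percentile of |values|. An all-zero image renders uniform mid-gray.
#'
#' @param image A `pa_image` with modality `"PA"`.
#' @param spec A `pa_display`.
#' @return A `pa_rgb`: array [nz x nx x 3] in [0, 1].
#' @export
bipolar_colormap <- function(image, spec = display_spec()) {
  stopifnot(inherits(image, "pa_image"))
  if (image$modality != "PA")
    stop("bipolar_colormap expects a PA image", call. = FALSE)
  v <- image$values
  if (all(v == 0)) {
    g <- matrix(0.5, nrow(v), ncol(v))
  } else {
    a <- pa_normalizer(v, spec)
    g <- (pmin(pmax(v / a, -1), 1) + 1) / 2
  }
  rgb <- array(g, dim = c(nrow(v), ncol(v), 3))
  structure(rgb, class = "pa_rgb", grid = image$grid)
}

#' Negative-clipped maximum intensity projection
#'
#' Sets negative values to zero, then takes the maximum along the chosen
#' axis. Volume layout is [ny x nz x nx]; projecting along y yields the
#' (z, x) en-face image, along z the (y, x) top view, along x the (y, z)
#' side view.
#'
#' @param volume A `pa_volume`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A numeric matrix (for axis `"y"`, a `pa_image` on the volume's
#'   grid).
#' @export
mip_render <- function(volume, axis = c("y", "z", "x")) {
  stopifnot(inherits(volume, "pa_volume"))
  axis <- match.arg(axis)
  v <- pmax(volume$values, 0)
  out <- switch(axis,
                y = apply(v, c(2, 3), max),
                z = apply(v, c(1, 3), max),
                x = apply(v, c(1, 2), max))
  if (axis == "y") new_image(out, volume$grid, "PA") else out
}

#' Purple/cyan fusion of co-registered PA and US images
#'
#' With u the normalized US brightness and p the normalized |PA| amplitude,
#' the fused display is the additive blend
#' \eqn{RGB = \mathrm{clip}\left(u\,(1,0,1) + p\,(0,1,1)\right)}:
#' US-only pixels render purple, PA-only pixels cyan, and joint maxima white
#' — the blend of hues that flags the marker in the dual-modality co-plot.
#'
#' @param pa A `pa_image` with modality `"PA"`.
#' @param us A `pa_image` with modality `"US_bmode"` (values in [0, 1]), on
#'   the same grid.
#' @param spec A `pa_display` (controls PA normalization).
#' @return A `pa_rgb` array [nz x nx x 3] in [0, 1].
#' @export
fuse_images <- function(pa, us, spec = display_spec()) {
  stopifnot(inherits(pa, "pa_image"), inherits(us, "pa_image"))
  if (pa$modality != "PA") stop("pa must be a PA image", call. = FALSE)
  if (us$modality != "US_bmode") stop("us must be a US_bmode image", call. = FALSE)
  if (!grids_identical(pa$grid, us$grid))
    stop("pa and us images must share the same grid", call. = FALSE)
  u <- us$values
  p <- abs(pa$values)
  if (max(p) > 0) p <- pmin(p / pa_normalizer(pa$values, spec), 1)
  rgb <- array(0, dim = c(nrow(u), ncol(u), 3))
  rgb[, , 1] <- pmin(u, 1)
  rgb[, , 2] <- pmin(p, 1)
  rgb[, , 3] <- pmin(u + p, 1)
  structure(rgb, class = "pa_rgb", grid = pa$grid)
}

#' Export an RGB image to PNG with an optional scale bar
#'
#' @param rgb A `pa_rgb`.
#' @param path Output PNG path.
#' @param scale_bar Physical length of a white scale bar in meters (e.g.
#'   10e-3 for the customary 10 mm bar), or `NULL` for none. Requires a grid
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(rgb, path, scale_bar = NULL) {
  arr <- unclass(rgb)
  if (!is.null(scale_bar)) {
    grid <- attr(rgb, "grid")
    if (is.null(grid)) stop("scale bar requires a grid attribute", call. = FALSE)
    npix <- max(1L, round(scale_bar / grid$pixel_spacing))
    nz <- dim(arr)[1]; nx <- dim(arr)[2]
    bar_rows <- max(1L, nz - 4L):max(1L, nz - 3L)
    bar_cols <- 3:min(nx, 2L + npix)
    arr[bar_rows, bar_cols, ] <- 1
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Export an image or volume to 16-bit TIFF
#'
#' Values are affinely mapped to [0, 1] over their full range; volumes are
#' written as multi-page TIFF (one page per y slice).
#'
#' @param x A `pa_image` or `pa_volume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff_image <- function(x, path) {
  norm01 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  if (inherits(x, "pa_image")) {
    tiff::writeTIFF(norm01(x$values), path, bits.per.sample = 16L)
  } else if (inherits(x, "pa_volume")) {
    rng <- range(x$values)
    pages <- lapply(seq_len(dim(x$values)[1]), function(k) {
      m <- x$values[k, , ]
      if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else stop("x must be a pa_image or pa_volume", call. = FALSE)
  invisible(path)
}
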