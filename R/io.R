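#' Self-describing containers and run configuration
#'
#' Channel data and images are persisted in a single-file, self-describing
#' text container: a magic line identifying the schema, a JSON attribute
#' header (sampling metadata, geometry, grid), and the sample matrix in
#' tab-separated form at full double precision (17 significant digits, which
#' round-trips IEEE doubles losslessly). Run configurations are YAML with
#' lengths in millimeters at the interface; everything internal is meters
#' and seconds.
#'
#' @name cli_io
NULL

CHANNELS_MAGIC <- "#pausim-channels v1"
IMAGE_MAGIC <- "#pausim-image v1"

fmt_matrix <- function(m) {
  apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
}

geometry_to_header <- function(g) {
  list(kind = g$kind,
       center_frequency = g$center_frequency,
       fractional_bandwidth = g$fractional_bandwidth,
       pitch_or_radius = g$pitch_or_radius,
       element_positions = g$element_positions,
       element_normals = g$element_normals,
       elevation_sigma = g$elevation_sigma)
}

geometry_from_header <- function(h) {
  new_array_geometry(h$kind,
                     matrix(as.numeric(h$element_positions),
                            ncol = 2, dimnames = list(NULL, c("x", "z"))),
                     matrix(as.numeric(h$element_normals),
                            ncol = 2, dimnames = list(NULL, c("x", "z"))),
                     as.numeric(h$center_frequency),
                     as.numeric(h$fractional_bandwidth),
                     as.numeric(h$pitch_or_radius),
                     if (is.null(h$elevation_sigma)) NULL
                     else as.numeric(h$elevation_sigma))
}

require_fields <- function(header, fields, path) {
  for (f in fields) {
    if (is.null(header[[f]]))
      stop(sprintf("format error in '%s': missing attribute '%s'", path, f),
           call. = FALSE)
  }
}

#' Write channel data to the text container
#'
#' @param channels A `pa_channels`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channels <- function(channels, path) {
  stopifnot(inherits(channels, "pa_channels"))
  header <- list(schema = "pausim-channels", version = 1L,
                 sampling_rate = channels$sampling_rate,
                 t0 = channels$t0,
                 modality = channels$modality,
                 n_elements = nrow(channels$samples),
                 n_samples = ncol(channels$samples),
                 geometry = geometry_to_header(channels$geometry))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(CHANNELS_MAGIC, con)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)), con)
  writeLines(fmt_matrix(channels$samples), con)
  invisible(path)
}

#' Read channel data from the text container
#'
#' @param path File written by [write_channels()].
#' @return A `pa_channels`. A missing dataset or attribute raises a format
#'   error naming the field.
#' @export
read_channels <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || lines[1] != CHANNELS_MAGIC)
    stop(sprintf("format error in '%s': not a pausim channels container", path),
         call. = FALSE)
  header <- jsonlite::fromJSON(lines[2])
  require_fields(header, c("sampling_rate", "t0", "modality",
                           "n_elements", "n_samples", "geometry"), path)
  require_fields(header$geometry,
                 c("kind", "center_frequency", "fractional_bandwidth",
                   "pitch_or_radius", "element_positions", "element_normals"),
                 path)
  m <- as.matrix(data.table::fread(path, skip = 2L, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != header$n_elements || ncol(m) != header$n_samples)
    stop(sprintf("format error in '%s': samples dataset has wrong shape", path),
         call. = FALSE)
  storage.mode(m) <- "double"
  new_channel_data(m, as.numeric(header$sampling_rate),
                   as.numeric(header$t0), header$modality,
                   geometry_from_header(header$geometry))
}

#' Write a reconstructed image to the text container
#'
#' @param image A `pa_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "pa_image"))
  g <- image$grid
  header <- list(schema = "pausim-image", version = 1L,
                 modality = image$modality,
                 x_min = g$x_min, x_max = g$x_max,
                 z_min = g$z_min, z_max = g$z_max,
                 pixel_spacing = g$pixel_spacing,
                 nz = nrow(image$values), nx = ncol(image$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(IMAGE_MAGIC, con)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)), con)
  writeLines(fmt_matrix(image$values), con)
  invisible(path)
}

#' Read a reconstructed image from the text container
#'
#' @param path File written by [write_image()].
#' @return A `pa_image`.
#' @export
read_image <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || lines[1] != IMAGE_MAGIC)
    stop(sprintf("format error in '%s': not a pausim image container", path),
         call. = FALSE)
  header <- jsonlite::fromJSON(lines[2])
  require_fields(header, c("modality", "x_min", "x_max", "z_min", "z_max",
                           "pixel_spacing", "nz", "nx"), path)
  m <- as.matrix(data.table::fread(path, skip = 2L, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  grid <- image_grid(as.numeric(header$x_min), as.numeric(header$x_max),
                     as.numeric(header$z_min), as.numeric(header$z_max),
                     as.numeric(header$pixel_spacing))
  new_image(m, grid, header$modality)
}

# 32-bit polynomial rolling hash over the canonical YAML serialization; the
# fingerprint is written into run manifests so outputs can be traced back to
# their exact configuration. Intermediate values stay below 2^38, exactly
# representable in doubles.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL    # where outputs land is not part of their identity
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run configuration
#'
#' Assembles the full parameter set of one in-silico experiment. All lengths
#' at this interface are millimeters (converted to meters internally),
#' frequencies MHz, times microseconds; sound speeds m/s.
#'
#' @param preset `"depth_series"` (markers at several depths),
#'   `"orientation_study"` (three marker orientations, PA + US B-mode) or
#'   `"marker_3d"` (multi-angle arc views stacked into a small volume with
#'   MIP).
#' @param output_dir Directory for all outputs.
#' @param seed Integer seed for all stochastic generation.
#' @param phantom,array,acquisition,reconstruction,display,noise Named lists
#'   overriding individual defaults (see the vignette for the full schema).
#' @return A `pa_run_config`.
#' @export
run_config <- function(preset = c("depth_series", "orientation_study",
                                  "marker_3d"),
                       output_dir, seed = 1L,
                       phantom = list(), array = list(),
                       acquisition = list(), reconstruction = list(),
                       display = list(), noise = list()) {
  preset <- match.arg(preset)
  defaults <- list(
    phantom = list(depths_mm = c(5, 15, 25, 35), depth_mm = 5,
                   orientation = "in_plane_parallel", mu_eff_per_cm = 0.4,
                   with_hook = FALSE, sample_spacing_mm = 0.15),
    array = list(kind = "linear", n_elements = 128L, pitch_mm = 0.3,
                 radius_mm = 55, span_deg = 178,
                 center_frequency_mhz = 5, fractional_bandwidth = 0.7),
    acquisition = list(sampling_rate_mhz = 40, n_samples = 2048L,
                       sound_speed = 1500),
    reconstruction = list(sound_speed = 1500, x_mm = c(-15, 15),
                          z_mm = c(1, 40), pixel_spacing_mm = 0.2,
                          angular_exponent = 1, max_angle_deg = 60,
                          highpass_cutoff_mhz = 0.5),
    display = list(pa_percentile_clip = 99.9, us_dynamic_range = 40, gain = 0),
    noise = list(noise_std = 0, burst_times_us = numeric(),
                 burst_amplitude = 0))
  merge1 <- function(base, over) {
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    base
  }
  cfg <- list(preset = preset, output_dir = output_dir, seed = as.integer(seed),
              phantom = merge1(defaults$phantom, phantom),
              array = merge1(defaults$array, array),
              acquisition = merge1(defaults$acquisition, acquisition),
              reconstruction = merge1(defaults$reconstruction, reconstruction),
              display = merge1(defaults$display, display),
              noise = merge1(defaults$noise, noise))
  validate_config(cfg)
  structure(cfg, class = "pa_run_config")
}

validate_config <- function(cfg) {
  need_num <- function(section, field, min = -Inf) {
    v <- cfg[[section]][[field]]
    if (is.null(v) || !is.numeric(v) || any(!is.finite(v)) || any(v < min))
      stop(sprintf("config schema error at %s$%s", section, field),
           call. = FALSE)
  }
  need_num("phantom", "depths_mm", min = 1e-9)
  need_num("phantom", "mu_eff_per_cm", min = 0)
  need_num("array", "n_elements", min = 1)
  need_num("acquisition", "sampling_rate_mhz", min = 1e-9)
  need_num("reconstruction", "sound_speed", min = 1e-9)
  need_num("reconstruction", "pixel_spacing_mm", min = 1e-9)
  if (!cfg$phantom$orientation %in% c("in_plane_parallel",
                                      "perpendicular_to_plane",
                                      "in_plane_vertical"))
    stop("config schema error at phantom$orientation", call. = FALSE)
  invisible(TRUE)
}

#' Write / read a run configuration as YAML
#'
#' @param config A `pa_run_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pa_run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(preset = cfg$preset, output_dir = cfg$output_dir,
             seed = cfg$seed, phantom = cfg$phantom, array = cfg$array,
             acquisition = cfg$acquisition,
             reconstruction = cfg$reconstruction,
             display = cfg$display, noise = cfg$noise)
}

config_objects <- function(cfg) {
  arr <- if (cfg$array$kind == "linear") {
    make_linear_array(cfg$array$n_elements, cfg$array$pitch_mm * 1e-3,
                      cfg$array$center_frequency_mhz * 1e6,
                      cfg$array$fractional_bandwidth)
  } else {
    make_arc_array(cfg$array$radius_mm * 1e-3, cfg$array$span_deg,
                   cfg$array$n_elements,
                   cfg$array$center_frequency_mhz * 1e6,
                   cfg$array$fractional_bandwidth)
  }
  acq <- acquisition_params(cfg$acquisition$sampling_rate_mhz * 1e6,
                            cfg$acquisition$n_samples, 0,
                            cfg$acquisition$sound_speed)
  rc <- cfg$reconstruction
  grid <- image_grid(rc$x_mm[1] * 1e-3, rc$x_mm[2] * 1e-3,
                     rc$z_mm[1] * 1e-3, rc$z_mm[2] * 1e-3,
                     rc$pixel_spacing_mm * 1e-3)
  wts <- weighting_spec(rc$angular_exponent, rc$max_angle_deg * pi / 180)
  disp <- display_spec(cfg$display$pa_percentile_clip,
                       cfg$display$us_dynamic_range, cfg$display$gain)
  optics <- optical_model(cfg$phantom$mu_eff_per_cm * 100)
  list(array = arr, acq = acq, grid = grid, weights = wts, display = disp,
       optics = optics)
}

process_pa <- function(phantom, arr, acq, cfg, obj) {
  ch <- simulate_pa_channels(phantom, arr, acq)
  nz <- cfg$noise
  if (nz$noise_std > 0 || (nz$burst_amplitude > 0 && length(nz$burst_times_us)))
    ch <- add_noise_and_interference(
      ch, interference_spec(nz$burst_times_us * 1e-6, nz$burst_amplitude,
                            nz$noise_std, cfg$seed))
  highpass_filter(ch, cfg$reconstruction$highpass_cutoff_mhz * 1e6)
}

#' Run a complete in-silico experiment
#'
#' Executes phantom generation, forward simulation, filtering,
#' reconstruction and rendering for the chosen preset, writing channel
#' containers, image containers, PNG renders and a JSON manifest (file list,
#' seed, configuration fingerprint) into the output directory. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config A `pa_run_config`.
#' @return The manifest, invisibly (a list with `files`, `seed`,
#'   `config_hash`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "pa_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir))
    stop(sprintf("cannot create output directory '%s'", config$output_dir),
         call. = FALSE)
  obj <- config_objects(config)
  files <- character()
  emit <- function(x, name, writer) {
    p <- file.path(config$output_dir, name)
    writer(x, p)
    files <<- c(files, name)
  }
  ph_cfg <- config$phantom
  spacing <- ph_cfg$sample_spacing_mm * 1e-3
  if (config$preset == "depth_series") {
    for (d in ph_cfg$depths_mm) {
      ph <- make_phantom(
        make_marker(marker_spec(d * 1e-3, ph_cfg$orientation,
                                with_hook = ph_cfg$with_hook,
                                sample_spacing = spacing)),
        optics = obj$optics,
        speed_of_sound = config$acquisition$sound_speed)
      ch <- process_pa(ph, obj$array, obj$acq, config, obj)
      img <- das_reconstruct(ch, obj$grid,
                             config$reconstruction$sound_speed, obj$weights)
      tag <- sprintf("depth_%02dmm", as.integer(d))
      emit(ch, paste0(tag, "_pa_channels.txt"), write_channels)
      emit(img, paste0(tag, "_pa_image.txt"), write_image)
      emit(bipolar_colormap(img, obj$display), paste0(tag, "_pa.png"),
           function(x, p) write_png_image(x, p, scale_bar = 10e-3))
    }
  } else if (config$preset == "orientation_study") {
    for (ori in c("in_plane_parallel", "perpendicular_to_plane",
                  "in_plane_vertical")) {
      mk <- make_marker(marker_spec(ph_cfg$depth_mm * 1e-3, ori,
                                    with_hook = ph_cfg$with_hook,
                                    sample_spacing = spacing))
      ph <- make_phantom(mk,
                         scatterers = marker_scatterers(
                           marker_spec(ph_cfg$depth_mm * 1e-3, ori,
                                       with_hook = ph_cfg$with_hook,
                                       sample_spacing = spacing)),
                         optics = obj$optics,
                         speed_of_sound = config$acquisition$sound_speed)
      ch_pa <- process_pa(ph, obj$array, obj$acq, config, obj)
      img_pa <- das_reconstruct(ch_pa, obj$grid,
                                config$reconstruction$sound_speed, obj$weights)
      ch_us <- simulate_us_channels(ph, obj$array, obj$acq)
      img_us <- us_bmode(das_reconstruct(ch_us, obj$grid,
                                         config$reconstruction$sound_speed,
                                         obj$weights),
                         config$display$us_dynamic_range, config$display$gain)
      emit(img_pa, paste0(ori, "_pa_image.txt"), write_image)
      emit(img_us, paste0(ori, "_us_image.txt"), write_image)
      emit(fuse_images(img_pa, img_us, obj$display),
           paste0(ori, "_fused.png"),
           function(x, p) write_png_image(x, p, scale_bar = 10e-3))
    }
  } else { # marker_3d
    arc <- make_arc_array(center_frequency = obj$array$center_frequency,
                          fractional_bandwidth = obj$array$fractional_bandwidth,
                          elevation_sigma = 0.6e-3)
    ys <- seq(-2e-3, 2e-3, by = 1e-3)
    angles <- c(0, 45, 90, 135) * pi / 180
    grid3 <- image_grid(-5e-3, 5e-3, -5e-3, 5e-3, 0.25e-3)
    slices <- lapply(ys, function(y) {
      mk <- make_marker(marker_spec(0, "perpendicular_to_plane",
                                    with_hook = ph_cfg$with_hook,
                                    sample_spacing = spacing))
      mk$z <- mk$z + 0          # marker centered at arc center
      mk$y <- mk$y - y          # slice plane offset along elevation
      ph <- make_phantom(mk, optics = optical_model(mu_eff = 0),
                         speed_of_sound = config$acquisition$sound_speed)
      views <- lapply(angles, function(a) {
        pose <- make_pose(a)
        ch <- simulate_pa_channels(ph, apply_pose(arc, pose), obj$acq)
        ch$geometry <- arc      # store in probe frame; pose applied at recon
        list(channels = ch, pose = pose)
      })
      list(y = y, views = views)
    })
    vol <- reconstruct_volume(slices, grid3,
                              config$reconstruction$sound_speed, obj$weights)
    mip <- mip_render(vol, "y")
    emit(mip, "marker3d_mip_image.txt", write_image)
    emit(vol, "marker3d_volume.tiff", write_tiff_image)
    emit(bipolar_colormap(mip, obj$display), "marker3d_mip.png",
         function(x, p) write_png_image(x, p, scale_bar = 5e-3))
  }
  manifest <- list(preset = config$preset, seed = config$seed,
                   config_hash = config_hash(config), files = files)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
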