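make_scene <- function(n_elements = 32L, n_samples = 2048L) {
  arr <- make_linear_array(n_elements)
  acq <- acquisition_params(n_samples = n_samples)
  list(arr = arr, acq = acq)
}

test_that("vectorized DAS equals the naive per-pixel loop (PA and US)", {
  sc <- make_scene()
  grid <- image_grid(-4e-3, 4e-3, 16e-3, 24e-3, 0.4e-3)
  wts <- weighting_spec(angular_exponent = 1, max_angle = pi / 3)

  ch <- simulate_pa_channels(point_phantom(1e-3, 20e-3), sc$arr, sc$acq)
  img <- das_reconstruct(ch, grid, 1500, wts)
  oracle <- das_naive(ch, grid, 1500, wts)
  expect_rel_equal(img$values, oracle, 1e-6)

  ph_us <- make_phantom(scatterers = data.frame(x = -1e-3, y = 0, z = 20e-3,
                                                reflectivity = 1),
                        optics = optical_model(0))
  chu <- simulate_us_channels(ph_us, sc$arr, sc$acq)
  imgu <- das_reconstruct(chu, grid, 1500, wts)
  expect_identical(imgu$modality, "US_rf")
  expect_rel_equal(imgu$values, das_naive(chu, grid, 1500, wts), 1e-6)

  # different weighting: exponent 2, wide acceptance
  wts2 <- weighting_spec(2, pi / 2)
  expect_rel_equal(das_reconstruct(ch, grid, 1500, wts2)$values,
                   das_naive(ch, grid, 1500, wts2), 1e-6)
})

test_that("a point absorber reconstructs at its true position", {
  arr <- make_linear_array()
  acq <- acquisition_params()
  ch <- simulate_pa_channels(point_phantom(0, 20e-3), arr, acq)
  grid <- image_grid(-5e-3, 5e-3, 15e-3, 25e-3, 0.1e-3)
  pk <- locate_peak(das_reconstruct(ch, grid, 1500))
  err <- sqrt(pk$x^2 + (pk$z - 20e-3)^2)
  expect_lt(err, 0.3e-3)   # within one wavelength at 5 MHz
})

test_that("reconstruction is linear and zero in, zero out", {
  sc <- make_scene()
  grid <- image_grid(-4e-3, 4e-3, 16e-3, 24e-3, 0.2e-3)
  ch <- simulate_pa_channels(point_phantom(0, 20e-3), sc$arr, sc$acq)
  img <- das_reconstruct(ch, grid, 1500)

  scaled <- ch
  scaled$samples <- 1.09 * ch$samples
  expect_equal(das_reconstruct(scaled, grid, 1500)$values, 1.09 * img$values,
               tolerance = 1e-12)

  zero <- ch; zero$samples[] <- 0
  expect_true(all(das_reconstruct(zero, grid, 1500)$values == 0))
})

test_that("lateral phantom shifts translate the reconstructed peak", {
  arr <- make_linear_array()
  acq <- acquisition_params()
  grid <- image_grid(-6e-3, 6e-3, 16e-3, 24e-3, 0.2e-3)
  shift <- 10 * grid$pixel_spacing   # whole-pixel lateral shift
  pk0 <- locate_peak(das_reconstruct(
    simulate_pa_channels(point_phantom(0, 20e-3), arr, acq), grid, 1500))
  pk1 <- locate_peak(das_reconstruct(
    simulate_pa_channels(point_phantom(shift, 20e-3), arr, acq), grid, 1500))
  expect_lt(abs((pk1$x - pk0$x) - shift), 0.2 * grid$pixel_spacing)
  # |peak| may lock onto either lobe of the bipolar pulse; allow the
  # positive-to-negative lobe separation plus a pixel
  expect_lt(abs(pk1$z - pk0$z), 0.5e-3)
})

test_that("out-of-window pixels come back zero with a coverage warning", {
  sc <- make_scene(n_samples = 128L)   # record ends at 3.2 us ~ 4.8 mm
  ch <- simulate_pa_channels(point_phantom(0, 3e-3), sc$arr, sc$acq)
  grid <- image_grid(-2e-3, 2e-3, 2e-3, 40e-3, 1e-3)
  expect_warning(img <- das_reconstruct(ch, grid, 1500), "time window")
  deep <- img$values[img$grid$z > 10e-3, ]
  expect_true(all(deep == 0))
})

test_that("locate_peak refines sub-pixel and breaks ties toward small z then x", {
  grid <- image_grid(0, 4e-3, 0, 4e-3, 1e-3)
  v <- matrix(0, grid$nz, grid$nx)
  v[3, 4] <- 2
  img <- pausim:::new_image(v, grid, "PA")
  pk <- locate_peak(img)
  expect_equal(pk$x, grid$x[4])
  expect_equal(pk$z, grid$z[3])
  expect_equal(pk$amplitude, 2)

  v2 <- matrix(0, grid$nz, grid$nx)
  v2[2, 3] <- 1; v2[4, 3] <- 1      # symmetric tie: smaller z wins
  pk2 <- locate_peak(pausim:::new_image(v2, grid, "PA"))
  expect_equal(pk2$z, grid$z[2])

  expect_error(locate_peak(pausim:::new_image(v2 * 0, grid, "PA")), "no peak")
})

test_that("feature_extent measures the peak's connected component", {
  grid <- image_grid(0, 9e-3, 0, 9e-3, 1e-3)
  v <- matrix(0, grid$nz, grid$nx)
  v[5, 3:7] <- 1                      # 5-pixel horizontal bar
  v[2, 9] <- 0.6                      # disconnected weaker blob
  ext <- feature_extent(pausim:::new_image(v, grid, "PA"), 0.5)
  expect_equal(unname(ext["dx"]), 5e-3)
  expect_equal(unname(ext["dz"]), 1e-3)

  single <- matrix(0, grid$nz, grid$nx); single[4, 4] <- -3
  ext1 <- feature_extent(pausim:::new_image(single, grid, "PA"), 0.5)
  expect_equal(unname(ext1), c(1e-3, 1e-3))
  expect_error(feature_extent(pausim:::new_image(single, grid, "PA"), 1.5),
               "threshold_fraction")
})

test_that("B-mode envelope finds the scatterer and stays in [0, 1]", {
  arr <- make_linear_array()
  acq <- acquisition_params()
  ph <- make_phantom(scatterers = data.frame(x = 2e-3, y = 0, z = 20e-3,
                                             reflectivity = 1),
                     optics = optical_model(0))
  grid <- image_grid(-5e-3, 5e-3, 15e-3, 25e-3, 0.1e-3)
  rf <- das_reconstruct(simulate_us_channels(ph, arr, acq), grid, 1500)
  bm <- us_bmode(rf, dynamic_range = 40)
  expect_identical(bm$modality, "US_bmode")
  expect_true(all(bm$values >= 0 & bm$values <= 1))
  pk <- which(bm$values == max(bm$values), arr.ind = TRUE)
  err <- sqrt((grid$x[pk[1, 2]] - 2e-3)^2 + (grid$z[pk[1, 1]] - 20e-3)^2)
  expect_lt(err, 0.3e-3)

  zero <- rf; zero$values[] <- 0
  expect_true(all(us_bmode(zero)$values == 0))
  pa_img <- das_reconstruct(simulate_pa_channels(point_phantom(), arr, acq),
                            grid, 1500)
  expect_error(us_bmode(pa_img), "US_rf")
})

test_that("multi-view reduction, improvement and rotational equivariance", {
  arc <- make_arc_array(n_elements = 64L)
  acq <- acquisition_params(n_samples = 4096L)
  ph <- point_phantom(0, 0)
  grid <- image_grid(-2e-3, 2e-3, -2e-3, 2e-3, 0.05e-3)
  make_view <- function(angle, phantom = ph) {
    pose <- make_pose(angle)
    ch <- simulate_pa_channels(phantom, apply_pose(arc, pose), acq)
    ch$geometry <- arc
    list(channels = ch, pose = pose)
  }

  v0 <- make_view(0)
  expect_identical(
    multi_view_reconstruct(list(v0), grid, 1500)$values,
    das_reconstruct(v0$channels, grid, 1500)$values)

  views <- lapply(c(0, 45, 90, 135) * pi / 180, make_view)
  f1 <- lateral_fwhm(multi_view_reconstruct(views[1], grid, 1500))
  f4 <- lateral_fwhm(multi_view_reconstruct(views, grid, 1500))
  expect_lte(f4, f1)

  # rotating phantom and poses by 90 deg rotates the image by 90 deg
  ph_off <- point_phantom(0.6e-3, 0.4e-3)
  img_a <- multi_view_reconstruct(lapply(c(0, pi / 2), make_view,
                                         phantom = ph_off), grid, 1500)
  ph_rot <- point_phantom(-0.4e-3, 0.6e-3)   # (x,z) -> (-z,x)
  img_b <- multi_view_reconstruct(lapply(c(0, pi / 2) + pi / 2, make_view,
                                         phantom = ph_rot), grid, 1500)
  # img_b should equal img_a rotated by 90 deg in the symmetric square grid
  rot90 <- function(m) t(m)[, rev(seq_len(ncol(m)))]
  a <- img_a$values
  b <- img_b$values
  # map pixel (x,z) -> (-z,x): values_b[iz, ix] = values_a[z = x_new...]
  expect_lt(max(abs(b - rot90(a))) / max(abs(a)), 1e-3)

  expect_error(multi_view_reconstruct(list(), grid, 1500), "at least one")
})

test_that("volumes stack slices along y with strict ordering", {
  arc <- make_arc_array(n_elements = 32L)
  acq <- acquisition_params(n_samples = 4096L)
  grid <- image_grid(-2e-3, 2e-3, -2e-3, 2e-3, 0.2e-3)
  mk_slice <- function(y, phantom) {
    ch <- simulate_pa_channels(phantom, arc, acq)
    list(y = y, views = list(list(channels = ch, pose = make_pose())))
  }
  ph <- point_phantom(0, 0)
  one <- reconstruct_volume(list(mk_slice(0, ph)), grid, 1500)
  expect_equal(dim(one$values), c(1L, grid$nz, grid$nx))
  expect_equal(one$values[1, , ],
               multi_view_reconstruct(
                 list(list(channels = simulate_pa_channels(ph, arc, acq),
                           pose = make_pose())), grid, 1500)$values)

  empty_ph <- make_phantom()
  vol0 <- reconstruct_volume(list(mk_slice(0, empty_ph), mk_slice(1e-3, empty_ph)),
                             grid, 1500)
  expect_true(all(vol0$values == 0))

  expect_error(reconstruct_volume(list(mk_slice(0, ph), mk_slice(0, ph)),
                                  grid, 1500), "duplicate")
  expect_error(reconstruct_volume(list(mk_slice(1e-3, ph), mk_slice(0, ph)),
                                  grid, 1500), "increasing")
})

test_that("a marker spanning the elevation axis spans the matching y slices", {
  # elevational focusing (the arc's focal geometry) keeps each slice thin
  arc <- make_arc_array(n_elements = 48L, elevation_sigma = 0.6e-3)
  acq <- acquisition_params(n_samples = 4096L)
  grid <- image_grid(-2e-3, 2e-3, -2e-3, 2e-3, 0.1e-3)
  ys <- seq(-2.5e-3, 2.5e-3, by = 0.5e-3)
  base <- make_marker(marker_spec(1e-6, "perpendicular_to_plane",
                                  sample_spacing = 0.25e-3))
  base$z <- base$z - 1e-6   # marker centered at the arc center
  slices <- lapply(ys, function(y) {
    mk <- base; mk$y <- mk$y - y
    ph <- make_phantom(mk, optics = optical_model(0))
    ch <- simulate_pa_channels(ph, arc, acq)
    list(y = y, views = list(list(channels = ch, pose = make_pose())))
  })
  vol <- reconstruct_volume(slices, grid, 1500)
  prof <- apply(pmax(vol$values, 0), 1, max)
  span <- diff(range(ys[prof >= max(prof) / 2]))
  expect_lt(abs(span - 3e-3), 2 * 0.5e-3)
})
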