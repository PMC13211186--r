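# Synthetic scene generator: ground-truth fidelity, determinism, noise and
# jitter statistics.

test_that("empty and single-disk scenes render with exact ground truth", {
  out <- render_scene(scene_spec(64, 48, background_level = 180, noise_sd = 0))
  expect_equal(dim(out$image), c(48, 64))
  expect_true(all(out$image == 180))
  expect_equal(nrow(out$truth), 0)

  spec <- scene_spec(256, 256,
                     circles = data.frame(cx_px = 100, cy_px = 100,
                                          radius_px = 50, contrast = -100),
                     noise_sd = 0)
  out <- render_scene(spec)
  expect_equal(out$truth$cx_px, 100)
  expect_equal(out$truth$cy_px, 100)
  expect_equal(out$truth$radius_px, 50)
})

test_that("disk area matches the analytic value within 3%", {
  spec <- scene_spec(256, 256, background_level = 200,
                     circles = data.frame(cx_px = 100, cy_px = 100,
                                          radius_px = 50, contrast = -100),
                     noise_sd = 0, edge_softness_px = 2)
  img <- render_scene(spec)$image
  # pixels at least half the contrast below background lie inside the rim
  n_disk <- sum(img <= 200 - 50)
  expect_lt(abs(n_disk - pi * 50^2) / (pi * 50^2), 0.03)
})

test_that("circle invariants are enforced", {
  expect_error(scene_spec(100, 100,
                          circles = data.frame(cx_px = 150, cy_px = 50,
                                               radius_px = 10, contrast = -50)),
               "inside the image")
  expect_error(scene_spec(100, 100,
                          circles = data.frame(cx_px = 50, cy_px = 50,
                                               radius_px = 2, contrast = -50)),
               "radius_px")
})

test_that("rendering is deterministic and clipped to the bit range", {
  spec <- scene_spec(80, 80,
                     circles = data.frame(cx_px = 40, cy_px = 40,
                                          radius_px = 20, contrast = -250),
                     noise_sd = 10, seed = 7)
  a <- render_scene(spec)$image
  b <- render_scene(spec)$image
  expect_identical(a, b)
  expect_gte(min(a), 0)
  expect_lte(max(a), 255)
})

test_that("noiseless disk centroid stays within 0.5 px of the true center", {
  for (ctr in list(c(61.3, 44.8), c(40, 40.5))) {
    spec <- scene_spec(120, 120,
                       circles = data.frame(cx_px = ctr[1], cy_px = ctr[2],
                                            radius_px = 25, contrast = -100),
                       noise_sd = 0)
    img <- render_scene(spec)$image
    wgt <- 200 - img
    xs <- matrix(rep(0:119, each = 120), 120, 120)
    ys <- matrix(rep(0:119, times = 120), 120, 120)
    expect_lt(abs(sum(wgt * xs) / sum(wgt) - ctr[1]), 0.5)
    expect_lt(abs(sum(wgt * ys) / sum(wgt) - ctr[2]), 0.5)
  }
})

test_that("pixel noise reproduces the requested standard deviation", {
  spec0 <- scene_spec(128, 128, noise_sd = 0)
  spec5 <- scene_spec(128, 128, noise_sd = 5, seed = 11)
  resid <- render_scene(spec5)$image - render_scene(spec0)$image
  expect_gte(length(resid), 1e4)
  expect_lt(abs(stats::sd(resid) - 5) / 5, 0.10)
})

test_that("zero-jitter sequences repeat the single frame bit-identically", {
  spec <- scene_spec(96, 96,
                     circles = data.frame(cx_px = 48, cy_px = 48,
                                          radius_px = 20, contrast = -80),
                     noise_sd = 3, seed = 5)
  seq0 <- render_sequence(spec, 5, jitter_sd_px = 0)
  base <- render_scene(spec)$image
  for (f in seq0$frames) expect_identical(f, base)
  # determinism of the jittered path
  s1 <- render_sequence(spec, 4, jitter_sd_px = 1)
  s2 <- render_sequence(spec, 4, jitter_sd_px = 1)
  expect_identical(s1, s2)
})

test_that("center jitter has the requested per-axis spread", {
  spec <- scene_spec(200, 200,
                     circles = data.frame(cx_px = 100, cy_px = 100,
                                          radius_px = 20, contrast = -80),
                     noise_sd = 0, seed = 3)
  sq <- render_sequence(spec, 200, jitter_sd_px = 1)
  expect_lt(abs(stats::sd(sq$truth$cx_px) - 1), 0.15)
  expect_lt(abs(stats::sd(sq$truth$cy_px) - 1), 0.15)
  expect_error(render_sequence(spec, 0), "n_frames")
})

test_that("micrometer targets place rulings at the specified pitch", {
  spec <- micrometer_spec(900, 60, spacing_um = 100, um_per_px = 0.5)
  out <- render_micrometer(spec)
  expect_equal(diff(out$positions_px), rep(200, length(out$positions_px) - 1))

  spec2 <- micrometer_spec(400, 60, spacing_um = 100, um_per_px = 1.0)
  out2 <- render_micrometer(spec2)
  expect_equal(length(out2$positions_px),
               sum(seq(50, 399, by = 100) <= 399))

  # ground truth independent of noise
  spec3 <- micrometer_spec(400, 60, spacing_um = 100, um_per_px = 1.0,
                           noise_sd = 5, seed = 9)
  expect_equal(render_micrometer(spec3)$positions_px, out2$positions_px)

  # unresolvable rulings rejected
  expect_error(micrometer_spec(400, 60, spacing_um = 4, um_per_px = 1,
                               line_width_px = 3), "resolvable")
})
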