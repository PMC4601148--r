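test_that("scene spec validation names the offending field", {
  expect_error(scene_spec(coloc_fraction = 1.2), "coloc_fraction")
  expect_error(scene_spec(pixel_size = 0), "pixel_size")
  expect_error(scene_spec(n_nuclei = -1), "n_nuclei")
  expect_error(scene_spec(focus_sigma_range = c(2, 1)), "focus_sigma_range")
  expect_error(scene_spec(pan_nuclear_fraction = 2), "pan_nuclear_fraction")
})

test_that("impossible nucleus packing raises a placement error", {
  sp <- scene_spec(image_shape = c(128, 128), n_nuclei = 30,
                   nucleus_radius_range = c(20, 24), seed = 1)
  expect_error(generate_scene(sp), "non-overlapping|do not fit")
})

test_that("identical spec and seed give bit-identical scenes and truth", {
  sp <- scene_spec(n_nuclei = 3, foci_per_nucleus = 10, seed = 7,
                   image_shape = c(192, 192))
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$scene$data, s2$scene$data)
  expect_identical(s1$truth, s2$truth)
})

test_that("no foci and no noise leaves channel A flat at background", {
  sp <- scene_spec(n_nuclei = 1, foci_per_nucleus = 0, noise_sigma = 0,
                   background_level = 0, image_shape = c(128, 128), seed = 2)
  sc <- generate_scene(sp)
  expect_true(all(get_channel(sc$scene, "A") == 0))
  expect_equal(nrow(sc$truth$foci_A), 0)
})

test_that("full colocalized fraction duplicates every channel-A focus in B", {
  sp <- scene_spec(n_nuclei = 3, foci_per_nucleus = 5, coloc_fraction = 1,
                   independent_foci_B = 0, noise_sigma = 0, seed = 9,
                   image_shape = c(256, 256))
  tr <- generate_scene(sp)$truth
  expect_equal(nrow(tr$foci_B), nrow(tr$foci_A))
  b_of_a <- tr$foci_B[match(tr$foci_A$id, tr$foci_B$paired_with), ]
  expect_equal(b_of_a$row, tr$foci_A$row)
  expect_equal(b_of_a$col, tr$foci_A$col)
})

test_that("planted pair count equals round(coloc_fraction x n_foci_A)", {
  for (f in c(0, 0.25, 0.5, 0.77, 1)) {
    sp <- scene_spec(n_nuclei = 4, foci_per_nucleus = 7, coloc_fraction = f,
                     independent_foci_B = 0, seed = 20 + round(100 * f),
                     image_shape = c(256, 256))
    tr <- generate_scene(sp)$truth
    expect_equal(nrow(tr$colocalized_pairs), round(f * nrow(tr$foci_A)))
  }
})

test_that("every planted focus lies inside its nucleus and is visible without noise", {
  sp <- scene_spec(n_nuclei = 4, foci_per_nucleus = 8, noise_sigma = 0,
                   seed = 5, image_shape = c(256, 256))
  sc <- generate_scene(sp)
  tr <- sc$truth
  A <- get_channel(sc$scene, "A")
  for (i in seq_len(nrow(tr$foci_A))) {
    f <- tr$foci_A[i, ]
    nu <- tr$nuclei[tr$nuclei$label == f$nucleus, ]
    u <- cos(nu$theta) * (f$col - nu$col) + sin(nu$theta) * (f$row - nu$row)
    v <- -sin(nu$theta) * (f$col - nu$col) + cos(nu$theta) * (f$row - nu$row)
    expect_lte((u / nu$a)^2 + (v / nu$b)^2, 1)
    expect_gt(A[round(f$row), round(f$col)], sp$background_level)
  }
})

test_that("focus footprint at half-maximum grows with sigma", {
  areas <- vapply(c(1, 2, 3), function(s) {
    sp <- scene_spec(n_nuclei = 1, foci_per_nucleus = 1,
                     focus_sigma_range = c(s, s), noise_sigma = 0,
                     background_level = 0, image_shape = c(128, 128),
                     nucleus_radius_range = c(25, 30), seed = 31)
    A <- get_channel(generate_scene(sp)$scene, "A")
    sum(A >= max(A) / 2)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("minimum focus spacing is honoured when feasible", {
  sp <- scene_spec(n_nuclei = 3, foci_per_nucleus = 6, min_focus_spacing = 9,
                   noise_sigma = 0, seed = 13, image_shape = c(256, 256))
  tr <- generate_scene(sp)$truth
  expect_true(all(min_focus_spacing_per_nucleus(tr) >= 9))
})

test_that("pan-nuclear nuclei are rendered dense and recorded in truth", {
  sp <- scene_spec(n_nuclei = 4, pan_nuclear_fraction = 0.5, noise_sigma = 0,
                   seed = 17, image_shape = c(256, 256))
  sc <- generate_scene(sp)
  expect_length(sc$truth$pan_nuclear_labels, 2)
  A <- get_channel(sc$scene, "A")
  for (lab in sc$truth$pan_nuclear_labels) {
    nu <- sc$truth$nuclei[sc$truth$nuclei$label == lab, ]
    expect_equal(A[round(nu$row), round(nu$col)],
                 sp$background_level + 1.5 * sp$focus_amplitude)
  }
  # no discrete foci are planted in pan-nuclear nuclei
  expect_false(any(sc$truth$foci_A$nucleus %in% sc$truth$pan_nuclear_labels))
})

test_that("timecourse retention is validated and respected at the extremes", {
  sp <- scene_spec(n_nuclei = 2, foci_per_nucleus = 5, seed = 3,
                   image_shape = c(192, 192))
  expect_error(generate_timecourse(sp, c(1, 4), c("1" = 1, "4" = 1.5)),
               "\\[0, 1\\]")
  expect_error(generate_timecourse(sp, c(1, 4), c("1" = 0.5, "4" = 0.5)),
               "first timepoint")
  tc <- generate_timecourse(sp, c(1, 4, 72),
                            c("1" = 1, "4" = 1, "72" = 0))
  expect_equal(nrow(tc[[1]]$truth$foci_A), nrow(tc[[2]]$truth$foci_A))
  expect_equal(nrow(tc[[3]]$truth$foci_A), 0)
})

test_that("timecourse focus survival follows the binomial retention model", {
  # 50 nuclei x 20 foci = 1000 Bernoulli trials at p = 0.37
  sp <- scene_spec(image_shape = c(800, 800), n_nuclei = 50,
                   foci_per_nucleus = 20, seed = 41)
  tc <- generate_timecourse(sp, c(1, 48), c("1" = 1, "48" = 0.37))
  n0 <- nrow(tc[[1]]$truth$foci_A)
  frac <- nrow(tc[[2]]$truth$foci_A) / n0
  tol <- 3 * sqrt(0.37 * 0.63 / n0)
  expect_lt(abs(frac - 0.37), tol)
})
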