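test_that("sub-3-pixel blobs are discarded as noise", {
  # one nucleus disk; a 2-pixel bright blob and a 5-pixel bright blob
  dna <- disk_image(64, 32, 32, 20)
  mask <- segment_nuclei(dna, min_area = 50)
  ch <- matrix(100, 64, 64)
  ch[32, 30:31] <- 1000                 # 2 px: below the noise floor
  ch[22:23, 22:23] <- 1000; ch[22, 24] <- 1000  # 5 px: a real focus
  det <- detect_foci(ch, mask, pixel_size = 0.285)
  expect_equal(det$summaries$focus_count, 1)
  expect_equal(det$records$area_px, 5L)
})

test_that("areas convert to um^2 by the squared pixel size", {
  sp <- scene_spec(n_nuclei = 2, noise_sigma = 0, min_focus_spacing = 8,
                   seed = 23, image_shape = c(256, 256))
  sc <- generate_scene(sp)
  mask <- segment_nuclei(get_channel(sc$scene, "dna"))
  det <- detect_foci(get_channel(sc$scene, "A"), mask, sp$pixel_size)
  expect_equal(det$records$area_um2, det$records$area_px * sp$pixel_size^2)
  # the 3-pixel noise floor at the 0.285 um projection pixel is 0.24 um^2
  expect_equal(round(3 * 0.285^2, 2), 0.24)
})

test_that("planted foci are recovered exactly on noise-free scenes", {
  for (seed in c(101, 102)) {
    sp <- scene_spec(n_nuclei = 5, foci_per_nucleus = 10, noise_sigma = 0,
                     min_focus_spacing = 8, seed = seed)
    sc <- generate_scene(sp)
    mask <- segment_nuclei(get_channel(sc$scene, "dna"))
    det <- detect_foci(get_channel(sc$scene, "A"), mask, sp$pixel_size)
    lab_of <- truth_to_mask_label(sc$truth, mask)
    planted <- table(factor(sc$truth$foci_A$nucleus,
                            levels = sc$truth$nuclei$label))
    detected <- det$summaries$focus_count[match(lab_of,
                                                det$summaries$nucleus_label)]
    expect_equal(unname(detected), as.vector(planted))
  }
})

test_that("focus counts are invariant under intensity rescaling", {
  sp <- scene_spec(n_nuclei = 3, noise_sigma = 0, min_focus_spacing = 8,
                   seed = 31, image_shape = c(256, 256))
  sc <- generate_scene(sp)
  mask <- segment_nuclei(get_channel(sc$scene, "dna"))
  A <- get_channel(sc$scene, "A")
  d1 <- detect_foci(A, mask, sp$pixel_size)
  d2 <- detect_foci(A * 0.3, mask, sp$pixel_size)
  expect_equal(d1$summaries$focus_count, d2$summaries$focus_count)
  expect_equal(d1$records$area_px, d2$records$area_px)
})

test_that("pan-nuclear nuclei are flagged and excluded; focal nuclei are not", {
  sp <- scene_spec(n_nuclei = 4, pan_nuclear_fraction = 0.25, noise_sigma = 0,
                   min_focus_spacing = 8, seed = 29, image_shape = c(384, 384))
  sc <- generate_scene(sp)
  mask <- segment_nuclei(get_channel(sc$scene, "dna"))
  A <- get_channel(sc$scene, "A")
  flags <- flag_pan_nuclear(A, mask)
  lab_of <- truth_to_mask_label(sc$truth, mask)
  pan_mask_labels <- lab_of[sc$truth$nuclei$pan_nuclear]
  expect_setequal(which(flags), pan_mask_labels)

  det <- detect_foci(A, mask, sp$pixel_size)
  expect_true(all(det$summaries$excluded[det$summaries$pan_nuclear]))
  expect_false(any(det$records$nucleus_label %in% pan_mask_labels))
})

test_that("sparse foci and background-only nuclei are never pan-flagged", {
  dna <- disk_image(96, 30, 30, 18) + disk_image(96, 66, 66, 18)
  mask <- segment_nuclei(dna, min_area = 50)
  ch <- matrix(100, 96, 96)
  ch[28:30, 28:30] <- 5000  # small foci in nucleus 1, < 5 % coverage
  flags <- flag_pan_nuclear(ch, mask, coverage_cutoff = 0.5)
  expect_false(any(flags))
  expect_error(flag_pan_nuclear(ch, mask, coverage_cutoff = 1.5), "(0, 1)")
})

test_that("PAF histogram bins, fractions, peak and mean behave as specified", {
  h1 <- paf_histogram(rep(0.45, 8))
  expect_equal(sum(h1$table$count > 0), 1)
  occupied <- h1$table[h1$table$count > 0, ]
  expect_equal(c(occupied$bin_low, occupied$bin_high), c(0.4, 0.5))
  expect_equal(occupied$fraction, 1)
  expect_equal(h1$peak_bin, c(0.4, 0.5))

  h2 <- paf_histogram(c(0.24, 0.45, 5.6))
  tab <- h2$table
  expect_equal(tab$count[tab$bin_low == 0.2], 1)
  expect_equal(tab$count[tab$bin_low == 0.4], 1)
  expect_equal(tab$count[is.infinite(tab$bin_high)], 1)
  expect_equal(sum(tab$count), 3)
  expect_equal(sum(tab$fraction), 1)

  expect_equal(paf_histogram(c(0.6, 1.0, 0.83))$mean_um2, 0.81)

  h0 <- paf_histogram(numeric(0))
  expect_true(is.na(h0$mean_um2))
  expect_equal(h0$n, 0)

  set.seed(9)
  hr <- paf_histogram(runif(200, 0.05, 8))
  expect_equal(sum(hr$table$fraction), 1)
  expect_equal(sum(hr$table$count), 200)
})

test_that("mean foci per nucleus: closed-form SE and exclusion rule", {
  s <- data.frame(nucleus_label = 1:3, focus_count = c(5L, 5L, 5L),
                  pan_nuclear = FALSE, excluded = FALSE)
  r <- mean_foci_per_nucleus(s)
  expect_equal(r$mean, 5); expect_equal(r$se, 0)

  s2 <- data.frame(nucleus_label = 1:3, focus_count = c(1L, 2L, 3L),
                   pan_nuclear = FALSE, excluded = FALSE)
  r2 <- mean_foci_per_nucleus(s2)
  expect_equal(r2$mean, 2)
  expect_equal(r2$se, 1 / sqrt(3))
  expect_equal(r2$se3, 3 / sqrt(3))

  s3 <- data.frame(nucleus_label = 1:3, focus_count = c(NA, 4L, 6L),
                   pan_nuclear = c(TRUE, FALSE, FALSE),
                   excluded = c(TRUE, FALSE, FALSE))
  r3 <- mean_foci_per_nucleus(s3)
  expect_equal(r3$mean, 5); expect_equal(r3$n, 2)

  expect_warning(r1 <- mean_foci_per_nucleus(s3[1:2, ]), "SE undefined")
  expect_true(is.na(r1$se))
})
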