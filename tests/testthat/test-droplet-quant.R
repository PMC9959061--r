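test_that("flat images yield no droplets; noiseless disks are found exactly", {
  mk <- liver_mask(matrix(TRUE, 64, 64))
  flat <- const_image(50, "lipid_green", 64, 64)
  expect_warning(dr <- segment_droplets(flat, mk),
                 class = "staz_flat_intensity_warning")
  expect_length(dr, 0L)

  centers <- as.matrix(expand.grid(c(10, 25, 40, 55), c(12, 32, 52)))[1:10, ]
  sl <- disk_slice(centers, radius = 3)
  dr <- segment_droplets(sl$green, sl$mask)
  expect_length(dr, 10L)
  areas <- vapply(dr, `[[`, numeric(1), "area_px")
  expect_true(all(abs(areas - pi * 9) / (pi * 9) <= 0.2))
})

test_that("min_area_px removes sub-resolution specks", {
  centers <- as.matrix(expand.grid(c(10, 25, 40, 55), c(12, 32, 52)))[1:10, ]
  sl <- disk_slice(centers, radius = 3)
  px <- sl$green$pixels
  px[60, 60] <- 210  # single-pixel speck
  g <- channel_image(px, "lipid_green")
  cfg0 <- segmentation_config(smoothing_radius_px = 0, min_area_px = 1)
  cfg4 <- segmentation_config(smoothing_radius_px = 0, min_area_px = 4)
  expect_length(segment_droplets(g, sl$mask, cfg0), 11L)
  expect_length(segment_droplets(g, sl$mask, cfg4), 10L)
})

test_that("components are 8-connected and clipped to the mask", {
  px <- matrix(0, 12, 12)
  px[3, 3] <- px[4, 4] <- px[5, 5] <- px[6, 6] <- 100  # diagonal chain
  g <- channel_image(px, "lipid_green")
  mk <- liver_mask(matrix(TRUE, 12, 12))
  cfg <- segmentation_config(smoothing_radius_px = 0, min_area_px = 1,
                             threshold_method = "fixed", fixed_threshold = 50)
  dr <- segment_droplets(g, mk, cfg)
  expect_length(dr, 1L)
  expect_identical(dr[[1]]$area_px, 4L)

  half <- matrix(FALSE, 12, 12); half[, 1:4] <- TRUE
  dr2 <- segment_droplets(g, liver_mask(half), cfg)
  expect_length(dr2, 1L)
  expect_identical(dr2[[1]]$area_px, 2L)  # chain clipped at column 4
})

test_that("quantify_droplets matches the stated definitions", {
  mk <- square_mask(104, 104, 3, 102, 3, 102)  # 100x100 liver = 10000 px
  q0 <- quantify_droplets(list(), mk)
  expect_identical(q0$ld_dens, 0)
  expect_identical(q0$ld_area, 0)

  # 5 droplets totalling 500 px
  fake <- lapply(0:4, function(k) {
    rows <- (4 + k * 12):(13 + k * 12)
    pts <- as.matrix(expand.grid(rows, 11:20))
    list(pixel_set = pts, area_px = 100L,
         centroid = colMeans(pts), equiv_diameter_px = 2 * sqrt(100 / pi))
  })
  q <- quantify_droplets(fake, mk)
  expect_equal(q$ld_dens, 5e-4)
  expect_equal(q$ld_area, 0.05)

  whole <- list(list(pixel_set = which(mk$mask, arr.ind = TRUE),
                     area_px = mk$area_px, centroid = c(52, 52),
                     equiv_diameter_px = 2 * sqrt(mk$area_px / pi)))
  expect_equal(quantify_droplets(whole, mk)$ld_area, 1.0)

  outside <- list(list(pixel_set = matrix(c(1L, 1L), 1), area_px = 1L,
                       centroid = c(1, 1), equiv_diameter_px = 1))
  expect_error(quantify_droplets(outside, mk),
               class = "staz_consistency_error")
})

test_that("ld_area equals a brute-force threshold count on small images", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    sim <- simulate_larva(larva_sim_params(
      image_size = c(64, 64), liver_center = c(32, 32),
      liver_axes = c(20, 14), seed = seed))
    sl <- sim$record$slices[[1]]
    cfg <- segmentation_config(min_area_px = 1L)
    dr <- segment_droplets(sl$channels$lipid_green, sl$mask, cfg)
    thr <- attr(dr, "threshold")
    smoothed <- stazr:::median_smooth(sl$channels$lipid_green$pixels, 1L)
    brute <- 0L
    for (r in 1:64) for (c in 1:64)
      if (sl$mask$mask[r, c] && smoothed[r, c] > thr) brute <- brute + 1L
    q <- quantify_droplets(dr, sl$mask)
    expect_equal(q$ld_area, brute / sl$mask$area_px, tolerance = 1e-12)
  }
})

test_that("Otsu-mode segmentation is invariant to intensity rescaling", {
  sim <- simulate_larva(larva_sim_params(seed = 17))
  sl <- sim$record$slices[[1]]
  dr1 <- segment_droplets(sl$channels$lipid_green, sl$mask)
  for (fac in c(0.25, 8)) {
    g2 <- channel_image(sl$channels$lipid_green$pixels * fac, "lipid_green")
    dr2 <- segment_droplets(g2, sl$mask)
    expect_identical(lapply(dr2, `[[`, "pixel_set"),
                     lapply(dr1, `[[`, "pixel_set"))
  }
  # non-dyadic factors may move the threshold by one ulp; the droplet set
  # itself must still be stable
  g3 <- channel_image(sl$channels$lipid_green$pixels * 3, "lipid_green")
  dr3 <- segment_droplets(g3, sl$mask)
  expect_identical(length(dr3), length(dr1))
  expect_equal(vapply(dr3, `[[`, numeric(1), "area_px"),
               vapply(dr1, `[[`, numeric(1), "area_px"))
})

test_that("watershed splitting separates touching blobs", {
  px <- matrix(0, 30, 30)
  for (r in 1:30) for (c in 1:30) {
    if ((r - 15)^2 + (c - 11)^2 <= 16 || (r - 15)^2 + (c - 19)^2 <= 16)
      px[r, c] <- 200
  }
  g <- channel_image(px, "lipid_green")
  mk <- liver_mask(matrix(TRUE, 30, 30))
  cfg <- segmentation_config(smoothing_radius_px = 0,
                             threshold_method = "fixed",
                             fixed_threshold = 100)
  expect_length(segment_droplets(g, mk, cfg), 1L)
  cfgw <- segmentation_config(smoothing_radius_px = 0,
                              threshold_method = "fixed",
                              fixed_threshold = 100, split_touching = TRUE)
  expect_length(segment_droplets(g, mk, cfgw), 2L)
})
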