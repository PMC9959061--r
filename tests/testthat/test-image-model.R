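test_that("channel_image and liver_mask enforce their invariants", {
  expect_error(channel_image(matrix(-1, 2, 2), "lipid_green"),
               class = "staz_format_error")
  expect_error(channel_image(matrix(1, 2, 2), "nonsense"))
  expect_error(liver_mask(matrix(FALSE, 3, 3)),
               class = "staz_empty_roi_error")
  m <- liver_mask(matrix(c(0, 1, 2, 0), 2, 2))
  expect_identical(m$area_px, 2L)
  expect_identical(m$area_px, sum(m$mask))
})

test_that("slice_record rejects mixed channel pairs and shape mismatches", {
  g <- const_image(1, "lipid_green")
  b <- const_image(1, "norm_blue")
  o <- const_image(1, "gp_ordered")
  mk <- square_mask()
  expect_s3_class(slice_record("L1", 1, list(g, b), mk), "slice_record")
  expect_error(slice_record("L1", 1, list(g, o), mk),
               class = "staz_config_error")
  small <- liver_mask(matrix(TRUE, 4, 4))
  expect_error(slice_record("L1", 1, list(g, b), small),
               class = "staz_shape_error")
  expect_error(larva_record("L1", "B1", "DMSO", NA,
                            list(slice_record("L1", 1, list(g, b), mk),
                                 slice_record("L1", 1, list(g, b), mk))),
               class = "staz_config_error")
})

test_that("multi-plane TIFF round trip is lossless for 16-bit data", {
  withr::local_seed(1)
  a <- matrix(sample.int(65536L, 64 * 64, replace = TRUE) - 1L, 64, 64)
  a[1, 1] <- 65535L
  b <- matrix(sample.int(65536L, 64 * 64, replace = TRUE) - 1L, 64, 64)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(a / 65535, b / 65535), path, bits.per.sample = 16L)
  ch <- read_multichannel_tiff(path, c(lipid_green = 1, norm_blue = 2))
  expect_named(ch, c("lipid_green", "norm_blue"))
  expect_equal(ch$lipid_green$pixels, a, ignore_attr = TRUE, tolerance = 0)
  expect_equal(ch$norm_blue$pixels, b, ignore_attr = TRUE, tolerance = 0)
  expect_equal(max(ch$lipid_green$pixels), 65535)
  expect_error(read_multichannel_tiff(path, c(lipid_green = 3)),
               class = "staz_config_error")
  expect_error(read_multichannel_tiff("no/such/file.tif",
                                      c(lipid_green = 1)),
               class = "staz_io_error")
})

test_that("mask images load with nonzero-equals-liver and dims checked", {
  path <- withr::local_tempfile(fileext = ".png")
  m <- matrix(0, 20, 20)
  m[6:15, 6:15] <- 1
  png::writePNG(m, path)
  mk <- read_mask(path, c(20, 20))
  expect_identical(mk$area_px, 100L)
  expect_error(read_mask(path, c(10, 20)), class = "staz_shape_error")
  png::writePNG(matrix(0, 20, 20), path)
  expect_error(read_mask(path, c(20, 20)), class = "staz_empty_roi_error")
})

test_that("rectangular ImageJ ROI rasterizes to the pixel-centre count", {
  path <- withr::local_tempfile(fileext = ".roi")
  write_roi_rect(path, top = 3, left = 2, bottom = 9, right = 6)
  mk <- read_mask(path, c(16, 16))
  # pixel centres (c + .5, r + .5) strictly inside [2,6] x [3,9]:
  # cols 2..5, rows 3..8 -> 4 x 6 pixels
  expect_identical(mk$area_px, 24L)
  expect_true(all(which(mk$mask, arr.ind = TRUE)[, 1] %in% 4:9))
  expect_true(all(which(mk$mask, arr.ind = TRUE)[, 2] %in% 3:6))
})

test_that("polygon and oval ROIs agree with an independent containment scan", {
  path <- withr::local_tempfile(fileext = ".roi")
  x <- c(2L, 14L, 14L, 8L, 2L)
  y <- c(3L, 3L, 11L, 15L, 11L)
  write_roi_polygon(path, x, y)
  mk <- read_mask(path, c(18, 18))
  ref <- matrix(FALSE, 18, 18)
  inside <- function(px, py) {  # independent even-odd scan
    n <- length(x); cnt <- 0L; j <- n
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py) &&
          px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
        cnt <- cnt + 1L
      j <- i
    }
    cnt %% 2L == 1L
  }
  for (r in 1:18) for (c in 1:18) ref[r, c] <- inside(c - 0.5, r - 0.5)
  expect_identical(mk$mask, ref)

  write_roi_oval(path, top = 2, left = 2, bottom = 12, right = 10)
  mk2 <- read_mask(path, c(16, 16))
  ref2 <- matrix(FALSE, 16, 16)
  for (r in 1:16) for (c in 1:16)
    ref2[r, c] <- ((c - 0.5 - 6) / 4)^2 + ((r - 0.5 - 7) / 5)^2 <= 1
  expect_identical(mk2$mask, ref2)
})

test_that("results tables round-trip numerics to 1e-12", {
  df <- data.frame(larva_id = c("L1", "L2", "L3"),
                   score = c(pi, exp(1) * 1e-7, -123.456789012345),
                   n_slices = c(3L, 3L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(df, path)
  expect_identical(length(readLines(path)), 4L)
  back <- read_results_table(path)
  expect_equal(back$score, df$score, tolerance = 1e-12)
  expect_identical(back$n_slices, df$n_slices)

  write_results_table(df[0, ], path)
  expect_identical(length(readLines(path)), 1L)
})

test_that("sample sheets validate columns, uniqueness and file existence", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)),
                  file.path(dir, "img.tif"))
  png::writePNG(matrix(1, 8, 8), file.path(dir, "mask.png"))
  sheet <- data.frame(larva_id = "L1", batch_id = "B1", treatment = "DMSO",
                      concentration = NA, slice_index = 1,
                      image_path = "img.tif", mask_path = "mask.png")
  p <- file.path(dir, "samples.csv")
  write_results_table(sheet, p)
  loaded <- read_sample_sheet(p)
  expect_true(file.exists(loaded$image_path[1]))

  bad <- sheet; bad$image_path <- "absent.tif"
  write_results_table(bad, p)
  expect_error(read_sample_sheet(p), class = "staz_io_error")

  dup <- rbind(sheet, sheet)
  write_results_table(dup, p)
  expect_error(read_sample_sheet(p), class = "staz_config_error")
})
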