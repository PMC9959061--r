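#' Read planes of a multi-page TIFF as channel images
#'
#' Planes are read losslessly: integer sample formats keep their integer
#' values (a 16-bit pixel of 65535 reads back as 65535), float data is
#' passed through. Channel identity is always taken from `channel_map`,
#' never guessed from intensities.
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector mapping role -> 1-based plane
#'   index, e.g. `c(lipid_green = 1, norm_blue = 2)`.
#' @param pixel_size_um optional physical pixel size attached to each channel.
#' @return named list of [channel_image()]s, one per entry of `channel_map`.
#' @export
read_multichannel_tiff <- function(path, channel_map, pixel_size_um = NULL) {
  if (!file.exists(path))
    staz_error("staz_io_error", sprintf("file not found: %s", path))
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e)
                       staz_error("staz_format_error",
                                  sprintf("cannot read TIFF '%s': %s",
                                          path, conditionMessage(e))))
  if (!is.list(planes)) planes <- list(planes)
  roles <- names(channel_map)
  if (is.null(roles) || any(!nzchar(roles)))
    staz_error("staz_config_error", "channel_map must be named by role")
  out <- vector("list", length(channel_map))
  names(out) <- roles
  for (i in seq_along(channel_map)) {
    p <- as.integer(channel_map[[i]])
    if (is.na(p) || p < 1L || p > length(planes))
      staz_error("staz_config_error",
                 sprintf("plane %d requested but '%s' has %d plane(s)",
                         p, path, length(planes)))
    px <- planes[[p]]
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grayscale-as-RGB
    storage.mode(px) <- "double"
    out[[i]] <- channel_image(px, roles[i], pixel_size_um)
  }
  out
}

#' Read a liver mask from a mask image or an ImageJ ROI file
#'
#' Mask images (PNG or TIFF): any nonzero pixel counts as liver. ImageJ
#' `.roi` files (rectangle, oval, polygon, freehand or traced outlines) are
#' rasterized onto `dims` with the pixel-centre containment rule: pixel
#' (row r, col c), 0-based, is liver when its centre (c + 0.5, r + 0.5) in
#' ImageJ coordinates lies inside the ROI shape.
#'
#' @param path mask image (`.png`, `.tif`, `.tiff`) or ImageJ `.roi` file.
#' @param dims expected `c(rows, cols)` of the accompanying channels.
#' @return a [liver_mask()].
#' @export
read_mask <- function(path, dims) {
  if (!file.exists(path))
    staz_error("staz_io_error", sprintf("file not found: %s", path))
  dims <- as.integer(dims)
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") {
    roi <- read_imagej_roi(path)
    m <- rasterize_roi(roi, dims)
  } else {
    px <- tryCatch({
      if (ext == "png") png::readPNG(path)
      else tiff::readTIFF(path, as.is = TRUE)
    }, error = function(e)
      staz_error("staz_format_error",
                 sprintf("cannot read mask '%s': %s", path,
                         conditionMessage(e))))
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    if (!identical(dim(px), dims))
      staz_error("staz_shape_error",
                 sprintf("mask '%s' is %dx%d, expected %dx%d",
                         path, nrow(px), ncol(px), dims[1], dims[2]))
    m <- px != 0
  }
  if (!any(m))
    staz_error("staz_empty_roi_error",
               sprintf("mask '%s' selects no pixels", path))
  liver_mask(m)
}

# Minimal ImageJ .roi decoder: rectangle, oval and polygonal outlines.
# Layout (big-endian): "Iout", version(2), type(1)+pad(1),
# top/left/bottom/right as int16 at offsets 8..15, n_coordinates at 16,
# polygon vertices from offset 64 as int16 x-rel-to-left then y-rel-to-top.
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    staz_error("staz_format_error",
               sprintf("'%s' is not an ImageJ ROI file", path))
  i16 <- function(off)  # big-endian int16 at 0-based byte offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  type <- as.integer(raw[7])
  top <- i16(8); left <- i16(10); bottom <- i16(12); right <- i16(14)
  n <- i16(16)
  type_name <- switch(as.character(type),
                      "0" = "polygon", "1" = "rect", "2" = "oval",
                      "7" = "freehand", "8" = "traced", NULL)
  if (is.null(type_name))
    staz_error("staz_format_error",
               sprintf("unsupported ImageJ ROI type %d in '%s'", type, path))
  out <- list(type = type_name, top = top, left = left,
              bottom = bottom, right = right)
  if (type_name %in% c("polygon", "freehand", "traced")) {
    if (n < 3L || length(raw) < 64L + 4L * n)
      staz_error("staz_format_error",
                 sprintf("truncated polygon ROI '%s'", path))
    xs <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                  endian = "big")
    ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n, size = 2,
                  endian = "big")
    out$x <- left + xs
    out$y <- top + ys
  }
  out
}

# Rasterize a decoded ROI with the pixel-centre rule (0-based pixels).
rasterize_roi <- function(roi, dims) {
  rows <- dims[1]; cols <- dims[2]
  cx <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)  # centre x
  cy <- matrix(rep(seq_len(rows) - 0.5, times = cols), rows, cols) # centre y
  m <- switch(roi$type,
    rect = cx > roi$left & cx < roi$right & cy > roi$top & cy < roi$bottom,
    oval = {
      a <- (roi$right - roi$left) / 2
      b <- (roi$bottom - roi$top) / 2
      x0 <- (roi$left + roi$right) / 2
      y0 <- (roi$top + roi$bottom) / 2
      ((cx - x0) / a)^2 + ((cy - y0) / b)^2 <= 1
    },
    point_in_polygon(cx, cy, roi$x, roi$y))
  m
}

# even-odd ray-casting containment, vectorised over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- array(FALSE, dim = dim(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write a results table to CSV
#'
#' Numeric columns are written in plain decimal notation at full double
#' precision, so reading the file back reproduces the values to better than
#' 1e-12 relative error.
#'
#' @param rows a data.frame (may have zero rows; the header is still written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows))
    staz_error("staz_config_error", "rows must be a data.frame")
  ok <- tryCatch({
    utils::write.csv(format_full_precision(rows), path, row.names = FALSE,
                     quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    staz_error("staz_io_error",
               sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- "NA"
      df[[j]] <- v
    }
  }
  df
}

#' Read a results table written by [write_results_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path))
    staz_error("staz_io_error", sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a sample sheet
#'
#' The sample sheet is a CSV with one row per optical slice and columns
#' `larva_id, batch_id, treatment, concentration, slice_index, image_path,
#' mask_path` (plus optional `plane_a`/`plane_b` overriding the default TIFF
#' plane order 1/2). Relative paths are resolved against the sheet's
#' directory; every referenced file must exist.
#'
#' @param path CSV sample sheet.
#' @return data.frame with resolved absolute paths.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_results_table(path)
  need <- c("larva_id", "batch_id", "treatment", "concentration",
            "slice_index", "image_path", "mask_path")
  missing <- setdiff(need, names(sheet))
  if (length(missing))
    staz_error("staz_config_error",
               sprintf("sample sheet lacks column(s): %s",
                       paste(missing, collapse = ", ")))
  if (anyDuplicated(sheet[c("larva_id", "slice_index")]))
    staz_error("staz_config_error",
               "duplicate (larva_id, slice_index) rows in sample sheet")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  sheet$image_path <- resolve(sheet$image_path)
  sheet$mask_path <- resolve(sheet$mask_path)
  for (p in unique(c(sheet$image_path, sheet$mask_path)))
    if (!file.exists(p))
      staz_error("staz_io_error",
                 sprintf("sample sheet references missing file: %s", p))
  sheet
}

#' Load a cohort of larva records from a sample sheet
#'
#' @param sheet_path sample sheet CSV (see [read_sample_sheet()]).
#' @param kind `"nile_red"` loads plane A/B as `lipid_green`/`norm_blue`;
#'   `"gp"` loads them as `gp_ordered`/`gp_disordered`.
#' @return list of [larva_record()]s, in sheet order of first appearance.
#' @export
load_cohort <- function(sheet_path, kind = c("nile_red", "gp")) {
  kind <- match.arg(kind)
  roles <- if (kind == "nile_red") c("lipid_green", "norm_blue")
           else c("gp_ordered", "gp_disordered")
  sheet <- read_sample_sheet(sheet_path)
  ids <- unique(sheet$larva_id)
  lapply(ids, function(id) {
    rows <- sheet[sheet$larva_id == id, , drop = FALSE]
    slices <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      pa <- if ("plane_a" %in% names(r)) r$plane_a else 1L
      pb <- if ("plane_b" %in% names(r)) r$plane_b else 2L
      cm <- stats::setNames(c(pa, pb), roles)
      ch <- read_multichannel_tiff(r$image_path, cm)
      mk <- read_mask(r$mask_path, dim(ch[[1]]))
      slice_record(r$larva_id, r$slice_index, unname(ch), mk)
    })
    larva_record(rows$larva_id[1], rows$batch_id[1], rows$treatment[1],
                 rows$concentration[1], slices)
  })
}
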