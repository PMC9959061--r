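#' Segmentation settings for lipid-droplet detection
#'
#' The detection recipe is: median smoothing inside the liver mask, a
#' threshold (Otsu computed on in-mask pixels only, or a fixed value),
#' 8-connected components clipped to the mask, removal of components below
#' `min_area_px`, and an optional watershed split of touching blobs. All
#' knobs live here so a configuration is fully explicit; droplet counts and
#' areas are comparable only across runs sharing one configuration.
#'
#' @param smoothing_radius_px integer >= 0; radius of the median filter
#'   (0 disables smoothing). Default 1 suppresses single-pixel noise.
#' @param threshold_method `"otsu_in_mask"` (threshold from the intensity
#'   histogram of liver pixels only) or `"fixed"`.
#' @param fixed_threshold required when `threshold_method = "fixed"`; pixels
#'   strictly above it are droplet candidates.
#' @param min_area_px smallest component kept, in pixels. Default 4: smaller
#'   blobs are below the resolving power of the acquisition class and their
#'   apparent size is unreliable.
#' @param split_touching if `TRUE`, a distance-transform watershed separates
#'   touching droplets.
#' @param min_contrast_sd robust background guard for the Otsu threshold:
#'   the threshold is never taken below
#'   `median + min_contrast_sd * MAD` of the in-mask intensities. Otsu's
#'   criterion always splits a histogram, even a droplet-free one where the
#'   split would land inside the noise; the guard keeps near-background
#'   pixels out of the foreground. Set to 0 to disable.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(smoothing_radius_px = 1L,
                                threshold_method = c("otsu_in_mask", "fixed"),
                                fixed_threshold = NULL,
                                min_area_px = 4L,
                                split_touching = FALSE,
                                min_contrast_sd = 3) {
  threshold_method <- match.arg(threshold_method)
  smoothing_radius_px <- as.integer(smoothing_radius_px)
  min_area_px <- as.integer(min_area_px)
  stopifnot(smoothing_radius_px >= 0L, min_area_px >= 1L,
            is.logical(split_touching), min_contrast_sd >= 0)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold))
      staz_error("staz_config_error",
                 "fixed_threshold is required when threshold_method = 'fixed'")
  } else if (!is.null(fixed_threshold)) {
    staz_error("staz_config_error",
               "fixed_threshold only applies to threshold_method = 'fixed'")
  }
  structure(list(smoothing_radius_px = smoothing_radius_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = min_area_px,
                 split_touching = isTRUE(split_touching),
                 min_contrast_sd = min_contrast_sd),
            class = "segmentation_config")
}

# Median smoothing with edge replication. Radius 1 (the default) uses a
# vectorised median-of-9 selection network; larger radii fall back to
# EBImage's constant-time median filter.
median_smooth <- function(px, radius) {
  if (radius == 0L) return(px)
  if (radius > 1L) {
    top <- max(px)
    if (top == 0) return(px)
    return(EBImage::medianFilter(px / top, radius) * top)
  }
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- px
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  s <- vector("list", 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    s[[k]] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  # 19-comparator median-of-9 network (result in element 5)
  net <- matrix(c(2,3, 5,6, 8,9, 1,2, 4,5, 7,8, 2,3, 5,6, 8,9,
                  1,4, 6,9, 5,8, 4,7, 2,5, 3,6, 5,8, 5,3, 7,5, 5,3),
                nrow = 2)
  for (j in seq_len(ncol(net))) {
    a <- net[1, j]; b <- net[2, j]
    lo <- pmin(s[[a]], s[[b]])
    s[[b]] <- pmax(s[[a]], s[[b]])
    s[[a]] <- lo
  }
  s[[5]]
}

# Otsu threshold from a vector of intensities (256-bin histogram over the
# observed range). Returns NA when the histogram cannot be split.
otsu_threshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  rng[1] + k / nbins * diff(rng)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bin), ncol(bin))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(nl), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

#' Detect lipid droplets in the green channel within the liver mask
#'
#' Deterministic for fixed inputs. When the in-mask intensity is constant no
#' threshold exists; zero droplets are returned with a
#' `staz_flat_intensity_warning`. The threshold actually applied (on the
#' smoothed image) is attached to the result as attribute `"threshold"`.
#'
#' @param green a `lipid_green` [channel_image()].
#' @param mask a [liver_mask()] of the same dimensions.
#' @param cfg a [segmentation_config()].
#' @return list of droplets; each has `pixel_set` (2-column matrix of 1-based
#'   row/col indices), `area_px`, `centroid` (row, col) and
#'   `equiv_diameter_px` (diameter of the circle of equal area).
#' @export
segment_droplets <- function(green, mask, cfg = segmentation_config()) {
  stopifnot(inherits(green, "channel_image"), inherits(mask, "liver_mask"))
  if (green$role != "lipid_green")
    staz_error("staz_config_error", "segment_droplets needs a lipid_green channel")
  if (!identical(dim(green), dim(mask)))
    staz_error("staz_shape_error", "green channel and mask dimensions differ")
  px <- median_smooth(green$pixels, cfg$smoothing_radius_px)
  m <- mask$mask
  inmask <- px[m]
  if (cfg$threshold_method == "otsu_in_mask") {
    thr <- otsu_threshold(inmask)
    if (is.na(thr)) {
      staz_warn("staz_flat_intensity_warning",
                "constant in-mask intensity: threshold undefined, no droplets")
      return(structure(list(), threshold = NA_real_))
    }
    if (cfg$min_contrast_sd > 0) {
      guard <- stats::median(inmask) +
        cfg$min_contrast_sd * stats::mad(inmask)
      thr <- max(thr, guard)
    }
  } else {
    thr <- cfg$fixed_threshold
  }
  bin <- (px > thr) & m
  if (!any(bin)) return(structure(list(), threshold = thr))
  lab <- label8(bin)
  if (cfg$split_touching) lab <- watershed_split(lab, bin)
  structure(build_droplets(lab, cfg$min_area_px), threshold = thr)
}

# distance-transform watershed on the foreground, preserving labels
watershed_split <- function(lab, bin) {
  dmap <- EBImage::distmap(bin)
  ws <- EBImage::watershed(dmap)
  ws <- matrix(as.integer(EBImage::imageData(ws)), nrow(bin), ncol(bin))
  ws[!bin] <- 0L
  # renumber combined (component, basin) pairs into consecutive labels
  key <- ifelse(ws > 0L, lab * (max(ws) + 1L) + ws, 0L)
  u <- sort(unique(key[key > 0L]))
  key[key > 0L] <- match(key[key > 0L], u)
  key
}

build_droplets <- function(lab, min_area_px) {
  nl <- max(lab)
  if (nl == 0L) return(list())
  out <- vector("list", nl)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  keep <- 0L
  for (l in seq_len(nl)) {
    pts <- idx[labs == l, , drop = FALSE]
    a <- nrow(pts)
    if (a < min_area_px) next
    keep <- keep + 1L
    out[[keep]] <- list(pixel_set = unname(pts),
                        area_px = a,
                        centroid = c(mean(pts[, 1]), mean(pts[, 2])),
                        equiv_diameter_px = 2 * sqrt(a / pi))
  }
  out[seq_len(keep)]
}

#' Droplet density and area fraction for one slice
#'
#' `ld_dens` is droplets per liver pixel (count / liver area); `ld_area` is
#' the dimensionless fraction of liver area covered by droplet pixels. When
#' a physical pixel size is known, density per square micrometre is
#' `ld_dens / pixel_size_um^2` — reported separately, never folded into the
#' score.
#'
#' @param droplets output of [segment_droplets()].
#' @param mask the [liver_mask()] the droplets were detected in.
#' @return list of class `droplet_quant` with fields `droplets`,
#'   `n_droplets`, `droplet_area_px`, `liver_area_px`, `ld_dens`, `ld_area`.
#' @export
quantify_droplets <- function(droplets, mask) {
  stopifnot(inherits(mask, "liver_mask"))
  for (d in droplets) {
    inm <- mask$mask[d$pixel_set]
    if (!all(inm))
      staz_error("staz_consistency_error",
                 "droplet contains pixels outside the liver mask")
  }
  n <- length(droplets)
  darea <- if (n) sum(vapply(droplets, `[[`, numeric(1), "area_px")) else 0L
  structure(list(droplets = droplets,
                 n_droplets = as.integer(n),
                 droplet_area_px = as.integer(darea),
                 liver_area_px = mask$area_px,
                 ld_dens = n / mask$area_px,
                 ld_area = darea / mask$area_px),
            class = "droplet_quant")
}

#' Per-droplet table for one slice
#'
#' @param droplets output of [segment_droplets()].
#' @param larva_id,slice_index identifiers copied into every row.
#' @return data.frame with one row per droplet: id, area, centroid,
#'   equivalent diameter.
#' @export
droplet_table <- function(droplets, larva_id = NA_character_,
                          slice_index = NA_integer_) {
  data.frame(
    larva_id = rep(larva_id, length(droplets)),
    slice_index = rep(as.integer(slice_index), length(droplets)),
    droplet_id = seq_along(droplets),
    area_px = vapply(droplets, `[[`, numeric(1), "area_px"),
    centroid_row = vapply(droplets, function(d) d$centroid[1], numeric(1)),
    centroid_col = vapply(droplets, function(d) d$centroid[2], numeric(1)),
    equiv_diameter_px = vapply(droplets, `[[`, numeric(1),
                               "equiv_diameter_px"))
}
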