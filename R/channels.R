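#' Single-channel fluorescence image
#'
#' Wraps one 2-D plane of non-negative intensities together with its role in
#' the assay. Roles: `lipid_green` (neutral-lipid emission), `norm_blue`
#' (normalization channel: autofluorescence or liver-restricted blue
#' fluorophore), `gp_ordered` / `gp_disordered` (ordered- and
#' disordered-phase emission windows for generalized-polarization mapping).
#'
#' @param pixels numeric matrix of intensities, all `>= 0`.
#' @param role one of `"lipid_green"`, `"norm_blue"`, `"gp_ordered"`,
#'   `"gp_disordered"`.
#' @param pixel_size_um optional positive physical pixel size in micrometres.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, role, pixel_size_um = NULL) {
  roles <- c("lipid_green", "norm_blue", "gp_ordered", "gp_disordered")
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    staz_error("staz_format_error", "pixels must be a non-empty numeric matrix")
  if (anyNA(pixels) || any(pixels < 0))
    staz_error("staz_format_error", "pixel intensities must be finite and >= 0")
  role <- match.arg(role, roles)
  if (!is.null(pixel_size_um)) {
    stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
              pixel_size_um > 0)
  }
  structure(list(pixels = pixels, role = role, pixel_size_um = pixel_size_um),
            class = "channel_image")
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, range [%g, %g]\n",
              x$role, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary liver region-of-interest mask
#'
#' @param mask logical (or 0/1 numeric) matrix; `TRUE`/nonzero marks liver.
#' @return object of class `liver_mask` with fields `mask` (logical matrix)
#'   and `area_px` (number of liver pixels).
#' @export
liver_mask <- function(mask) {
  if (!is.matrix(mask) || length(mask) == 0L)
    staz_error("staz_format_error", "mask must be a non-empty matrix")
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask) || anyNA(mask))
    staz_error("staz_format_error", "mask must be logical or numeric, no NA")
  area <- sum(mask)
  if (area < 1L)
    staz_error("staz_empty_roi_error", "liver mask contains no pixels")
  structure(list(mask = mask, area_px = as.integer(area)),
            class = "liver_mask")
}

#' @export
dim.liver_mask <- function(x) dim(x$mask)

#' One optical slice of one larva
#'
#' Bundles the channel pair of a slice with its liver mask. The pair must be
#' either `lipid_green` + `norm_blue` (steatosis workflow) or `gp_ordered` +
#' `gp_disordered` (membrane-order workflow), and all grids must share
#' dimensions.
#'
#' @param larva_id identifier string.
#' @param slice_index integer 1..3.
#' @param channels list of two `channel_image`s.
#' @param mask a `liver_mask`.
#' @return object of class `slice_record`.
#' @export
slice_record <- function(larva_id, slice_index, channels, mask) {
  stopifnot(length(larva_id) == 1L, length(slice_index) == 1L)
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 1L || slice_index > 3L)
    staz_error("staz_config_error", "slice_index must be in 1..3")
  if (!is.list(channels) || length(channels) != 2L ||
      !all(vapply(channels, inherits, logical(1), "channel_image")))
    staz_error("staz_config_error", "channels must be a list of two channel_images")
  roles <- sort(vapply(channels, `[[`, character(1), "role"))
  ok <- identical(roles, sort(c("lipid_green", "norm_blue"))) ||
        identical(roles, sort(c("gp_ordered", "gp_disordered")))
  if (!ok)
    staz_error("staz_config_error",
               "channel roles must pair lipid_green+norm_blue or gp_ordered+gp_disordered")
  if (!inherits(mask, "liver_mask"))
    staz_error("staz_config_error", "mask must be a liver_mask")
  dims <- lapply(c(channels, list(mask)), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    staz_error("staz_shape_error", "channel and mask dimensions differ")
  names(channels) <- vapply(channels, `[[`, character(1), "role")
  structure(list(larva_id = as.character(larva_id),
                 slice_index = slice_index,
                 channels = channels, mask = mask),
            class = "slice_record")
}

# pull a channel of a given role out of a slice_record
slice_channel <- function(slice, role) {
  ch <- slice$channels[[role]]
  if (is.null(ch))
    staz_error("staz_config_error",
               sprintf("slice has no channel with role '%s'", role))
  ch
}

#' One larva: identity, grouping and its optical slices
#'
#' @param larva_id,batch_id,treatment identifier strings.
#' @param concentration optional numeric exposure concentration (the unit is
#'   carried as the `conc_unit` attribute of the cohort table, not here).
#' @param slices list of 1..3 `slice_record`s with distinct slice indices.
#' @return object of class `larva_record`.
#' @export
larva_record <- function(larva_id, batch_id, treatment,
                         concentration = NA_real_, slices) {
  if (!is.list(slices) || length(slices) < 1L || length(slices) > 3L ||
      !all(vapply(slices, inherits, logical(1), "slice_record")))
    staz_error("staz_config_error", "slices must be a list of 1..3 slice_records")
  idx <- vapply(slices, `[[`, integer(1), "slice_index")
  if (anyDuplicated(idx))
    staz_error("staz_config_error", "slice indices must be unique within a larva")
  structure(list(larva_id = as.character(larva_id),
                 batch_id = as.character(batch_id),
                 treatment = as.character(treatment),
                 concentration = as.numeric(concentration),
                 slices = slices[order(idx)]),
            class = "larva_record")
}
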