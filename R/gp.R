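#' Per-pixel generalized polarization (GP) map
#'
#' For each liver pixel with total intensity at or above `intensity_floor`,
#' GP = (I_ordered - I_disordered) / (I_ordered + I_disordered), a
#' ratiometric membrane-order statistic in `[-1, 1]` (higher = more ordered,
#' i.e. more rigid membranes). Dim pixels, where the ratio is noise-
#' dominated, and pixels outside the liver mask are flagged undefined.
#'
#' @param ordered,disordered `gp_ordered` and `gp_disordered`
#'   [channel_image()]s (ordered-phase and disordered-phase emission windows).
#' @param mask the [liver_mask()].
#' @param intensity_floor minimum `I_ord + I_dis` for a pixel to be defined;
#'   `NULL` selects the default of 2% of the 99th percentile of the in-mask
#'   total intensity (a background guard, configurable).
#' @return object of class `gp_map`: `gp` (matrix, `NA` where undefined),
#'   `valid_mask` (logical matrix), `intensity_floor` (the value used).
#' @export
gp_map <- function(ordered, disordered, mask, intensity_floor = NULL) {
  stopifnot(inherits(ordered, "channel_image"),
            inherits(disordered, "channel_image"),
            inherits(mask, "liver_mask"))
  if (ordered$role != "gp_ordered" || disordered$role != "gp_disordered")
    staz_error("staz_config_error",
               "gp_map needs gp_ordered and gp_disordered channels")
  if (!identical(dim(ordered), dim(disordered)) ||
      !identical(dim(ordered), dim(mask)))
    staz_error("staz_shape_error", "channel/mask dimensions differ")
  tot <- ordered$pixels + disordered$pixels
  if (is.null(intensity_floor))
    intensity_floor <- 0.02 * stats::quantile(tot[mask$mask], 0.99,
                                              names = FALSE)
  if (!is.finite(intensity_floor) || intensity_floor < 0)
    staz_error("staz_config_error", "intensity_floor must be >= 0")
  valid <- mask$mask & tot >= intensity_floor & tot > 0
  if (!any(valid))
    staz_error("staz_empty_gp_error",
               "no defined GP pixels (all below intensity floor or outside mask)")
  gp <- matrix(NA_real_, nrow(tot), ncol(tot))
  gp[valid] <- (ordered$pixels[valid] - disordered$pixels[valid]) / tot[valid]
  structure(list(gp = gp, valid_mask = valid,
                 intensity_floor = intensity_floor),
            class = "gp_map")
}

#' Per-larva GP value
#'
#' Unweighted mean of the defined GP pixels of a map (intensity weighting is
#' deliberately not applied).
#'
#' @param gpmap a [gp_map()].
#' @return scalar mean GP.
#' @export
larva_gp <- function(gpmap) {
  stopifnot(inherits(gpmap, "gp_map"))
  mean(gpmap$gp[gpmap$valid_mask])
}

#' Control-anchored delta-GP per larva
#'
#' To absorb batch-to-batch and staining-to-staining variation, each larva's
#' mean GP is expressed relative to the mean GP of the control larvae of the
#' same batch: `delta_gp = mean_gp - mean(control mean_gp of the batch)`.
#' Within every batch the control group's delta-GP averages zero by
#' construction.
#'
#' @param results data.frame with columns `larva_id, batch_id, treatment,
#'   mean_gp` (one row per larva).
#' @param control_label treatment label of the control group.
#' @return the input with a `delta_gp` column appended.
#' @export
delta_gp <- function(results, control_label = "DMSO") {
  need <- c("larva_id", "batch_id", "treatment", "mean_gp")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    staz_error("staz_config_error",
               sprintf("results must have columns: %s",
                       paste(need, collapse = ", ")))
  out <- results
  out$delta_gp <- NA_real_
  for (b in unique(results$batch_id)) {
    in_b <- results$batch_id == b
    ctl <- results$mean_gp[in_b & results$treatment == control_label]
    if (length(ctl) == 0L)
      staz_error("staz_missing_control_error",
                 sprintf("no '%s' control larvae in batch '%s'",
                         control_label, b))
    out$delta_gp[in_b] <- results$mean_gp[in_b] - mean(ctl)
  }
  out
}

#' GP results for a cohort of larvae
#'
#' Computes the GP map and per-larva mean GP for every larva (slices are
#' averaged with equal weight), then anchors to batch controls.
#'
#' @param larvae list of [larva_record()]s holding `gp_ordered` /
#'   `gp_disordered` channel pairs.
#' @param control_label control treatment label.
#' @param intensity_floor passed to [gp_map()] (`NULL` = automatic).
#' @return data.frame: `larva_id, batch_id, treatment, n_defined_px,
#'   mean_gp, delta_gp`.
#' @export
gp_cohort <- function(larvae, control_label = "DMSO",
                      intensity_floor = NULL) {
  stopifnot(length(larvae) >= 1L,
            all(vapply(larvae, inherits, logical(1), "larva_record")))
  per <- do.call(rbind, lapply(larvae, function(lv) {
    vals <- vapply(lv$slices, function(sl) {
      g <- gp_map(slice_channel(sl, "gp_ordered"),
                  slice_channel(sl, "gp_disordered"),
                  sl$mask, intensity_floor)
      c(larva_gp(g), sum(g$valid_mask))
    }, numeric(2))
    data.frame(larva_id = lv$larva_id, batch_id = lv$batch_id,
               treatment = lv$treatment,
               n_defined_px = as.integer(sum(vals[2, ])),
               mean_gp = mean(vals[1, ]))
  }))
  delta_gp(per, control_label)
}
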