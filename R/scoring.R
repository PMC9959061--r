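#' Steatosis score coefficients
#'
#' Weights of the linear combination of the three per-slice parameters. The
#' defaults (400, 10000, 100) are the published values, set so that the
#' corrected ratio, droplet density (per liver pixel) and droplet area
#' fraction contribute with homogeneous weight to the composite score.
#'
#' @param w_ratio weight of the corrected fluorescence ratio.
#' @param w_dens weight of the droplet density (droplets per liver pixel).
#' @param w_area weight of the droplet area fraction.
#' @return object of class `score_coefficients`.
#' @export
score_coefficients <- function(w_ratio = 400, w_dens = 10000, w_area = 100) {
  stopifnot(is.finite(w_ratio), is.finite(w_dens), is.finite(w_area))
  structure(list(w_ratio = w_ratio, w_dens = w_dens, w_area = w_area),
            class = "score_coefficients")
}

#' Raw green/blue fluorescence ratio over the liver
#'
#' Total green intensity over liver pixels divided by total blue intensity
#' over the same pixels. Because both sums run over one shared mask this
#' equals the ratio of in-mask mean intensities.
#'
#' @param green,blue `lipid_green` and `norm_blue` [channel_image()]s.
#' @param mask the [liver_mask()].
#' @return positive scalar.
#' @export
raw_ratio <- function(green, blue, mask) {
  stopifnot(inherits(green, "channel_image"), inherits(blue, "channel_image"),
            inherits(mask, "liver_mask"))
  if (green$role != "lipid_green" || blue$role != "norm_blue")
    staz_error("staz_config_error",
               "raw_ratio needs a lipid_green and a norm_blue channel")
  if (!identical(dim(green), dim(blue)) || !identical(dim(green), dim(mask)))
    staz_error("staz_shape_error", "channel/mask dimensions differ")
  fb <- sum(blue$pixels[mask$mask])
  if (fb <= 0)
    staz_error("staz_degenerate_normalization_error",
               "blue channel sums to zero over the liver mask")
  sum(green$pixels[mask$mask]) / fb
}

#' Control-corrected fluorescence ratio
#'
#' Relative deviation of a raw ratio from the mean raw ratio of the vehicle
#' (DMSO) control group: `(raw - control_mean) / control_mean`. Zero means
#' "at control level"; negative values (raw below control) are legitimate
#' and are not clamped.
#'
#' @param raw raw green/blue ratio of one slice or larva.
#' @param control_mean mean raw ratio of the control larvae of the same
#'   normalization unit (batch, or the whole cohort).
#' @return scalar.
#' @export
corrected_ratio <- function(raw, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    staz_error("staz_degenerate_control_error",
               "control mean ratio must be positive and finite")
  (raw - control_mean) / control_mean
}

#' Composite steatosis score of one optical slice
#'
#' The published linear combination
#' `w_ratio * corrected_ratio + w_dens * ld_dens + w_area * ld_area`.
#'
#' @param corrected_ratio control-corrected fluorescence ratio.
#' @param ld_dens droplet density, droplets per liver pixel.
#' @param ld_area droplet area fraction of the liver, in `[0, 1]`.
#' @param coeffs a [score_coefficients()].
#' @return scalar score.
#' @export
slice_score <- function(corrected_ratio, ld_dens, ld_area,
                        coeffs = score_coefficients()) {
  stopifnot(inherits(coeffs, "score_coefficients"))
  if (!all(is.finite(c(corrected_ratio, ld_dens, ld_area))))
    staz_error("staz_config_error", "slice_score inputs must be finite")
  coeffs$w_ratio * corrected_ratio + coeffs$w_dens * ld_dens +
    coeffs$w_area * ld_area
}

#' Larva-level score: mean over its slice scores
#'
#' The assay images three optical slices per larva; the larva score is the
#' arithmetic mean of the slice scores. Fewer than three slices is accepted
#' with a warning (the score is then a shallower average).
#'
#' @param slice_scores numeric vector of 1..3 slice scores.
#' @return scalar mean score.
#' @export
larva_score <- function(slice_scores) {
  if (length(slice_scores) == 0L)
    staz_error("staz_missing_data_error", "larva has no slice scores")
  if (length(slice_scores) > 3L)
    staz_error("staz_config_error", "more than 3 slice scores supplied")
  if (length(slice_scores) < 3L)
    staz_warn("staz_short_slice_warning",
              sprintf("larva scored from %d slice(s) instead of 3",
                      length(slice_scores)))
  mean(slice_scores)
}

#' Score a cohort of larvae against its vehicle controls
#'
#' Runs the full per-slice quantification (fluorescence ratio + droplet
#' segmentation) for every larva, computes the control mean raw ratio per
#' normalization unit from control larvae only, corrects every slice against
#' its unit's control mean, and assembles slice and larva scores. Control
#' larvae are scored too; within each unit their corrected ratios average
#' zero by construction.
#'
#' @param larvae list of [larva_record()]s.
#' @param control_label treatment label of the vehicle control group
#'   (default `"DMSO"`).
#' @param scope `"per_batch"` computes a control mean per batch (matching
#'   the assay's per-experiment anchoring); `"global"` pools all controls.
#' @param coeffs a [score_coefficients()].
#' @param seg a [segmentation_config()].
#' @return data.frame of class `larva_scores`, one row per larva:
#'   `larva_id, batch_id, treatment, concentration, n_slices,
#'   raw_ratio_mean, corrected_ratio_mean, ld_dens_mean, ld_area_mean,
#'   score`. The per-slice table is attached as attribute `"slices"`.
#' @export
score_cohort <- function(larvae, control_label = "DMSO",
                         scope = c("per_batch", "global"),
                         coeffs = score_coefficients(),
                         seg = segmentation_config()) {
  scope <- match.arg(scope)
  stopifnot(length(larvae) >= 1L,
            all(vapply(larvae, inherits, logical(1), "larva_record")))

  # per-slice raw measurements first (independent of control anchoring)
  slices <- do.call(rbind, lapply(larvae, function(lv) {
    do.call(rbind, lapply(lv$slices, function(sl) {
      g <- slice_channel(sl, "lipid_green")
      b <- slice_channel(sl, "norm_blue")
      dq <- quantify_droplets(segment_droplets(g, sl$mask, seg), sl$mask)
      data.frame(larva_id = lv$larva_id, batch_id = lv$batch_id,
                 treatment = lv$treatment, concentration = lv$concentration,
                 slice_index = sl$slice_index,
                 raw_ratio = raw_ratio(g, b, sl$mask),
                 ld_dens = dq$ld_dens, ld_area = dq$ld_area)
    }))
  }))

  unit <- if (scope == "per_batch") slices$batch_id
          else rep("__all__", nrow(slices))
  slices$unit <- unit

  # control mean raw ratio per unit, from control larvae's per-larva means
  larva_raw <- stats::aggregate(raw_ratio ~ larva_id + unit + treatment,
                                slices, mean)
  ctrl_means <- c()
  for (u in unique(larva_raw$unit)) {
    ctl <- larva_raw[larva_raw$unit == u &
                     larva_raw$treatment == control_label, "raw_ratio"]
    if (length(ctl) == 0L)
      staz_error("staz_missing_control_error",
                 sprintf("no '%s' control larvae in batch '%s'",
                         control_label,
                         if (u == "__all__") "(global)" else u))
    ctrl_means[u] <- mean(ctl)
  }

  slices$corrected_ratio <- mapply(corrected_ratio, slices$raw_ratio,
                                   ctrl_means[slices$unit])
  slices$score <- slice_score(slices$corrected_ratio, slices$ld_dens,
                              slices$ld_area, coeffs)

  per_larva <- do.call(rbind, lapply(larvae, function(lv) {
    s <- slices[slices$larva_id == lv$larva_id, , drop = FALSE]
    sc <- withCallingHandlers(
      larva_score(s$score),
      staz_short_slice_warning = function(w) invokeRestart("muffleWarning"))
    data.frame(larva_id = lv$larva_id, batch_id = lv$batch_id,
               treatment = lv$treatment, concentration = lv$concentration,
               n_slices = nrow(s),
               raw_ratio_mean = mean(s$raw_ratio),
               corrected_ratio_mean = mean(s$corrected_ratio),
               ld_dens_mean = mean(s$ld_dens),
               ld_area_mean = mean(s$ld_area),
               score = sc)
  }))
  rownames(per_larva) <- NULL
  slices$unit <- NULL
  attr(per_larva, "slices") <- slices
  attr(per_larva, "control_label") <- control_label
  attr(per_larva, "scope") <- scope
  class(per_larva) <- c("larva_scores", "data.frame")
  per_larva
}
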