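#' Parameters of the synthetic larva image generator
#'
#' The generator emulates the assay's imaging geometry: an elliptical liver
#' emitting a blue normalization signal (weak autofluorescence on an
#' ambient background in `"wildtype"` mode; a strong liver-restricted signal
#' in `"transgenic"` mode), bright green lipid droplets of controllable
#' density and size placed inside the liver without overlap, a diffuse green
#' background, Gaussian point-spread blur, and Poisson shot noise plus
#' Gaussian read noise. Intensities are in arbitrary camera counts.
#'
#' @param image_size `c(rows, cols)`.
#' @param liver_center,liver_axes,liver_rotation ellipse centre (row, col,
#'   0-based), semi-axes in pixels, rotation in radians.
#' @param mode `"wildtype"` or `"transgenic"`; sets the default blue levels.
#' @param blue_liver_level,blue_background_level blue counts inside /
#'   outside the liver. Transgenic mode requires liver > background.
#' @param green_background_level diffuse green counts everywhere.
#' @param droplet_rate expected droplets per liver pixel.
#' @param droplet_radius_px `c(mean, sd)` of droplet radii (truncated at 1).
#' @param droplet_intensity green counts added inside each droplet.
#' @param psf_sigma_px Gaussian blur sigma (0 disables).
#' @param noise_gaussian_sd additive Gaussian noise SD in counts.
#' @param noise_poisson apply Poisson shot noise to the expected counts.
#' @param min_separation_px extra clearance required between droplet rims,
#'   keeping ground-truth counts unambiguous after blurring.
#' @param shared_mask reuse one liver outline for all three optical slices
#'   of a larva (the default; per-slice outlines arise when callers vary the
#'   ellipse between calls).
#' @param seed integer seed; the same seed reproduces images bit-for-bit.
#' @return object of class `larva_sim_params`.
#' @export
larva_sim_params <- function(image_size = c(96L, 96L),
                             liver_center = c(48, 48),
                             liver_axes = c(30, 20),
                             liver_rotation = 0.4,
                             mode = c("wildtype", "transgenic"),
                             blue_liver_level = NULL,
                             blue_background_level = NULL,
                             green_background_level = 20,
                             droplet_rate = 1.5e-3,
                             droplet_radius_px = c(2.2, 0.3),
                             droplet_intensity = 160,
                             psf_sigma_px = 0.8,
                             noise_gaussian_sd = 4,
                             noise_poisson = TRUE,
                             min_separation_px = 3,
                             shared_mask = TRUE,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(blue_liver_level))
    blue_liver_level <- if (mode == "wildtype") 45 else 130
  if (is.null(blue_background_level))
    blue_background_level <- if (mode == "wildtype") 35 else 8
  p <- list(image_size = as.integer(image_size),
            liver_center = liver_center, liver_axes = liver_axes,
            liver_rotation = liver_rotation, mode = mode,
            blue_liver_level = blue_liver_level,
            blue_background_level = blue_background_level,
            green_background_level = green_background_level,
            droplet_rate = droplet_rate,
            droplet_radius_px = droplet_radius_px,
            droplet_intensity = droplet_intensity,
            psf_sigma_px = psf_sigma_px,
            noise_gaussian_sd = noise_gaussian_sd,
            noise_poisson = isTRUE(noise_poisson),
            min_separation_px = min_separation_px,
            shared_mask = isTRUE(shared_mask),
            seed = as.integer(seed))
  lv <- c(p$blue_liver_level, p$blue_background_level,
          p$green_background_level, p$droplet_rate, p$droplet_intensity)
  if (any(lv < 0) || p$psf_sigma_px < 0 || p$noise_gaussian_sd < 0)
    staz_error("staz_config_error", "rates and levels must be >= 0")
  half <- max(p$liver_axes)
  if (p$liver_center[1] - half < 0 || p$liver_center[2] - half < 0 ||
      p$liver_center[1] + half > p$image_size[1] ||
      p$liver_center[2] + half > p$image_size[2])
    staz_error("staz_config_error", "liver ellipse must fit inside the image")
  if (mode == "transgenic" && blue_liver_level <= blue_background_level)
    staz_error("staz_config_error",
               "transgenic mode requires blue_liver_level > blue_background_level")
  structure(p, class = "larva_sim_params")
}

# pixel-centre rasterization of the liver ellipse (0-based geometry)
liver_ellipse_mask <- function(p) {
  nr <- p$image_size[1]; nc <- p$image_size[2]
  cy <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  cx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  dy <- cy - p$liver_center[1]; dx <- cx - p$liver_center[2]
  u <- dy * cos(p$liver_rotation) + dx * sin(p$liver_rotation)
  v <- -dy * sin(p$liver_rotation) + dx * cos(p$liver_rotation)
  (u / p$liver_axes[1])^2 + (v / p$liver_axes[2])^2 <= 1
}

gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  size <- 2L * ceiling(3 * sigma) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(px, brush, boundary = "replicate"))
}

# place n non-overlapping droplets fully inside the mask by rejection
place_droplets <- function(n, mask, p) {
  liver_idx <- which(mask, arr.ind = TRUE)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      r <- max(1, stats::rnorm(1, p$droplet_radius_px[1],
                               p$droplet_radius_px[2]))
      ctr <- liver_idx[sample.int(nrow(liver_idx), 1L), ] - 0.5
      # disk fully inside the liver: probe the rim at 8 angles + centre
      ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
      pr <- round(ctr[1] + r * sin(ang) + 0.5)
      pc <- round(ctr[2] + r * cos(ang) + 0.5)
      if (any(pr < 1 | pc < 1 | pr > nrow(mask) | pc > ncol(mask))) next
      if (!all(mask[cbind(pr, pc)])) next
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
        if (any(d < radii + r + p$min_separation_px)) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
      placed <- TRUE
      break
    }
    if (!placed)
      staz_error("staz_packing_error",
                 sprintf("could not place droplet %d of %d after 1000 tries; lower droplet_rate or radius", k, n))
  }
  list(centers = centers, radii = radii)
}

render_disks <- function(dims, centers, radii, grid = pixel_grid(dims)) {
  img <- matrix(0, dims[1], dims[2])
  if (!nrow(centers)) return(img)
  for (k in seq_len(nrow(centers))) {
    img <- img + ((grid$cy - centers[k, 1])^2 +
                    (grid$cx - centers[k, 2])^2 <= radii[k]^2)
  }
  img
}

pixel_grid <- function(dims) {
  list(cy = matrix(rep(seq_len(dims[1]) - 0.5, times = dims[2]),
                   dims[1], dims[2]),
       cx = matrix(rep(seq_len(dims[2]) - 0.5, each = dims[1]),
                   dims[1], dims[2]))
}

apply_noise <- function(expected, p) {
  px <- expected
  if (p$noise_poisson)
    px <- matrix(stats::rpois(length(px), pmax(px, 0)), nrow(px), ncol(px))
  if (p$noise_gaussian_sd > 0)
    px <- px + stats::rnorm(length(px), 0, p$noise_gaussian_sd)
  pmax(px, 0)
}

#' Simulate one larva: three optical slices with ground truth
#'
#' Droplet counts per slice are Poisson with mean `droplet_rate * liver
#' area`; droplets are disks placed without overlap (rejection sampling, at
#' most 1000 retries each) fully inside the liver. The same seed reproduces
#' the output bit for bit.
#'
#' @param params a [larva_sim_params()].
#' @param larva_id,batch_id,treatment,concentration identifiers for the
#'   returned [larva_record()].
#' @param intensity_factor multiplicative factor on all emission levels
#'   (used to emulate batch-to-batch intensity variation).
#' @return list with `record` (a [larva_record()]) and `truth`: the liver
#'   mask, per-slice droplet centres/radii, per-slice `n_droplets`,
#'   `ld_dens`, `ld_area` and the noise-free expected `raw_ratio`.
#' @export
simulate_larva <- function(params = larva_sim_params(), larva_id = "larva1",
                           batch_id = "batch1", treatment = "DMSO",
                           concentration = NA_real_,
                           intensity_factor = 1) {
  stopifnot(inherits(params, "larva_sim_params"), intensity_factor > 0)
  with_seed(params$seed, {
    mask <- liver_ellipse_mask(params)
    lmask <- liver_mask(mask)
    area <- lmask$area_px
    grid <- pixel_grid(params$image_size)
    blue_expected <- gaussian_blur(
      intensity_factor * (params$blue_background_level +
                            (params$blue_liver_level -
                               params$blue_background_level) * mask),
      params$psf_sigma_px)
    slices <- vector("list", 3L)
    truth_rows <- vector("list", 3L)
    droplet_truth <- vector("list", 3L)
    for (s in 1:3) {
      n <- stats::rpois(1L, params$droplet_rate * area)
      dd <- place_droplets(n, mask, params)
      disks <- render_disks(params$image_size, dd$centers, dd$radii, grid)
      droplet_px <- sum(disks > 0 & mask)
      green_expected <- gaussian_blur(
        intensity_factor * (params$green_background_level +
                              params$droplet_intensity * disks),
        params$psf_sigma_px)
      green <- apply_noise(green_expected, params)
      blue <- apply_noise(blue_expected, params)
      slices[[s]] <- slice_record(
        larva_id, s,
        list(channel_image(green, "lipid_green"),
             channel_image(blue, "norm_blue")),
        lmask)
      truth_rows[[s]] <- data.frame(
        slice_index = s, n_droplets = n,
        ld_dens = n / area, ld_area = droplet_px / area,
        raw_ratio = sum(green_expected[mask]) / sum(blue_expected[mask]))
      droplet_truth[[s]] <- list(centers = dd$centers, radii = dd$radii)
    }
    rec <- larva_record(larva_id, batch_id, treatment, concentration, slices)
    list(record = rec,
         truth = list(mask = lmask,
                      slices = do.call(rbind, truth_rows),
                      droplets = droplet_truth))
  })
}

#' Simulate an ordered/disordered channel pair from a known GP field
#'
#' Inverts the GP formula: for total intensity `T` and true field `G`,
#' `I_ord = T (1 + G) / 2` and `I_dis = T (1 - G) / 2`, so that in the
#' noise-free case the computed GP map reproduces `G` exactly. Multiplicative
#' Gaussian noise of relative SD `noise_sd_frac` is then applied per channel.
#'
#' @param true_gp_field numeric matrix with values in `[-1, 1]`.
#' @param total_intensity scalar or matrix of positive total counts.
#' @param noise_sd_frac relative SD of the multiplicative noise (0 = none).
#' @param seed integer seed.
#' @return list with `ordered`, `disordered` ([channel_image()]s) and
#'   `truth` (the input field).
#' @export
simulate_gp_pair <- function(true_gp_field, total_intensity = 1000,
                             noise_sd_frac = 0, seed = 1L) {
  stopifnot(is.matrix(true_gp_field), all(abs(true_gp_field) <= 1),
            all(total_intensity > 0), noise_sd_frac >= 0)
  with_seed(seed, {
    i_ord <- total_intensity * (1 + true_gp_field) / 2
    i_dis <- total_intensity * (1 - true_gp_field) / 2
    if (noise_sd_frac > 0) {
      i_ord <- pmax(i_ord * (1 + stats::rnorm(length(i_ord), 0,
                                              noise_sd_frac)), 0)
      i_dis <- pmax(i_dis * (1 + stats::rnorm(length(i_dis), 0,
                                              noise_sd_frac)), 0)
    }
    list(ordered = channel_image(i_ord, "gp_ordered"),
         disordered = channel_image(i_dis, "gp_disordered"),
         truth = true_gp_field)
  })
}

# deterministic per-larva sub-seed; stays below 2^31 - 1
larva_subseed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629) + 1L
}

#' Simulate a multi-batch cohort with known ground truth
#'
#' Each group's larvae are distributed over the batches round-robin; every
#' batch must end up with at least one control (DMSO) larva. Each larva is
#' generated from its own sub-seed, so a larva's images are independent of
#' the cohort composition. An optional per-batch multiplicative intensity
#' factor emulates acquisition differences between experiments.
#'
#' @param group_specs list of group definitions: each a `list(treatment =,
#'   n =, overrides = list(...), concentration =)`, where `overrides`
#'   replaces fields of `base_params` (e.g. `droplet_rate`).
#' @param n_batches number of batches (independent experiments).
#' @param base_params a [larva_sim_params()] shared by all groups.
#' @param seed cohort seed; drives every per-larva sub-seed.
#' @param control_label treatment label of the control group.
#' @param batch_factors optional numeric vector (length `n_batches`) of
#'   per-batch intensity factors; default all 1.
#' @param out_dir when given, images (2-plane TIFF per slice), masks (PNG),
#'   `samples.csv`, `truth.csv` and `manifest.yaml` are written there and
#'   paths are returned; when `NULL` the records stay in memory.
#' @return list with `records` (list of [larva_record()]s, `NULL` when
#'   written to disk), `truth` (per-larva truth table), and when `out_dir`
#'   is given, `sheet` (sample sheet path) and `dir`.
#' @export
simulate_cohort <- function(group_specs, n_batches = 1L,
                            base_params = larva_sim_params(), seed = 1L,
                            control_label = "DMSO", batch_factors = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(base_params, "larva_sim_params"), n_batches >= 1L)
  labels <- vapply(group_specs, `[[`, character(1), "treatment")
  if (!control_label %in% labels)
    staz_error("staz_config_error",
               sprintf("group_specs must include a '%s' control group",
                       control_label))
  nctl <- group_specs[[match(control_label, labels)]]$n
  if (nctl < n_batches)
    staz_error("staz_config_error",
               "control group needs at least one larva per batch")
  if (is.null(batch_factors)) batch_factors <- rep(1, n_batches)
  stopifnot(length(batch_factors) == n_batches, all(batch_factors > 0))

  plan <- do.call(rbind, lapply(seq_along(group_specs), function(gi) {
    g <- group_specs[[gi]]
    data.frame(treatment = g$treatment,
               concentration = if (!is.null(g$concentration))
                 g$concentration else NA_real_,
               group_index = gi,
               batch = ((seq_len(g$n) - 1L) %% n_batches) + 1L)
  }))
  plan$larva_id <- sprintf("L%03d", seq_len(nrow(plan)))
  plan$batch_id <- sprintf("B%d", plan$batch)

  rows <- vector("list", nrow(plan))
  records <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    g <- group_specs[[plan$group_index[i]]]
    p <- base_params
    for (nm in names(g$overrides)) p[[nm]] <- g$overrides[[nm]]
    p$seed <- larva_subseed(seed, i)
    sim <- simulate_larva(p, larva_id = plan$larva_id[i],
                          batch_id = plan$batch_id[i],
                          treatment = plan$treatment[i],
                          concentration = plan$concentration[i],
                          intensity_factor = batch_factors[plan$batch[i]])
    records[[i]] <- sim$record
    tr <- sim$truth$slices
    rows[[i]] <- data.frame(
      larva_id = plan$larva_id[i], batch_id = plan$batch_id[i],
      treatment = plan$treatment[i],
      concentration = plan$concentration[i],
      droplet_rate = p$droplet_rate,
      n_droplets_total = sum(tr$n_droplets),
      true_ld_dens_mean = mean(tr$ld_dens),
      true_ld_area_mean = mean(tr$ld_area),
      expected_raw_ratio_mean = mean(tr$raw_ratio))
  }
  truth <- do.call(rbind, rows)
  ctl_rate <- truth$droplet_rate[truth$treatment == control_label][1]
  truth$rate_ratio_vs_control <- truth$droplet_rate / ctl_rate

  if (is.null(out_dir))
    return(list(records = records, truth = truth))

  write_cohort(records, truth, seed, out_dir)
}

write_cohort <- function(records, truth, seed, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  sheet_rows <- list()
  for (rec in records) {
    for (sl in rec$slices) {
      stem <- sprintf("%s_s%d", rec$larva_id, sl$slice_index)
      img_rel <- file.path("images", paste0(stem, ".tif"))
      mask_rel <- file.path("masks", paste0(stem, "_mask.png"))
      planes <- lapply(sl$channels[c("lipid_green", "norm_blue")],
                       function(ch) pmin(round(ch$pixels), 65535) / 65535)
      tiff::writeTIFF(unname(planes), file.path(out_dir, img_rel),
                      bits.per.sample = 16L)
      png::writePNG(sl$mask$mask * 1, file.path(out_dir, mask_rel))
      sheet_rows[[length(sheet_rows) + 1L]] <- data.frame(
        larva_id = rec$larva_id, batch_id = rec$batch_id,
        treatment = rec$treatment, concentration = rec$concentration,
        slice_index = sl$slice_index,
        image_path = img_rel, mask_path = mask_rel)
    }
  }
  sheet_path <- file.path(out_dir, "samples.csv")
  write_results_table(do.call(rbind, sheet_rows), sheet_path)
  write_results_table(truth, file.path(out_dir, "truth.csv"))
  yaml::write_yaml(list(seed = seed, n_larvae = length(records),
                        created_by = "stazr simulate_cohort"),
                   file.path(out_dir, "manifest.yaml"))
  list(records = NULL, truth = truth, sheet = sheet_path, dir = out_dir)
}
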