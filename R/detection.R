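#' Spot-detection configuration
#'
#' @param sigma_um Expected spot SD in um per axis `(z, y, x)`; must be at
#'   least one voxel along every axis.
#' @param threshold_k Detection threshold in robust-noise units: a candidate
#'   local maximum must exceed `threshold_k` times the MAD (scaled to be
#'   consistent with the SD) of the filter response inside the cell mask.
#' @param measure_channels Auxiliary channels whose local signal is measured
#'   at every detected spot (see [measure_channel_at_spot()]).
#' @param probe_radius_um Probe-ball radius for auxiliary-channel
#'   measurements.
#' @param refine `"centroid"` (default) for intensity-weighted sub-voxel
#'   centroid refinement, `"none"` to keep voxel-centre positions.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(sigma_um = c(0.4, 0.25, 0.25), threshold_k = 5,
                             measure_channels = c("nterm", "cterm"),
                             probe_radius_um = 0.3,
                             refine = c("centroid", "none")) {
  structure(list(sigma_um = as.numeric(sigma_um), threshold_k = threshold_k,
                 measure_channels = measure_channels,
                 probe_radius_um = probe_radius_um,
                 refine = match.arg(refine)),
            class = "detection_config")
}

#' Detect sub-voxel mRNA spots in one channel
#'
#' Applies a scale-normalised Laplacian-of-Gaussian filter matched to the
#' expected spot size (axis-wise sigma in voxel units, so anisotropic voxels
#' are handled in filter space), finds strict 3D local maxima above
#' `threshold_k` x MAD of the masked response, refines each maximum to a
#' sub-voxel position by an intensity-weighted centroid over a 2-sigma
#' neighbourhood of the background-subtracted raw image, and integrates the
#' background-subtracted raw intensity over a 3-sigma ellipsoid. The local
#' background for each spot is the median of a 3-5 sigma ellipsoidal
#' annulus. Candidates whose integrated flux is not photometrically
#' significant (below `threshold_k` x the annulus noise scale of the summed
#' support) and spots outside the cell mask are discarded.
#'
#' @param image A [voxel_image].
#' @param channel Channel to detect on (default `"mrna"`).
#' @param config A [detection_config()].
#' @return A data frame with one row per spot: `z_um, y_um, x_um` (sub-voxel
#'   position), `intensity` (background-subtracted integrated intensity),
#'   `quality` (peak response in MAD units), `snr` (integrated flux over the
#'   noise scale of the summation support; candidates below `threshold_k`
#'   are rejected), `edge` (TRUE when the measurement support was clipped by
#'   the image border), and `<ch>_signal` / `<ch>_mad` columns for every
#'   measured auxiliary channel.
#' @export
detect_spots <- function(image, channel = "mrna",
                         config = detection_config()) {
  stopifnot(inherits(image, "voxel_image"))
  ch <- get_channel(image, channel)
  vs <- image$voxel_size
  sigma_vox <- config$sigma_um / vs
  if (any(sigma_vox < 1)) {
    stop("expected spot sigma is below one voxel on some axis; ",
         "acquire finer sampling or increase sigma_um (sigma must be >= ",
         "voxel_size per axis)")
  }
  mask <- image_mask(image)
  resp <- log_response(ch, sigma_vox)
  noise_mad <- stats::mad(resp[mask])
  thr <- config$threshold_k * noise_mad
  peaks <- local_maxima_3d(resp, thr, mask)

  shape <- dim(ch)
  off_core <- ellipsoid_offsets(2 * config$sigma_um, vs)
  off_int <- ellipsoid_offsets(3 * config$sigma_um, vs)
  off_bg <- {
    big <- ellipsoid_offsets(5 * config$sigma_um, vs)
    keep <- !duplicated(rbind(off_int, big))[-seq_len(nrow(off_int))]
    big[keep, , drop = FALSE]
  }

  n <- nrow(peaks)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- peaks[i, ]
    bg_at <- offsets_at(v, off_bg, shape)
    bg <- stats::median(ch[bg_at$idx])
    core <- offsets_at(v, off_core, shape)
    w <- pmax(ch[core$idx] - bg, 0)
    pos_um <- if (config$refine == "centroid" && sum(w) > 0) {
      colSums(voxel_center_um(core$idx, vs) * w) / sum(w)
    } else {
      (v - 0.5) * vs
    }
    ib <- offsets_at(v, off_int, shape)
    intensity <- sum(ch[ib$idx] - bg)
    # photometric significance: the integrated (background-subtracted) flux
    # of a real spot must exceed k x the noise scale of a sum of that many
    # voxels; this rejects filter-response flukes from heavy Poisson tails
    ann_mad <- stats::mad(ch[bg_at$idx])
    snr <- intensity / (ann_mad * sqrt(nrow(ib$idx)) + .Machine$double.eps)
    out[[i]] <- data.frame(
      z_um = pos_um[1], y_um = pos_um[2], x_um = pos_um[3],
      intensity = intensity,
      quality = resp[v[1], v[2], v[3]] / noise_mad,
      snr = snr,
      edge = ib$truncated || bg_at$truncated)
  }
  spots <- if (n > 0) do.call(rbind, out) else
    data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
               intensity = numeric(0), quality = numeric(0),
               snr = numeric(0), edge = logical(0))
  spots <- spots[spots$intensity > 0 &
                   spots$snr > config$threshold_k, , drop = FALSE]
  # mask restriction on the refined position
  if (nrow(spots) > 0) {
    vox <- um_to_voxel(as.matrix(spots[, c("z_um", "y_um", "x_um")]),
                       matrix(vs, nrow(spots), 3, byrow = TRUE),
                       matrix(shape, nrow(spots), 3, byrow = TRUE))
    inside <- mask[matrix(vox, ncol = 3)]
    spots <- spots[inside, , drop = FALSE]
  }
  rownames(spots) <- NULL
  for (aux in config$measure_channels) {
    if (!aux %in% image$channel_labels) next
    sig <- numeric(nrow(spots)); madv <- numeric(nrow(spots))
    for (i in seq_len(nrow(spots))) {
      m <- measure_channel_at_spot(
        image, c(spots$z_um[i], spots$y_um[i], spots$x_um[i]), aux,
        probe_radius_um = config$probe_radius_um)
      sig[i] <- m$signal; madv[i] <- m$mad
    }
    spots[[paste0(aux, "_signal")]] <- sig
    spots[[paste0(aux, "_mad")]] <- madv
  }
  spots
}

#' Segmentation configuration for PCM reference bodies
#'
#' @param smooth_sigma_um Gaussian pre-smoothing SD (um, isotropic).
#' @param threshold_k Robust-noise multiplier: the detection threshold is
#'   `max(Otsu within mask, background median + threshold_k * MAD)`.
#' @param min_volume_um3 Minimum component volume retained.
#' @param max_components Keep at most this many components per cell, ranked
#'   by summed intensity (mitotic cells have 1-2 centrosomes).
#' @param peak_fraction Per-component boundary refinement level as a
#'   fraction of the background-subtracted component peak. The default
#'   `exp(-2)` is the 1/e^2 (beam-waist) convention: for a Gaussian blob of
#'   SD sigma the boundary falls at `r = 2 * sigma`, i.e. at the nominal PCM
#'   radius when the blob SD is radius/2.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(smooth_sigma_um = 0.1, threshold_k = 5,
                                min_volume_um3 = 0.1, max_components = 2L,
                                peak_fraction = exp(-2)) {
  structure(list(smooth_sigma_um = smooth_sigma_um, threshold_k = threshold_k,
                 min_volume_um3 = min_volume_um3,
                 max_components = as.integer(max_components),
                 peak_fraction = peak_fraction),
            class = "segmentation_config")
}

#' Segment centrosome / PCM reference bodies
#'
#' Gaussian pre-smoothing, a global detection threshold of
#' `max(Otsu, background median + k * MAD)` within the cell mask, and
#' 26-connected components above the minimum volume. Because a PCM blob has
#' no sharp edge, each detected component's boundary is then refined to the
#' 1/e^2-of-peak level (see [segmentation_config()]); the component
#' containing the peak at that level defines the segmented volume. Per
#' component the intensity-weighted centre of mass, the equivalent radius of
#' the sphere matching the segmented volume, and the sum of *original*
#' (unsmoothed, non-background-subtracted) intensities are reported.
#'
#' @param image A [voxel_image].
#' @param channel Channel carrying the reference marker (default
#'   `"reference"`).
#' @param config A [segmentation_config()].
#' @return A data frame with one row per retained component, ranked by
#'   `sum_intensity` (rank 1 = brightest): `rank, z_um, y_um, x_um`
#'   (centre of mass), `radius_um` (equivalent radius), `sum_intensity`,
#'   `volume_um3`, `n_voxels`. Empty (0-row) when nothing exceeds threshold.
#' @export
segment_reference <- function(image, channel = "reference",
                              config = segmentation_config()) {
  stopifnot(inherits(image, "voxel_image"))
  ch <- get_channel(image, channel)
  vs <- image$voxel_size
  mask <- image_mask(image)
  sm <- gaussian_smooth_3d(ch, config$smooth_sigma_um / vs)
  bg_med <- stats::median(sm[mask])
  bg_mad <- stats::mad(sm[mask])
  thr <- max(otsu_threshold(sm[mask]), bg_med + config$threshold_k * bg_mad)
  det <- sm > thr & mask
  voxel_vol <- prod(vs)
  empty <- data.frame(rank = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), radius_um = numeric(0),
                      sum_intensity = numeric(0), volume_um3 = numeric(0),
                      n_voxels = integer(0))
  if (!any(det)) return(empty)
  labs <- label_components_3d(det)
  n_comp <- max(labs)
  recs <- list()
  for (k in seq_len(n_comp)) {
    comp_idx <- which(labs == k, arr.ind = TRUE, useNames = FALSE)
    if (nrow(comp_idx) * voxel_vol < config$min_volume_um3) next
    peak_row <- comp_idx[which.max(sm[comp_idx]), ]
    peak_val <- sm[peak_row[1], peak_row[2], peak_row[3]]
    refine_thr <- bg_med + config$peak_fraction * (peak_val - bg_med)
    # refined region: connected component of the refined super-threshold set
    # that contains this peak (computed in a padded crop for economy)
    pad_vox <- ceiling(2 * 2 / vs)  # generous 4 um halo never hurts
    lo <- pmax(apply(comp_idx, 2, min) - pad_vox, 1L)
    hi <- pmin(apply(comp_idx, 2, max) + pad_vox, dim(ch))
    crop <- sm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    crop_mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dim(crop) <- hi - lo + 1L
    dim(crop_mask) <- hi - lo + 1L
    rl <- label_components_3d(crop >= refine_thr & crop_mask)
    peak_in_crop <- peak_row - lo + 1L
    lab_at_peak <- rl[peak_in_crop[1], peak_in_crop[2], peak_in_crop[3]]
    if (lab_at_peak == 0L) next
    reg <- which(rl == lab_at_peak, arr.ind = TRUE, useNames = FALSE)
    reg_abs <- sweep(reg, 2, lo - 1L, "+")
    w <- pmax(ch[reg_abs] - bg_med, 0)
    com <- if (sum(w) > 0) {
      colSums(voxel_center_um(reg_abs, vs) * w) / sum(w)
    } else {
      colMeans(voxel_center_um(reg_abs, vs))
    }
    vol <- nrow(reg_abs) * voxel_vol
    recs[[length(recs) + 1L]] <- data.frame(
      rank = NA_integer_, z_um = com[1], y_um = com[2], x_um = com[3],
      radius_um = (3 * vol / (4 * pi))^(1 / 3),
      sum_intensity = sum(ch[reg_abs]), volume_um3 = vol,
      n_voxels = nrow(reg_abs), peak_z = peak_row[1])
  }
  if (length(recs) == 0) return(empty)
  recs <- do.call(rbind, recs)
  # refinement can merge two detections into one region: drop duplicates
  recs <- recs[!duplicated(round(recs[, c("z_um", "y_um", "x_um")], 6)), ,
               drop = FALSE]
  recs <- recs[order(-recs$sum_intensity), , drop = FALSE]
  recs <- utils::head(recs, config$max_components)
  recs$rank <- seq_len(nrow(recs))
  recs$peak_z <- NULL
  rownames(recs) <- NULL
  recs
}

#' Local background-subtracted channel signal at a spot
#'
#' Mean intensity of `channel` within a `probe_radius_um` physical ball
#' centred on the given position, minus the median of an ellipsoidal annulus
#' spanning 2-3 x the probe radius (local background). The annulus MAD is
#' returned as the robust noise scale for positivity calls.
#'
#' @param image A [voxel_image].
#' @param position_um Numeric length-3 `(z, y, x)` position in um (or a
#'   1-row spot data frame with `z_um, y_um, x_um`).
#' @param channel Channel name.
#' @param probe_radius_um Probe-ball radius in um (must reach at least one
#'   voxel).
#' @return List with `signal` (ball mean minus annulus median), `background`
#'   (annulus median), `mad` (annulus MAD), `n` (ball voxels used),
#'   `truncated` (TRUE when the support was clipped by the image edge).
#' @export
measure_channel_at_spot <- function(image, position_um, channel,
                                    probe_radius_um = 0.3) {
  stopifnot(inherits(image, "voxel_image"))
  if (is.data.frame(position_um)) {
    position_um <- as.numeric(position_um[1, c("z_um", "y_um", "x_um")])
  }
  ch <- get_channel(image, channel)
  vs <- image$voxel_size
  if (probe_radius_um < min(vs)) {
    stop("probe_radius_um must reach at least one voxel")
  }
  shape <- dim(ch)
  v <- um_to_voxel(position_um, vs, shape)
  ball_off <- ellipsoid_offsets(rep(probe_radius_um, 3), vs)
  outer_off <- ellipsoid_offsets(rep(3 * probe_radius_um, 3), vs)
  inner_off <- ellipsoid_offsets(rep(2 * probe_radius_um, 3), vs)
  ann_keep <- !duplicated(rbind(inner_off, outer_off))[-seq_len(nrow(inner_off))]
  ann_off <- outer_off[ann_keep, , drop = FALSE]
  ball <- offsets_at(v, ball_off, shape)
  ann <- offsets_at(v, ann_off, shape)
  bg <- stats::median(ch[ann$idx])
  madv <- stats::mad(ch[ann$idx])
  list(signal = mean(ch[ball$idx]) - bg, background = bg, mad = madv,
       n = nrow(ball$idx), truncated = ball$truncated || ann$truncated)
}
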