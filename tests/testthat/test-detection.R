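test_that("blank images yield (almost) no spots at the default threshold", {
  fp <- 0L; voxels <- 0
  for (s in 1:20) {
    g <- generate_cell(tiny_params(n_spots = 0L, seed = 100L + s))
    sp <- detect_spots(g$image)
    fp <- fp + nrow(sp)
    voxels <- voxels + prod(dim(get_channel(g$image, "mrna")))
  }
  expect_lte(fp / (voxels / 1e6), 1)  # <= 1 false positive per megavoxel
})

test_that("an isolated SNR-8 source is found with sub-voxel accuracy", {
  p <- generator_params(image_shape = c(20L, 48L, 48L), n_centrosomes = 1L,
                        n_spots = 0L, seed = 17L)
  g <- generate_cell(p)
  # inject one point source off voxel centres, then re-apply noise protocol
  pos <- c(2.87, 4.93, 5.11)
  mrna <- centrofish:::render_gaussian_source(
    array(p$noise$baseline, p$image_shape), pos, p$psf_sigma,
    p$spot_intensity, p$voxel_size)
  mrna <- centrofish:::with_seed(3L, centrofish:::apply_noise(mrna, p$noise))
  img <- voxel_image(list(mrna = mrna), p$voxel_size)
  sp <- detect_spots(img)
  expect_equal(nrow(sp), 1)
  err <- abs(c(sp$z_um, sp$y_um, sp$x_um) - pos)
  expect_true(all(err <= 0.5 * p$voxel_size))
  expect_lt(abs(sp$intensity - p$spot_intensity) / p$spot_intensity, 0.2)
})

test_that("two sources 5 um apart are resolved and matched to truth", {
  p <- generator_params(image_shape = c(20L, 48L, 48L), n_centrosomes = 1L,
                        n_spots = 0L, seed = 18L)
  truth <- make_spots(z = c(3.0, 3.0), y = c(2.4, 5.4), x = c(2.8, 6.8),
                      intensity = p$spot_intensity)
  mrna <- array(p$noise$baseline, p$image_shape)
  for (i in 1:2) {
    mrna <- centrofish:::render_gaussian_source(
      mrna, as.numeric(truth[i, c("z_um", "y_um", "x_um")]), p$psf_sigma,
      truth$intensity[i], p$voxel_size)
  }
  mrna <- centrofish:::with_seed(5L, centrofish:::apply_noise(mrna, p$noise))
  sp <- detect_spots(voxel_image(list(mrna = mrna), p$voxel_size))
  expect_equal(nrow(sp), 2)
  m <- match_spots(truth, sp, radius = 0.3)
  expect_equal(m$n_matched, 2L)
})

test_that("detection meets recall/precision >= 0.9 on default presets", {
  rec <- prec <- numeric(0)
  for (s in 1:10) {
    g <- generate_cell(preset_params("early_M_control", seed = s))
    sp <- detect_spots(g$image)
    m <- match_spots(g$truth$spots, sp, radius = 0.5)
    rec <- c(rec, m$recall); prec <- c(prec, m$precision)
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})

test_that("whole-voxel translation shifts detections by exactly the offset", {
  g <- generate_cell(preset_params("early_M_control", seed = 23L))
  mrna <- get_channel(g$image, "mrna")
  d <- dim(mrna)
  off <- c(2L, 3L, -4L)
  shifted <- array(0, d)
  src_z <- pmin(pmax(seq_len(d[1]) - off[1], 1L), d[1])
  src_y <- pmin(pmax(seq_len(d[2]) - off[2], 1L), d[2])
  src_x <- pmin(pmax(seq_len(d[3]) - off[3], 1L), d[3])
  shifted[, , ] <- mrna[src_z, src_y, src_x]
  sp0 <- detect_spots(voxel_image(list(mrna = mrna), g$image$voxel_size))
  sp1 <- detect_spots(voxel_image(list(mrna = shifted), g$image$voxel_size))
  off_um <- off * g$image$voxel_size
  # compare interior spots (away from the replicated borders)
  ext <- dim(mrna) * g$image$voxel_size
  # margin must exceed the 5-sigma background annulus reach (2.0 um in z)
  interior <- function(s, margin = 2.1) {
    s[s$z_um > margin & s$z_um < ext[1] - margin &
        s$y_um > margin & s$y_um < ext[2] - margin &
        s$x_um > margin & s$x_um < ext[3] - margin, ]
  }
  a <- interior(sp0)
  a$z_um <- a$z_um + off_um[1]; a$y_um <- a$y_um + off_um[2]
  a$x_um <- a$x_um + off_um[3]
  a <- interior(a)
  for (i in seq_len(nrow(a))) {
    dd <- sqrt((sp1$z_um - a$z_um[i])^2 + (sp1$y_um - a$y_um[i])^2 +
                 (sp1$x_um - a$x_um[i])^2)
    expect_lt(min(dd), 1e-8)
  }
})

test_that("doubling true fluxes never decreases matched intensities", {
  noise_off <- list(photon_scaling = 1, read_sd = 2, baseline = 10,
                    enabled = FALSE)
  p1 <- preset_params("early_M_control", seed = 31L, noise = noise_off)
  p2 <- preset_params("early_M_control", seed = 31L, noise = noise_off,
                      spot_intensity = 2 * 2400)
  s1 <- detect_spots(generate_cell(p1)$image)
  s2 <- detect_spots(generate_cell(p2)$image)
  m <- match_spots(s1, s2, radius = 0.3)
  paired <- which(!is.na(m$match_of))
  expect_gt(length(paired), 10)
  expect_true(all(s2$intensity[m$match_of[paired]] >= s1$intensity[paired]))
})

test_that("cell-mask restriction holds for spots and centrosomes", {
  p <- preset_params("early_M_control", seed = 41L)
  g <- generate_cell(p)
  # ellipsoidal mask centred in the volume
  shp <- p$image_shape; vs <- p$voxel_size
  ctr <- shp * vs / 2
  idx <- which(array(TRUE, shp), arr.ind = TRUE)
  cc <- centrofish:::voxel_center_um(idx, vs)
  r2 <- ((cc[, 1] - ctr[1]) / 2.5)^2 + ((cc[, 2] - ctr[2]) / 4)^2 +
    ((cc[, 3] - ctr[3]) / 4)^2
  mask <- array(r2 <= 1, shp)
  img <- voxel_image(list(mrna = get_channel(g$image, "mrna"),
                          reference = get_channel(g$image, "reference")),
                     vs, cell_mask = mask)
  sp <- detect_spots(img, config = detection_config(measure_channels = NULL))
  cs <- segment_reference(img)
  inside <- function(z, y, x) {
    v <- centrofish:::um_to_voxel(c(z, y, x), vs, shp)
    mask[v[1], v[2], v[3]]
  }
  if (nrow(sp) > 0) {
    expect_true(all(mapply(inside, sp$z_um, sp$y_um, sp$x_um)))
  }
  if (nrow(cs) > 0) {
    expect_true(all(mapply(inside, cs$z_um, cs$y_um, cs$x_um)))
  }
})

test_that("detection rejects sub-voxel sigma and missing channels", {
  g <- generate_cell(tiny_params(seed = 2L))
  expect_error(detect_spots(g$image, channel = "nope"), "not found")
  expect_error(
    detect_spots(g$image,
                 config = detection_config(sigma_um = c(0.4, 0.1, 0.1))),
    "below one voxel")
})

test_that("PCM segmentation recovers blob geometry and ranking", {
  # blank reference -> empty result
  g0 <- generate_cell(tiny_params(n_spots = 0L, centrosome_amplitude = 1e-6,
                                  seed = 3L))
  ref0 <- array(10, dim(get_channel(g0$image, "reference")))
  img0 <- voxel_image(list(reference = ref0), g0$image$voxel_size)
  expect_equal(nrow(segment_reference(img0)), 0)

  # a single blob of nominal radius 1 um
  p <- generator_params(n_centrosomes = 1L, n_spots = 0L, seed = 6L)
  g <- generate_cell(p)
  cs <- segment_reference(g$image)
  expect_equal(nrow(cs), 1)
  truth_ctr <- p$centrosome_centers[1, ]
  expect_lt(sqrt(sum((c(cs$z_um, cs$y_um, cs$x_um) - truth_ctr)^2)), 0.2)
  expect_lt(abs(cs$radius_um - 1.0), 0.3)

  # two blobs with fluxes A and 2A -> the brighter is rank 1
  p2 <- generator_params(n_centrosomes = 2L, n_spots = 0L, seed = 7L)
  g2 <- generate_cell(p2)
  ref <- get_channel(g2$image, "reference")
  # add an extra blob of twice the flux at a third location
  ref <- centrofish:::render_gaussian_source(
    ref, c(3, 9.6, 6.4), rep(p2$centrosome_radius / 2, 3),
    2 * p2$centrosome_amplitude, p2$voxel_size)
  cs2 <- segment_reference(voxel_image(list(reference = ref),
                                       p2$voxel_size),
                           config = segmentation_config(max_components = 3L))
  expect_equal(nrow(cs2), 3)
  expect_lt(sqrt((cs2$y_um[1] - 9.6)^2 + (cs2$x_um[1] - 6.4)^2), 0.3)
  expect_true(all(diff(cs2$sum_intensity) <= 0))
})

test_that("channel measurement handles null, flat and real signals", {
  p <- generator_params(n_centrosomes = 1L, n_spots = 0L, seed = 8L,
                        translating_fraction = 0)
  shp <- p$image_shape
  zero <- array(0, shp)
  flat <- array(123.4, shp)
  nterm <- centrofish:::render_gaussian_source(
    array(p$noise$baseline, shp), c(3, 6.4, 6.4), p$psf_sigma,
    p$nterm_spot_amplitude, p$voxel_size)
  nterm <- centrofish:::with_seed(4L,
                                  centrofish:::apply_noise(nterm, p$noise))
  img <- voxel_image(list(zero = zero, flat = flat, nterm = nterm),
                     p$voxel_size)
  expect_equal(measure_channel_at_spot(img, c(3, 6.4, 6.4), "zero")$signal, 0)
  expect_equal(measure_channel_at_spot(img, c(3, 6.4, 6.4), "flat")$signal, 0)
  m <- measure_channel_at_spot(img, c(3, 6.4, 6.4), "nterm")
  expect_gt(m$signal, 5 * m$mad)
  # edge truncation is flagged
  edge <- measure_channel_at_spot(img, c(0.1, 0.1, 0.1), "nterm")
  expect_true(edge$truncated)
  expect_error(measure_channel_at_spot(img, c(3, 6.4, 6.4), "nterm",
                                       probe_radius_um = 0.05),
               "at least one voxel")
})
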