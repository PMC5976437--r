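test_that("empty cells and determinism behave as stated", {
  p <- tiny_params(n_spots = 0L, seed = 7L)
  g <- generate_cell(p)
  expect_equal(nrow(g$truth$spots), 0)
  # mRNA channel contains only baseline + noise: nothing above a level far
  # below any spot but far above noise
  mrna <- get_channel(g$image, "mrna")
  expect_lt(max(mrna), p$noise$baseline + 40)

  g1 <- generate_cell(tiny_params(seed = 11L))
  g2 <- generate_cell(tiny_params(seed = 11L))
  expect_identical(g1$image$data, g2$image$data)
  expect_identical(g1$truth$spots, g2$truth$spots)
  g3 <- generate_cell(tiny_params(seed = 12L))
  expect_false(identical(g1$image$data, g3$image$data))
})

test_that("parameter invariants are enforced", {
  expect_error(tiny_params(proximal_fraction = 1.2), "fractions")
  expect_error(tiny_params(proximal_decay_length = -1), "positive")
  expect_error(generator_params(voxel_size = c(0.3, 0, 0.2)), "positive")
  expect_error(tiny_params(centrosome_centers = matrix(c(-1, 0, 0), 1)),
               "bounds")
  expect_error(generator_params(n_centrosomes = 3L), "1 or 2")
})

test_that("proximal radial law matches the quadrature oracle", {
  # pure proximal component, generous volume, noise off
  p <- generator_params(image_shape = c(32L, 64L, 64L),
                        voxel_size = c(0.3, 0.2, 0.2),
                        n_centrosomes = 1L, n_spots = 500L,
                        proximal_fraction = 1.0,
                        proximal_decay_length = 1.5,
                        noise = list(photon_scaling = 1, read_sd = 2,
                                     baseline = 10, enabled = FALSE),
                        seed = 5L)
  g <- generate_cell(p, render = FALSE)
  d <- g$truth$spots$distance_um
  r_max <- min(c(p$centrosome_centers[1, ],
                 p$image_shape * p$voxel_size - p$centrosome_centers[1, ]))
  mu <- truncated_shell_mean(1.5, r_max)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mu), 3 * se)
  expect_lte(max(d), r_max + 1e-12)
})

test_that("rendered spot flux is conserved before noise", {
  n_checked <- 0L
  for (seed in 21:25) {
    p <- generator_params(image_shape = c(24L, 64L, 64L),
                          n_centrosomes = 1L, n_spots = 8L,
                          proximal_fraction = 0, translating_fraction = 0,
                          noise = list(photon_scaling = 1, read_sd = 2,
                                       baseline = 0, enabled = FALSE),
                          cterm_background = 0, seed = seed)
    g <- generate_cell(p)
    tr <- g$truth$spots
    mrna <- get_channel(g$image, "mrna")
    vs <- p$voxel_size
    for (i in seq_len(nrow(tr))) {
      ctr <- c(tr$z_um[i], tr$y_um[i], tr$x_um[i])
      # only spots whose 4-sigma support is fully inside the image and with
      # no neighbour close enough to leak mass into the summation box
      supp_ok <- all(ctr - 4 * p$psf_sigma > 0) &&
        all(ctr + 4 * p$psf_sigma < p$image_shape * vs)
      if (!supp_ok) next
      lo <- pmax(floor((ctr - 5 * p$psf_sigma) / vs) + 1, 1)
      hi <- pmin(ceiling((ctr + 5 * p$psf_sigma) / vs), p$image_shape)
      box_lo <- (lo - 1) * vs; box_hi <- hi * vs
      # skip spots whose neighbours leak non-negligible Gaussian mass into
      # the summation box (analytic bound, anisotropy-aware)
      leak <- 0
      for (j in setdiff(seq_len(nrow(tr)), i)) {
        pj <- c(tr$z_um[j], tr$y_um[j], tr$x_um[j])
        leak <- leak + tr$intensity[j] *
          prod(pnorm(box_hi, pj, p$psf_sigma) -
                 pnorm(box_lo, pj, p$psf_sigma))
      }
      if (leak > 0.002 * tr$intensity[i]) next
      s <- sum(mrna[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
      expect_lt(abs(s - tr$intensity[i]) / tr$intensity[i], 0.01)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 3)
})

test_that("raising the proximal fraction pulls spots inward", {
  meds <- vapply(c(0.2, 0.5, 0.9), function(pf) {
    g <- generate_cell(generator_params(n_spots = 500L,
                                        proximal_fraction = pf,
                                        seed = 33L), render = FALSE)
    median(g$truth$spots$distance_um)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("translating flags are exact and C-terminus stays diffuse", {
  p <- generator_params(n_spots = 25L, translating_fraction = 0.4,
                        noise = list(photon_scaling = 1, read_sd = 2,
                                     baseline = 0, enabled = FALSE),
                        seed = 9L)
  g <- generate_cell(p)
  expect_equal(sum(g$truth$spots$translating), round(0.4 * 25))
  # no translating spot contributes a C-terminus source: the noise-free
  # cterm channel is exactly the flat background everywhere
  expect_equal(max(abs(get_channel(g$image, "cterm") - p$cterm_background)),
               0)
  # every translating spot leaves N-terminus flux near its position
  nterm <- get_channel(g$image, "nterm")
  tr <- g$truth$spots[g$truth$spots$translating, ]
  for (i in seq_len(nrow(tr))) {
    v <- pmin(pmax(floor(c(tr$z_um[i], tr$y_um[i], tr$x_um[i]) /
                           p$voxel_size) + 1, 1), p$image_shape)
    expect_gt(nterm[v[1], v[2], v[3]], 1)
  }
})

test_that("presets encode the published effect-size ratios", {
  ctrl <- preset_params("early_M_control")
  # emetine preserves polysomes: localization identical to control
  expect_equal(preset_params("early_M_emetine")$proximal_fraction,
               ctrl$proximal_fraction)
  # twofold PCM increase from late G2 to early M
  expect_equal(ctrl$centrosome_amplitude /
                 preset_params("late_G2")$centrosome_amplitude, 2.0)
  # fourfold mRNA increase from G1 to late G2
  expect_equal(preset_params("late_G2")$n_spots /
                 preset_params("G1")$n_spots, 4.0)
  # acute puromycin: 30% PCM reduction, dispersal, no translation
  puro <- preset_params("early_M_puromycin")
  expect_equal(puro$centrosome_amplitude / ctrl$centrosome_amplitude, 0.7)
  expect_equal(puro$translating_fraction, 0)
  expect_lt(puro$proximal_fraction, 0.1)
  expect_identical(preset_params("early_M_harringtonine")$proximal_fraction,
                   puro$proximal_fraction)
  expect_error(preset_params("interphase"), "unknown preset")
})

test_that("population generation is deterministic with documented jitter", {
  pop <- generate_population("early_M_control", 3, seed = 4L,
                             render = FALSE)
  expect_length(pop, 3)
  expect_false(identical(pop[[1]]$truth$spots, pop[[2]]$truth$spots))
  pop2 <- generate_population("early_M_control", 3, seed = 4L,
                              render = FALSE)
  expect_identical(pop, pop2)
  # zero jitter: all cells share the generating parameters
  pop0 <- generate_population("early_M_control", 3, seed = 4L,
                              jitter_sdlog = 0, render = FALSE)
  pars <- lapply(pop0, function(cl) {
    p <- cl$truth$params; p$seed <- NULL; p
  })
  expect_identical(pars[[1]], pars[[2]])
  expect_identical(pars[[1]], pars[[3]])
  expect_error(generate_population("early_M_control", 0), "n_cells")
})
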