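# Ground-truthed synthetic 3D smFISH / IF image generator.
#
# The generated world: one mitotic cell per image with 1-2 bright
# pericentriolar-material (PCM) blobs on a reference channel, diffraction-
# limited mRNA spots on an smFISH channel whose volumetric density around the
# nearest centrosome decays exponentially (a configurable fraction is drawn
# from this proximal component, the rest uniform background), and a subset of
# "translating" spots that carry a colocalised N-terminus IF source but no
# C-terminus source. Channels receive Poisson shot noise on photon-scaled
# signal plus additive Gaussian read noise.

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic cell generator
#'
#' Defaults describe a desk-scale early-mitotic cell: a 6 x 12.8 x 12.8 um
#' volume (roughly a quarter of a mitotic cell) at confocal-like sampling,
#' two bright PCM blobs of nominal radius 1 um (the blob is rendered as an
#' isotropic Gaussian of SD `radius/2`) 4 um apart, and 32 mRNA spots of
#' which 60% are drawn from a centrosome-proximal component whose volumetric
#' density decays exponentially with distance (decay length 1.5 um) and the
#' rest uniformly across the volume. The PSF SD (0.4 um axial, 0.25 um
#' lateral) emulates deconvolved confocal data; the density and PSF are
#' jointly chosen so that neighbouring spots are resolvable, as they
#' visibly are in real smFISH data. Half of the spots are actively
#' translating and carry an N-terminus IF source. Noise defaults give a
#' single-spot peak SNR of about 8.
#'
#' @param image_shape Integer length-3, voxels per axis `(z, y, x)`.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param n_centrosomes 1 or 2.
#' @param centrosome_centers Matrix (one row per centrosome) of um
#'   coordinates `(z, y, x)`, or `NULL` for symmetric defaults about the
#'   image centre (4 um apart along x when there are two).
#' @param centrosome_radius Nominal PCM radius in um; the rendered blob is a
#'   Gaussian of SD `centrosome_radius / 2`.
#' @param centrosome_amplitude Total integrated flux of each PCM blob (a.u.).
#' @param n_spots Number of mRNA spots.
#' @param proximal_fraction Fraction of spots drawn from the
#'   centrosome-proximal exponential component (the rest are uniform).
#' @param proximal_decay_length Decay length lambda (um) of the exponential
#'   volumetric density `exp(-r/lambda)`.
#' @param translating_fraction Fraction of spots carrying an N-terminus
#'   source; exactly `round(translating_fraction * n_spots)` spots are
#'   flagged.
#' @param spot_intensity Mean integrated mRNA spot flux (a.u.); individual
#'   fluxes are log-normal with `spot_intensity_sdlog`.
#' @param spot_intensity_sdlog Log-SD of spot flux variation.
#' @param nterm_spot_amplitude Integrated flux of the N-terminus IF source on
#'   a translating spot (a.u.).
#' @param cterm_background Constant C-terminus channel level (diffuse
#'   full-length protein), a.u.
#' @param psf_sigma Gaussian PSF SD in um per axis `(z, y, x)`.
#' @param noise List with `photon_scaling` (photons per a.u. for the Poisson
#'   stage), `read_sd` (Gaussian read-noise SD, a.u.), `baseline` (camera
#'   offset added to all channels, a.u.) and `enabled`.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#'
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(image_shape = c(20L, 64L, 64L),
                             voxel_size = c(0.3, 0.2, 0.2),
                             n_centrosomes = 2L,
                             centrosome_centers = NULL,
                             centrosome_radius = 1.0,
                             centrosome_amplitude = 2e5,
                             n_spots = 32L,
                             proximal_fraction = 0.6,
                             proximal_decay_length = 1.5,
                             translating_fraction = 0.5,
                             spot_intensity = 2400,
                             spot_intensity_sdlog = 0.25,
                             nterm_spot_amplitude = 4000,
                             cterm_background = 20,
                             psf_sigma = c(0.4, 0.25, 0.25),
                             noise = list(photon_scaling = 1, read_sd = 2,
                                          baseline = 10, enabled = TRUE),
                             seed = 1L) {
  extent <- image_shape * voxel_size
  if (is.null(centrosome_centers)) {
    mid <- extent / 2
    centrosome_centers <- if (n_centrosomes == 1L) {
      matrix(mid, nrow = 1)
    } else {
      rbind(mid + c(0, 0, -2), mid + c(0, 0, 2))
    }
  }
  centrosome_centers <- matrix(as.numeric(centrosome_centers), ncol = 3)
  p <- structure(
    list(image_shape = as.integer(image_shape),
         voxel_size = as.numeric(voxel_size),
         n_centrosomes = as.integer(n_centrosomes),
         centrosome_centers = centrosome_centers,
         centrosome_radius = centrosome_radius,
         centrosome_amplitude = centrosome_amplitude,
         n_spots = as.integer(n_spots),
         proximal_fraction = proximal_fraction,
         proximal_decay_length = proximal_decay_length,
         translating_fraction = translating_fraction,
         spot_intensity = spot_intensity,
         spot_intensity_sdlog = spot_intensity_sdlog,
         nterm_spot_amplitude = nterm_spot_amplitude,
         cterm_background = cterm_background,
         psf_sigma = as.numeric(psf_sigma),
         noise = noise,
         seed = as.integer(seed)),
    class = "generator_params")
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  fr <- c(p$proximal_fraction, p$translating_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  pos <- c(p$voxel_size, p$centrosome_radius, p$centrosome_amplitude,
           p$proximal_decay_length, p$spot_intensity, p$nterm_spot_amplitude,
           p$psf_sigma)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("lengths and amplitudes must be strictly positive")
  }
  if (p$n_spots < 0L) stop("n_spots must be >= 0")
  if (!p$n_centrosomes %in% 1:2) stop("n_centrosomes must be 1 or 2")
  if (nrow(p$centrosome_centers) != p$n_centrosomes) {
    stop("need one centre per centrosome")
  }
  extent <- p$image_shape * p$voxel_size
  inb <- p$centrosome_centers >= 0 &
    sweep(p$centrosome_centers, 2, extent, "<=")
  if (!all(inb)) stop("centrosome centres must lie inside the image bounds")
  invisible(p)
}

#' Condition presets for the synthetic generator
#'
#' Named parameter sets emulating the experimental conditions of the
#' underlying cell-cycle / translation-inhibition experiments, with effect
#' sizes fixed relative to the early-mitotic control:
#'
#' * `early_M_control`: defaults of [generator_params()].
#' * `early_M_puromycin`: ribosomes dissociated — proximal fraction collapsed
#'   to near background (0.05), no translating spots, PCM flux x 0.7 (the
#'   ~30% reduction in centrosomal protein after acute translation block).
#' * `early_M_harringtonine`: run-off, polysomes lost — same as puromycin.
#' * `early_M_emetine`: elongation frozen, polysomes intact — identical to
#'   control.
#' * `late_G2`: PCM flux x 0.5 relative to early M (the twofold mitotic
#'   increase), same mRNA count as early M.
#' * `G1`: one centrosome and a quarter of the late-G2 mRNA count (the
#'   fourfold G1 to late-G2 increase), PCM flux as late G2.
#'
#' @param name One of `G1`, `late_G2`, `early_M_control`,
#'   `early_M_puromycin`, `early_M_emetine`, `early_M_harringtonine`.
#' @param ... Overrides passed to [generator_params()].
#' @return A `generator_params` object.
#' @export
preset_params <- function(name, ...) {
  base <- list(...)
  mods <- switch(
    name,
    early_M_control = list(),
    early_M_emetine = list(),
    early_M_puromycin = list(proximal_fraction = 0.05,
                             translating_fraction = 0,
                             centrosome_amplitude = 2e5 * 0.7),
    early_M_harringtonine = list(proximal_fraction = 0.05,
                                 translating_fraction = 0,
                                 centrosome_amplitude = 2e5 * 0.7),
    late_G2 = list(centrosome_amplitude = 2e5 * 0.5),
    G1 = list(centrosome_amplitude = 2e5 * 0.5, n_spots = 8L,
              n_centrosomes = 1L),
    stop(sprintf("unknown preset '%s'", name))
  )
  args <- utils::modifyList(mods, base)
  p <- do.call(generator_params, args)
  attr(p, "preset") <- name
  p
}

# exact integral of a 3D Gaussian source over voxel extents, added in place.
# centre/sigma in um; flux is the integrated intensity. Support cut at 4 SD.
render_gaussian_source <- function(arr, center_um, sigma_um, flux,
                                   voxel_size) {
  d <- dim(arr)
  rng <- vector("list", 3)
  frac <- vector("list", 3)
  for (ax in 1:3) {
    dvx <- voxel_size[ax]
    lo <- max(1L, floor((center_um[ax] - 4 * sigma_um[ax]) / dvx) + 1L)
    hi <- min(d[ax], ceiling((center_um[ax] + 4 * sigma_um[ax]) / dvx))
    if (lo > hi) return(arr)
    edges <- (seq.int(lo - 1L, hi)) * dvx
    frac[[ax]] <- diff(stats::pnorm(edges, center_um[ax], sigma_um[ax]))
    rng[[ax]] <- lo:hi
  }
  patch <- flux * (frac[[1]] %o% frac[[2]] %o% frac[[3]])
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + patch
  arr
}

# distance from a point to the nearest face of the image box
min_face_distance <- function(center_um, extent_um) {
  min(c(center_um, extent_um - center_um))
}

# sample mRNA spot positions: proximal spots have distance r ~ Gamma(shape 3,
# scale lambda) truncated at the centre's minimum face distance (so the
# radial law is an analytically known truncated exponential-shell density and
# every proximal spot is in bounds); directions are uniform on the sphere.
sample_spot_positions <- function(n, params) {
  extent <- params$image_shape * params$voxel_size
  n_prox <- round(params$proximal_fraction * n)
  pos <- matrix(0, n, 3)
  if (n_prox > 0) {
    which_cs <- sample.int(params$n_centrosomes, n_prox, replace = TRUE)
    for (i in seq_len(n_prox)) {
      ctr <- params$centrosome_centers[which_cs[i], ]
      r_max <- min_face_distance(ctr, extent)
      repeat {
        r <- stats::rgamma(1, shape = 3, scale = params$proximal_decay_length)
        if (r <= r_max) break
      }
      u <- stats::rnorm(3)
      pos[i, ] <- ctr + r * u / sqrt(sum(u^2))
    }
  }
  if (n > n_prox) {
    m <- n - n_prox
    pos[(n_prox + 1):n, ] <- cbind(stats::runif(m, 0, extent[1]),
                                   stats::runif(m, 0, extent[2]),
                                   stats::runif(m, 0, extent[3]))
  }
  pos
}

apply_noise <- function(ch, noise) {
  if (!isTRUE(noise$enabled)) return(ch)
  d <- dim(ch)
  s <- noise$photon_scaling
  v <- stats::rpois(length(ch), lambda = s * as.vector(ch)) / s
  v <- v + stats::rnorm(length(ch), sd = noise$read_sd)
  v[v < 0] <- 0
  array(v, d)
}

#' Generate one synthetic cell image with ground truth
#'
#' Renders a 4-channel `(mrna, nterm, cterm, reference)` [voxel_image] from
#' [generator_params()]: mRNA spots as PSF-blurred point sources (exact
#' Gaussian integrals over voxel extents, so flux is conserved), PCM blobs as
#' isotropic Gaussians of SD `radius/2` on the reference channel, an
#' N-terminus source colocalised with every translating spot (and no
#' C-terminus source), then per-channel Poisson shot noise and Gaussian read
#' noise on top of a constant camera baseline.
#'
#' @param params A `generator_params` object.
#' @param render If `FALSE`, skip image rendering and return only the ground
#'   truth (fast path for population-level statistical checks).
#' @return A list with elements `image` ([voxel_image] or `NULL`) and `truth`
#'   (list with data frames `spots` — true position, flux, translating flag,
#'   nearest-centrosome id and distance — and `centrosomes`, plus `params`).
#' @export
generate_cell <- function(params, render = TRUE) {
  validate_generator_params(params)
  with_seed(params$seed, {
    extent <- params$image_shape * params$voxel_size
    n <- params$n_spots
    pos <- sample_spot_positions(n, params)
    flux <- if (n > 0) {
      stats::rlnorm(n,
                    meanlog = log(params$spot_intensity) -
                      params$spot_intensity_sdlog^2 / 2,
                    sdlog = params$spot_intensity_sdlog)
    } else numeric(0)
    translating <- rep(FALSE, n)
    n_tr <- round(params$translating_fraction * n)
    if (n_tr > 0) translating[sample.int(n, n_tr)] <- TRUE

    # brute-force nearest-centrosome truth
    if (n > 0) {
      dmat <- vapply(seq_len(params$n_centrosomes), function(j) {
        sqrt(colSums((t(pos) - params$centrosome_centers[j, ])^2))
      }, numeric(n))
      dmat <- matrix(dmat, nrow = n)
      nearest <- max.col(-dmat, ties.method = "first")
      dist_um <- dmat[cbind(seq_len(n), nearest)]
    } else {
      nearest <- integer(0); dist_um <- numeric(0)
    }

    truth <- list(
      spots = data.frame(
        spot_id = seq_len(n),
        z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
        intensity = flux, translating = translating,
        nearest_centrosome = nearest, distance_um = dist_um),
      centrosomes = data.frame(
        centrosome_id = seq_len(params$n_centrosomes),
        z_um = params$centrosome_centers[, 1],
        y_um = params$centrosome_centers[, 2],
        x_um = params$centrosome_centers[, 3],
        radius_um = params$centrosome_radius,
        flux = params$centrosome_amplitude),
      params = params)

    if (!render) return(list(image = NULL, truth = truth))

    shp <- params$image_shape
    zero <- array(0, shp)
    mrna <- zero; nterm <- zero; cterm <- zero + params$cterm_background
    ref <- zero
    for (i in seq_len(n)) {
      mrna <- render_gaussian_source(mrna, pos[i, ], params$psf_sigma,
                                     flux[i], params$voxel_size)
      if (translating[i]) {
        nterm <- render_gaussian_source(nterm, pos[i, ], params$psf_sigma,
                                        params$nterm_spot_amplitude,
                                        params$voxel_size)
      }
    }
    blob_sigma <- rep(params$centrosome_radius / 2, 3)
    for (j in seq_len(params$n_centrosomes)) {
      ref <- render_gaussian_source(ref, params$centrosome_centers[j, ],
                                    blob_sigma, params$centrosome_amplitude,
                                    params$voxel_size)
    }
    base <- params$noise$baseline
    chans <- list(mrna = mrna + base, nterm = nterm + base,
                  cterm = cterm + base, reference = ref + base)
    chans <- lapply(chans, apply_noise, noise = params$noise)
    img <- voxel_image(chans, params$voxel_size)
    list(image = img, truth = truth)
  })
}

#' Generate a population of synthetic cells under one condition
#'
#' Per-cell seeds are drawn deterministically from the master seed, and
#' cell-to-cell variability is applied as multiplicative log-normal jitter
#' (SD `jitter_sdlog` on the log scale) to the spot count, PCM flux and mean
#' spot flux.
#'
#' @param preset Preset name (see [preset_params()]) or a `generator_params`
#'   object.
#' @param n_cells Number of cells (>= 1).
#' @param seed Master integer seed.
#' @param jitter_sdlog Log-SD of the per-cell multiplicative jitter; 0 makes
#'   all cells share identical generating parameters.
#' @param render Passed to [generate_cell()].
#' @param ... Overrides forwarded to [preset_params()] when `preset` is a
#'   name.
#' @return List of `n_cells` results of [generate_cell()].
#' @export
generate_population <- function(preset, n_cells, seed = 1L,
                                jitter_sdlog = 0.15, render = TRUE, ...) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  base <- if (inherits(preset, "generator_params")) preset
          else preset_params(preset, ...)
  with_seed(seed, {
    cell_seeds <- sample.int(.Machine$integer.max, n_cells)
    jit <- matrix(stats::rlnorm(3 * n_cells, 0, jitter_sdlog), ncol = 3)
    lapply(seq_len(n_cells), function(i) {
      p <- base
      p$n_spots <- max(0L, as.integer(round(base$n_spots * jit[i, 1])))
      p$centrosome_amplitude <- base$centrosome_amplitude * jit[i, 2]
      p$spot_intensity <- base$spot_intensity * jit[i, 3]
      p$seed <- cell_seeds[i]
      generate_cell(p, render = render)
    })
  })
}
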