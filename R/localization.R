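#' Assign a spot to its nearest centrosome
#'
#' Euclidean distance in physical units (um) from the spot position to each
#' centrosome's centre of mass; the spot is assigned to the closest one,
#' with ties broken toward the lowest centrosome rank.
#'
#' @param spot Numeric length-3 `(z, y, x)` position in um, or a 1-row data
#'   frame with `z_um, y_um, x_um`.
#' @param centrosomes Data frame with columns `z_um, y_um, x_um` and
#'   optionally `rank` (as from [segment_reference()]); at least one row.
#' @return List with `centrosome` (row index into `centrosomes` after rank
#'   ordering), `rank`, and `distance_um`.
#' @export
nearest_centrosome <- function(spot, centrosomes) {
  a <- assign_spots(if (is.data.frame(spot)) spot else
    data.frame(z_um = spot[1], y_um = spot[2], x_um = spot[3]), centrosomes)
  list(centrosome = a$centrosome[1], rank = a$rank[1],
       distance_um = a$distance_um[1])
}

#' Vectorised nearest-centrosome assignment
#'
#' @param spots Data frame with `z_um, y_um, x_um` (one row per spot).
#' @param centrosomes As in [nearest_centrosome()].
#' @return Data frame with one row per spot: `centrosome`, `rank`,
#'   `distance_um`.
#' @export
assign_spots <- function(spots, centrosomes) {
  if (is.null(centrosomes) || nrow(centrosomes) == 0) {
    stop("at least one centrosome is required for assignment")
  }
  if (!"rank" %in% names(centrosomes)) {
    centrosomes$rank <- seq_len(nrow(centrosomes))
  }
  ord <- order(centrosomes$rank)
  cs <- centrosomes[ord, , drop = FALSE]
  n <- nrow(spots)
  if (n == 0) {
    return(data.frame(centrosome = integer(0), rank = integer(0),
                      distance_um = numeric(0)))
  }
  sp <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  dmat <- vapply(seq_len(nrow(cs)), function(j) {
    sqrt((sp[, 1] - cs$z_um[j])^2 + (sp[, 2] - cs$y_um[j])^2 +
           (sp[, 3] - cs$x_um[j])^2)
  }, numeric(n))
  dmat <- matrix(dmat, nrow = n)
  best <- max.col(-dmat, ties.method = "first")  # first = lowest rank on ties
  data.frame(centrosome = ord[best], rank = cs$rank[best],
             distance_um = dmat[cbind(seq_len(n), best)])
}

#' Per-cell intensity-weighted radial mRNA profile
#'
#' Spots are assigned to their nearest centrosome; bin weight is the sum of
#' spot `intensity` over spots whose distance falls in each half-open bin
#' `[a, a + bin_width)`, normalised by the cell's total spot intensity so the
#' fractions (including the terminal overflow bin collecting distances
#' `>= max_distance`) sum to exactly 1.
#'
#' @param spots Data frame with `z_um, y_um, x_um, intensity`.
#' @param centrosomes Data frame of centrosome centres (see
#'   [assign_spots()]).
#' @param bin_width Bin width in um (default 0.5).
#' @param max_distance Start of the overflow bin in um (default 10).
#' @return Numeric vector of per-bin fractions with names like
#'   `"[0,0.5)"` and a final `"overflow"` element; attributes `bin_edges`
#'   (left edges plus `max_distance`) and `total_intensity`.
#' @export
radial_profile <- function(spots, centrosomes, bin_width = 0.5,
                           max_distance = 10) {
  if (nrow(spots) == 0) stop("no spots to profile")
  total <- sum(spots$intensity)
  if (!is.finite(total) || total <= 0) {
    stop("total spot intensity must be positive")
  }
  d <- assign_spots(spots, centrosomes)$distance_um
  edges <- seq(0, max_distance, by = bin_width)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)  # overflow -> length(edges)
  bin[bin > length(edges) - 1L] <- length(edges)
  w <- vapply(seq_len(length(edges)), function(b) {
    sum(spots$intensity[bin == b])
  }, numeric(1))
  frac <- w / total
  names(frac) <- c(sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
                   "overflow")
  attr(frac, "bin_edges") <- edges
  attr(frac, "total_intensity") <- total
  frac
}

#' Radial profiles for a list of cells
#'
#' @param cells List of cells, each a list with elements `spots` and
#'   `centrosomes` (data frames as in [radial_profile()]).
#' @inheritParams radial_profile
#' @return Matrix (cells x bins) of per-cell fractions with attribute
#'   `bin_edges`; cells without spots or centrosomes are dropped (their ids
#'   are in attribute `excluded`).
#' @export
radial_profiles <- function(cells, bin_width = 0.5, max_distance = 10) {
  rows <- list(); excluded <- integer(0)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    if (is.null(cl$spots) || nrow(cl$spots) == 0 ||
        is.null(cl$centrosomes) || nrow(cl$centrosomes) == 0 ||
        sum(cl$spots$intensity) <= 0) {
      excluded <- c(excluded, i)
      next
    }
    rows[[length(rows) + 1L]] <- radial_profile(cl$spots, cl$centrosomes,
                                                bin_width, max_distance)
  }
  if (length(rows) == 0) stop("no analyzable cells")
  m <- do.call(rbind, rows)
  attr(m, "bin_edges") <- attr(rows[[1]], "bin_edges")
  attr(m, "excluded") <- excluded
  m
}

#' Aggregate per-cell radial profiles across a condition
#'
#' Per-bin unweighted mean across cells with a 95% Student-t confidence
#' interval on the per-cell fractions (n - 1 degrees of freedom). An
#' optional seeded percentile bootstrap across cells is available for
#' comparison.
#'
#' @param profiles Matrix (cells x bins) from [radial_profiles()], or a list
#'   of per-cell profile vectors.
#' @param conf_level Confidence level (default 0.95).
#' @param bootstrap If `TRUE`, also compute percentile-bootstrap intervals.
#' @param n_boot Number of bootstrap resamples.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return An object of class `radial_profile_summary`: list with
#'   `bin_edges`, `mean`, `ci_lo`, `ci_hi`, `n_cells`, `per_cell`, and
#'   (optionally) `boot_lo`, `boot_hi`. With fewer than 2 cells the CI
#'   bounds are `NA` and `ci_available` is `FALSE`.
#' @export
aggregate_profiles <- function(profiles, conf_level = 0.95,
                               bootstrap = FALSE, n_boot = 1e4,
                               boot_seed = 1L) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    profiles <- do.call(rbind, profiles)
  }
  n <- nrow(profiles)
  mu <- colMeans(profiles)
  out <- list(bin_edges = attr(profiles, "bin_edges"), mean = mu,
              n_cells = n, per_cell = profiles,
              ci_available = n >= 2)
  if (n >= 2) {
    se <- apply(profiles, 2, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    out$ci_lo <- mu - tq * se
    out$ci_hi <- mu + tq * se
  } else {
    out$ci_lo <- rep(NA_real_, length(mu))
    out$ci_hi <- rep(NA_real_, length(mu))
  }
  if (bootstrap && n >= 2) {
    qs <- with_seed(boot_seed, {
      bm <- matrix(0, n_boot, ncol(profiles))
      for (b in seq_len(n_boot)) {
        bm[b, ] <- colMeans(profiles[sample.int(n, n, replace = TRUE), ,
                                     drop = FALSE])
      }
      apply(bm, 2, stats::quantile,
            probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    })
    out$boot_lo <- qs[1, ]
    out$boot_hi <- qs[2, ]
  }
  structure(out, class = "radial_profile_summary")
}

#' @export
print.radial_profile_summary <- function(x, ...) {
  cat(sprintf("<radial_profile_summary> %d cells, %d bins\n", x$n_cells,
              length(x$mean)))
  df <- data.frame(bin = names(x$mean), mean = round(x$mean, 4),
                   ci_lo = round(x$ci_lo, 4), ci_hi = round(x$ci_hi, 4))
  print(utils::head(df, 10), row.names = FALSE)
  if (length(x$mean) > 10) cat("  ...\n")
  invisible(x)
}

#' Intensity-weighted fraction of mRNA within a proximity radius
#'
#' @param spots,centrosomes As in [radial_profile()].
#' @param radius_um Proximity radius in um (default 3).
#' @return Scalar fraction in `[0, 1]`.
#' @export
proximal_fraction <- function(spots, centrosomes, radius_um = 3) {
  if (nrow(spots) == 0 || sum(spots$intensity) <= 0) {
    stop("cell has no usable spot intensity")
  }
  d <- assign_spots(spots, centrosomes)$distance_um
  sum(spots$intensity[d < radius_um]) / sum(spots$intensity)
}

#' Compare mRNA dispersal between two conditions
#'
#' The per-cell summary statistic is the intensity-weighted fraction of mRNA
#' within `radius_um` of the nearest centrosome; conditions are compared by
#' a two-sided unpaired t-test (Welch by default) via
#' [compare_conditions()].
#'
#' @param cells_a,cells_b Lists of cells (`spots` + `centrosomes` each), or
#'   numeric vectors of precomputed per-cell proximal fractions.
#' @param radius_um Proximity radius in um (default 3).
#' @param label_a,label_b Condition labels.
#' @param var_equal Use the classic pooled-variance Student t-test instead
#'   of Welch.
#' @return A [compare_conditions()] result with the per-cell fractions
#'   attached.
#' @export
compare_dispersal <- function(cells_a, cells_b, radius_um = 3,
                              label_a = "A", label_b = "B",
                              var_equal = FALSE) {
  get_frac <- function(cells) {
    if (is.numeric(cells)) return(cells)
    vapply(cells, function(cl) {
      proximal_fraction(cl$spots, cl$centrosomes, radius_um)
    }, numeric(1))
  }
  compare_conditions(get_frac(cells_a), get_frac(cells_b),
                     label_a = label_a, label_b = label_b,
                     var_equal = var_equal)
}
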