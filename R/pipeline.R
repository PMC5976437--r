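# End-to-end orchestration: simulate -> detect -> profile -> translation ->
# intensity -> compare, with CSV outputs and JSON provenance.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param conditions Named list; each element is
#'   `list(preset = <preset name or generator_params>, n_cells = <int>)`.
#'   The first condition is the comparison reference unless
#'   `reference_condition` is given.
#' @param seed Master seed; every downstream random draw derives from it.
#' @param reference_condition Condition label used as comparison baseline.
#' @param detection,segmentation,shell Stage configurations
#'   ([detection_config()], [segmentation_config()], [shell_config()]).
#' @param bin_width,max_distance Radial-profile binning (um).
#' @param radius_um Proximity radius for the dispersal statistic (um).
#' @param jitter_sdlog Cell-to-cell jitter passed to
#'   [generate_population()].
#' @param var_equal Use pooled-variance Student's t-tests.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, conditions, seed = 1L,
                       reference_condition = names(conditions)[1],
                       detection = detection_config(),
                       segmentation = segmentation_config(),
                       shell = shell_config(),
                       bin_width = 0.5, max_distance = 10, radius_um = 3,
                       jitter_sdlog = 0.15, var_equal = FALSE) {
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("`conditions` must be a named list")
  }
  if (!reference_condition %in% names(conditions)) {
    stop("reference_condition must be one of the condition labels")
  }
  structure(list(out_dir = out_dir, conditions = conditions, seed = seed,
                 reference_condition = reference_condition,
                 detection = detection, segmentation = segmentation,
                 shell = shell, bin_width = bin_width,
                 max_distance = max_distance, radius_um = radius_um,
                 jitter_sdlog = jitter_sdlog, var_equal = var_equal),
            class = "run_config")
}

# analyse one generated/observed image: spots + centrosomes for a cell
analyze_cell_image <- function(image, detection = detection_config(),
                               segmentation = segmentation_config()) {
  list(spots = detect_spots(image, "mrna", detection),
       centrosomes = segment_reference(image, "reference", segmentation))
}

# tiny polynomial rolling hash of a deparsed object for provenance (no
# digest package installed; double arithmetic stays exact below 2^53)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on simulated populations
#'
#' Generates one cell population per condition, runs spot detection and PCM
#' segmentation on every cell, computes radial profiles, translation calls,
#' shell translation fractions, per-cell centrosomal intensities and mRNA
#' counts, and compares every condition against the reference on the
#' dispersal (proximal-fraction), intensity, count and shell-fraction
#' statistics. All tables are written as CSV under `config$out_dir`
#' together with a JSON provenance record (seed, config hash, package
#' version) and an exclusion log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory tables (`spots`,
#'   `centrosomes`, `profiles`, `profile_summary`, `translation_calls`,
#'   `shell_fractions`, `per_cell_intensity`, `per_cell_counts`,
#'   `comparisons`, `exclusions`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cond_names <- names(config$conditions)
  cond_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max,
                                     length(cond_names)))
  all_spots <- list(); all_cs <- list(); cells_by_cond <- list()
  exclusions <- list()
  for (ci in seq_along(cond_names)) {
    cname <- cond_names[ci]
    spec <- config$conditions[[cname]]
    pop <- generate_population(spec$preset, spec$n_cells,
                               seed = cond_seeds[ci],
                               jitter_sdlog = config$jitter_sdlog)
    cells <- vector("list", length(pop))
    for (k in seq_along(pop)) {
      cell_id <- sprintf("%s_%03d", cname, k)
      res <- analyze_cell_image(pop[[k]]$image, config$detection,
                                config$segmentation)
      if (nrow(res$centrosomes) == 0) {
        exclusions[[length(exclusions) + 1L]] <-
          data.frame(cell_id = cell_id, stage = "segmentation",
                     reason = "no centrosome above threshold")
      }
      if (nrow(res$spots) > 0) {
        all_spots[[length(all_spots) + 1L]] <-
          cbind(cell_id = cell_id, condition = cname, res$spots)
      } else {
        exclusions[[length(exclusions) + 1L]] <-
          data.frame(cell_id = cell_id, stage = "detection",
                     reason = "no spots detected")
      }
      if (nrow(res$centrosomes) > 0) {
        all_cs[[length(all_cs) + 1L]] <-
          cbind(cell_id = cell_id, condition = cname, res$centrosomes)
      }
      res$cell_id <- cell_id
      cells[[k]] <- res
    }
    cells_by_cond[[cname]] <- cells
  }
  spots_df <- do.call(rbind, all_spots)
  cs_df <- do.call(rbind, all_cs)

  analyzable <- function(cl) {
    !is.null(cl$spots) && nrow(cl$spots) > 0 &&
      !is.null(cl$centrosomes) && nrow(cl$centrosomes) > 0
  }

  profiles_rows <- list(); summary_rows <- list(); shell_rows <- list()
  int_rows <- list(); count_rows <- list(); calls_rows <- list()
  per_cond_stats <- list()
  for (cname in cond_names) {
    cells <- cells_by_cond[[cname]]
    ok <- vapply(cells, analyzable, logical(1))
    if (!any(ok)) stop(sprintf("condition '%s' has no analyzable cells",
                               cname))
    usable <- cells[ok]
    prof <- radial_profiles(usable, config$bin_width, config$max_distance)
    for (r in seq_len(nrow(prof))) {
      profiles_rows[[length(profiles_rows) + 1L]] <- data.frame(
        cell_id = usable[[r]]$cell_id, condition = cname,
        bin = colnames(prof), fraction = unname(prof[r, ]))
    }
    agg <- aggregate_profiles(prof)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      condition = cname, bin = names(agg$mean), mean = unname(agg$mean),
      ci_lo = unname(agg$ci_lo), ci_hi = unname(agg$ci_hi),
      n_cells = agg$n_cells)
    pf <- vapply(usable, function(cl) {
      proximal_fraction(cl$spots, cl$centrosomes, config$radius_um)
    }, numeric(1))
    stf <- shell_translation_fraction(usable, config$shell)
    for (ex in stf$excluded) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        cell_id = usable[[ex]]$cell_id, stage = "shell",
        reason = "no shell spots")
    }
    shell_members <- setdiff(seq_along(usable), stf$excluded)
    for (j in seq_along(shell_members)) {
      shell_rows[[length(shell_rows) + 1L]] <- data.frame(
        cell_id = usable[[shell_members[j]]]$cell_id, condition = cname,
        shell_fraction = stf$per_cell[j])
    }
    for (cl in usable) {
      calls <- call_translation(cl$spots, config$shell)
      calls_rows[[length(calls_rows) + 1L]] <- cbind(
        cell_id = cl$cell_id, condition = cname,
        calls[, c("z_um", "y_um", "x_um", "intensity", "nterm_positive",
                  "cterm_positive", "label")])
      int_rows[[length(int_rows) + 1L]] <- data.frame(
        cell_id = cl$cell_id, condition = cname,
        intensity = centrosomal_intensity(cl$centrosomes))
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        cell_id = cl$cell_id, condition = cname,
        mrna_count = mrna_count(cl$spots))
    }
    per_cond_stats[[cname]] <- list(
      proximal = pf, shell = stf$per_cell,
      intensity = vapply(usable, function(cl)
        centrosomal_intensity(cl$centrosomes), numeric(1)),
      count = vapply(usable, function(cl) mrna_count(cl$spots), numeric(1)))
  }

  ref <- config$reference_condition
  comp_rows <- list()
  for (cname in setdiff(cond_names, ref)) {
    for (metric in c("proximal", "intensity", "count", "shell")) {
      va <- per_cond_stats[[cname]][[metric]]
      vb <- per_cond_stats[[ref]][[metric]]
      if (length(va) < 2 || length(vb) < 2) next
      cc <- compare_conditions(va, vb, label_a = cname, label_b = ref,
                               var_equal = config$var_equal)
      comp_rows[[length(comp_rows) + 1L]] <-
        cbind(metric = metric, as.data.frame(cc))
    }
  }

  tables <- list(
    spots = spots_df, centrosomes = cs_df,
    profiles = do.call(rbind, profiles_rows),
    profile_summary = do.call(rbind, summary_rows),
    translation_calls = do.call(rbind, calls_rows),
    shell_fractions = do.call(rbind, shell_rows),
    per_cell_intensity = do.call(rbind, int_rows),
    per_cell_counts = do.call(rbind, count_rows),
    comparisons = if (length(comp_rows)) do.call(rbind, comp_rows) else
      data.frame(),
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(cell_id = character(0), stage = character(0),
                 reason = character(0)))

  paths <- character(0)
  for (nm in names(tables)) {
    f <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    paths[nm] <- f
  }
  prov <- list(
    package = "centrofish",
    version = as.character(utils::packageVersion("centrofish")),
    seed = config$seed,
    config_hash = config_hash(config),
    conditions = lapply(config$conditions, function(s) list(
      preset = if (is.character(s$preset)) s$preset else "custom",
      n_cells = s$n_cells)),
    reference_condition = ref)
  prov_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
  paths["provenance"] <- prov_path
  invisible(c(tables, list(paths = paths)))
}
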