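#' Shell configuration for translation-site statistics
#'
#' The shell is the region close to, but not inside, the centrosome: between
#' `r_inner` (the nominal ~1 um PCM radius) and `r_outer` from the
#' centrosome centre.
#'
#' @param r_inner Inner radius in um (default 1).
#' @param r_outer Outer radius in um (default 3); must exceed `r_inner`.
#' @param probe_radius_um Probe-ball radius for epitope-channel measurement.
#' @param cutoff_mad Positivity cutoff: a channel is called positive when
#'   its background-subtracted local signal exceeds `cutoff_mad` times the
#'   annulus MAD.
#' @return A list of class `shell_config`.
#' @export
shell_config <- function(r_inner = 1, r_outer = 3, probe_radius_um = 0.3,
                         cutoff_mad = 3) {
  if (!(r_inner >= 0 && r_inner < r_outer)) {
    stop("need 0 <= r_inner < r_outer")
  }
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 probe_radius_um = probe_radius_um, cutoff_mad = cutoff_mad),
            class = "shell_config")
}

#' Call the translation status of mRNA spots
#'
#' Implements the epitope logic for nascent-chain detection: a translating
#' mRNA carries nascent polypeptides whose N-terminus is synthesised but
#' whose C-terminus is not, so an actively translated spot is N-terminus
#' positive and C-terminus negative. An N+/C+ spot (mRNA coincident with
#' full-length protein) is labelled `ambiguous`; anything else is
#' `mrna_only`. Positivity of each epitope channel is
#' `signal > cutoff_mad * annulus MAD` using the per-spot local signals
#' measured by [measure_channel_at_spot()] (columns `nterm_signal`,
#' `nterm_mad`, `cterm_signal`, `cterm_mad` from [detect_spots()]).
#'
#' @param spots Data frame of spots carrying the four signal columns.
#' @param shell A [shell_config()] (supplies `cutoff_mad`).
#' @param exclude_ambiguous If `TRUE`, N+/C+ spots get label `NA` instead of
#'   `ambiguous` (excluded downstream).
#' @return `spots` with added logical columns `nterm_positive`,
#'   `cterm_positive` and a `label` column in
#'   `{"translating", "mrna_only", "ambiguous"}`.
#' @export
call_translation <- function(spots, shell = shell_config(),
                             exclude_ambiguous = FALSE) {
  need <- c("nterm_signal", "nterm_mad", "cterm_signal", "cterm_mad")
  if (!all(need %in% names(spots))) {
    stop("spots must carry measured channel signals: ",
         paste(setdiff(need, names(spots)), collapse = ", "))
  }
  np <- spots$nterm_signal > shell$cutoff_mad * spots$nterm_mad
  cp <- spots$cterm_signal > shell$cutoff_mad * spots$cterm_mad
  label <- ifelse(np & !cp, "translating",
                  ifelse(np & cp, "ambiguous", "mrna_only"))
  if (exclude_ambiguous) label[label == "ambiguous"] <- NA_character_
  spots$nterm_positive <- np
  spots$cterm_positive <- cp
  spots$label <- label
  spots
}

#' Shell-restricted translation fraction per cell
#'
#' For each cell, restricts spots to the shell (nearest-centrosome distance
#' in `[r_inner, r_outer)`) and computes the fraction of shell mRNA that is
#' N-terminus positive — intensity-weighted by default, count-based via
#' `weighting = "count"`. Cells with no shell spots are excluded and listed
#' in the `excluded` attribute. The summary is the mean with a 95% Student-t
#' CI across cells.
#'
#' @param cells List of cells, each with `spots` (including signal columns)
#'   and `centrosomes`.
#' @param shell A [shell_config()].
#' @param weighting `"intensity"` (default) or `"count"`.
#' @param exclude_ambiguous Drop N+/C+ spots from the denominator.
#' @return List with `per_cell` (numeric vector of per-cell fractions),
#'   `mean`, `ci_lo`, `ci_hi`, `n_cells`, and attribute-like field
#'   `excluded` (indices of cells with no shell spots).
#' @export
shell_translation_fraction <- function(cells, shell = shell_config(),
                                       weighting = c("intensity", "count"),
                                       exclude_ambiguous = FALSE) {
  weighting <- match.arg(weighting)
  fr <- numeric(0); excluded <- integer(0)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    if (is.null(cl$spots) || nrow(cl$spots) == 0 ||
        is.null(cl$centrosomes) || nrow(cl$centrosomes) == 0) {
      excluded <- c(excluded, i); next
    }
    sp <- call_translation(cl$spots, shell,
                           exclude_ambiguous = exclude_ambiguous)
    d <- assign_spots(sp, cl$centrosomes)$distance_um
    member <- d >= shell$r_inner & d < shell$r_outer & !is.na(sp$label)
    if (!any(member)) { excluded <- c(excluded, i); next }
    w <- if (weighting == "intensity") sp$intensity[member]
         else rep(1, sum(member))
    if (sum(w) <= 0) { excluded <- c(excluded, i); next }
    fr <- c(fr, sum(w[sp$nterm_positive[member]]) / sum(w))
  }
  n <- length(fr)
  if (n == 0) stop("no cells with shell spots")
  out <- list(per_cell = fr, mean = mean(fr), n_cells = n,
              excluded = excluded)
  if (n >= 2) {
    se <- stats::sd(fr) / sqrt(n)
    tq <- stats::qt(0.975, df = n - 1)
    out$ci_lo <- out$mean - tq * se
    out$ci_hi <- out$mean + tq * se
  } else {
    out$ci_lo <- NA_real_; out$ci_hi <- NA_real_
  }
  out
}

#' Translational kinetics parameters
#'
#' Defaults are the human pericentrin numbers: a ~10 knt transcript, a
#' 3336-amino-acid coding sequence, ~260 nt between adjacent ribosomes on a
#' translated mRNA, and an elongation rate of 3-10 amino acids per second
#' (slow default 3).
#'
#' @param transcript_length_nt Transcript length in nucleotides.
#' @param cds_length_aa Coding-sequence length in amino acids.
#' @param inter_ribosome_spacing_nt Inter-ribosome spacing in nucleotides.
#' @param elongation_rate_aa_per_s Elongation rate, amino acids per second.
#' @return A list of class `kinetics_params`.
#' @export
kinetics_params <- function(transcript_length_nt = 10000,
                            cds_length_aa = 3336,
                            inter_ribosome_spacing_nt = 260,
                            elongation_rate_aa_per_s = 3) {
  if (transcript_length_nt <= 0 || inter_ribosome_spacing_nt <= 0 ||
      elongation_rate_aa_per_s <= 0 || cds_length_aa < 0) {
    stop("kinetics parameters must be positive (cds length may be 0)")
  }
  structure(list(transcript_length_nt = transcript_length_nt,
                 cds_length_aa = cds_length_aa,
                 inter_ribosome_spacing_nt = inter_ribosome_spacing_nt,
                 elongation_rate_aa_per_s = elongation_rate_aa_per_s),
            class = "kinetics_params")
}

#' Maximum simultaneous ribosome occupancy of a transcript
#'
#' `floor(transcript_length_nt / inter_ribosome_spacing_nt)`: the number of
#' ribosomes that fit on the transcript at the characteristic spacing. For
#' a 10 knt transcript at 260 nt spacing this is 38 ribosomes.
#'
#' @param params A [kinetics_params()] object (or transcript length when
#'   `spacing` is given).
#' @param spacing Optional spacing override (nt) when `params` is a bare
#'   transcript length.
#' @return Integer ribosome count.
#' @export
ribosome_capacity <- function(params, spacing = NULL) {
  if (!inherits(params, "kinetics_params")) {
    params <- kinetics_params(transcript_length_nt = params,
                              inter_ribosome_spacing_nt = spacing)
  }
  as.integer(floor(params$transcript_length_nt /
                     params$inter_ribosome_spacing_nt))
}

#' Time to synthesise one full-length protein
#'
#' `cds_length_aa / elongation_rate_aa_per_s` seconds after initiation. For
#' 3336 aa at 3 aa/s this is 1112 s (~18.5 min); at 10 aa/s, 333.6 s.
#'
#' @param params A [kinetics_params()] object (or CDS length in aa when
#'   `rate` is given).
#' @param rate Optional elongation rate override (aa/s).
#' @return Time in seconds.
#' @export
synthesis_time <- function(params, rate = NULL) {
  if (!inherits(params, "kinetics_params")) {
    params <- kinetics_params(cds_length_aa = params,
                              elongation_rate_aa_per_s = rate)
  }
  params$cds_length_aa / params$elongation_rate_aa_per_s
}
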