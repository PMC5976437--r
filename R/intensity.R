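#' Per-cell summed centrosomal intensity
#'
#' The centrosomal protein level of a cell is the sum of `sum_intensity`
#' over its centrosome records (both spindle poles of a mitotic cell).
#'
#' @param centrosomes Data frame of centrosome records for one cell (as from
#'   [segment_reference()]); must have at least one row.
#' @return Scalar summed intensity (a.u.).
#' @export
centrosomal_intensity <- function(centrosomes) {
  if (is.null(centrosomes) || nrow(centrosomes) == 0) {
    stop("cell has no centrosome record; exclude it from intensity analysis")
  }
  sum(centrosomes$sum_intensity)
}

#' Per-cell mRNA count
#'
#' Counts detected spots. With `method = "intensity"` an
#' intensity-deconvolved estimate is returned instead:
#' `round(total intensity / median single-spot intensity)`, which corrects
#' for unresolved multi-transcript spots.
#'
#' @param spots Data frame of detected spots for one cell.
#' @param method `"count"` (default) or `"intensity"`.
#' @return Integer count (0 for an empty cell).
#' @export
mrna_count <- function(spots, method = c("count", "intensity")) {
  method <- match.arg(method)
  if (is.null(spots) || nrow(spots) == 0) return(0L)
  if (method == "count") return(nrow(spots))
  as.integer(round(sum(spots$intensity) /
                     stats::median(spots$intensity)))
}

#' Compare a per-cell statistic between two conditions
#'
#' Two-sided unpaired t-test (Welch by default; `var_equal = TRUE` restores
#' the classic pooled-variance Student's t-test), with fold change and
#' percent change of the condition means and a t-based confidence interval
#' on the mean difference `mean_a - mean_b`.
#'
#' @param values_a,values_b Numeric vectors of per-cell statistics (length
#'   >= 2 each).
#' @param label_a,label_b Condition labels.
#' @param var_equal Pooled-variance Student's t-test instead of Welch.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `condition_comparison`: list with `label_a`,
#'   `label_b`, `values_a`, `values_b`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `mean_diff`, `fold_change` (`mean_a / mean_b`), `percent_change`
#'   (`100 * (mean_a - mean_b) / mean_b`), `t`, `df`, `p_value`, `ci_lo`,
#'   `ci_hi`, `degenerate` (TRUE when both groups have zero variance, in
#'   which case `t = 0`, `p = 1` for equal means and `p = 0` otherwise).
#' @export
compare_conditions <- function(values_a, values_b, label_a = "A",
                               label_b = "B", var_equal = FALSE,
                               conf_level = 0.95) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each condition needs at least 2 cells")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (degenerate) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = if (isTRUE(all.equal(ma, mb))) 1 else 0,
               conf.int = c(ma - mb, ma - mb))
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = var_equal,
                        conf.level = conf_level)
  }
  structure(list(
    label_a = label_a, label_b = label_b,
    values_a = values_a, values_b = values_b,
    n_a = length(values_a), n_b = length(values_b),
    mean_a = ma, mean_b = mb, mean_diff = ma - mb,
    fold_change = ma / mb,
    percent_change = 100 * (ma - mb) / mb,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
    conf_level = conf_level, var_equal = var_equal,
    degenerate = degenerate), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s (n=%d) vs %s (n=%d)\n",
              x$label_a, x$n_a, x$label_b, x$n_b))
  cat(sprintf("  means: %.4g vs %.4g  (fold change %.3f, %+.1f%%)\n",
              x$mean_a, x$mean_b, x$fold_change, x$percent_change))
  cat(sprintf("  %s t = %.3f, p = %.3g, %d%% CI of difference [%.4g, %.4g]%s\n",
              if (x$var_equal) "Student" else "Welch", x$t, x$p_value,
              round(100 * x$conf_level), x$ci_lo, x$ci_hi,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' @export
as.data.frame.condition_comparison <- function(x, ...) {
  data.frame(condition_a = x$label_a, condition_b = x$label_b,
             n_a = x$n_a, n_b = x$n_b, mean_a = x$mean_a, mean_b = x$mean_b,
             mean_diff = x$mean_diff, fold_change = x$fold_change,
             percent_change = x$percent_change, t = x$t, df = x$df,
             p = x$p_value, ci_lo = x$ci_lo, ci_hi = x$ci_hi)
}
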