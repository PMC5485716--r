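#' Paired measured/simulated FFR values
#'
#' @param case_ids Vector of case labels.
#' @param m_ffr Clinically measured FFR values (pressure-wire reference).
#' @param sim_ffr Simulated FFR values, same length.
#' @return An object of class `paired_ffr`.
#' @export
paired_ffr <- function(case_ids, m_ffr, sim_ffr) {
  n <- length(m_ffr)
  if (length(sim_ffr) != n || length(case_ids) != n)
    octffr_error("case_ids, m_ffr and sim_ffr must have equal length",
                 "invalid_input")
  if (n < 2)
    octffr_error("need at least 2 pairs", "insufficient_data")
  if (any(!is.finite(m_ffr)) || any(!is.finite(sim_ffr)))
    octffr_error("missing or non-finite FFR values", "invalid_input")
  if (any(m_ffr <= 0) || any(m_ffr > 1.5) || any(sim_ffr <= 0) ||
      any(sim_ffr > 1.5))
    octffr_error("FFR values must lie in (0, 1.5]", "invalid_input")
  structure(list(case_ids = case_ids, m_ffr = as.numeric(m_ffr),
                 sim_ffr = as.numeric(sim_ffr)),
            class = "paired_ffr")
}

#' Read measured/simulated pairs from CSV
#'
#' Columns `case_id, m_ffr, oct_ffr`.
#'
#' @param path CSV path.
#' @return A [paired_ffr()] object.
#' @export
read_pairs <- function(path) {
  d <- utils::read.csv(path)
  paired_ffr(d$case_id, d$m_ffr, d$oct_ffr)
}

#' Bland-Altman agreement of simulated against measured FFR
#'
#' Differences are `sim - measured`; `bias` is their mean, `sd` the
#' sample standard deviation (n-1 denominator), and the 95% limits of
#' agreement are `bias -/+ 1.96 sd`.
#'
#' @param pairs A [paired_ffr()] object.
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_ffr"))
  d <- pairs$sim_ffr - pairs$m_ffr
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s, n = length(d))
}

#' Correlation statistics between measured and simulated FFR
#'
#' Pearson product-moment correlation, Spearman rank correlation
#' (mid-ranks for ties), and the coefficient of determination of the
#' least-squares line of simulated on measured. For a simple linear fit
#' the regression R^2 equals the squared Pearson coefficient; both are
#' returned.
#'
#' @param pairs A [paired_ffr()] object.
#' @return List with `pearson`, `spearman`, `r2` (regression-based),
#'   `r2_pearson` (squared Pearson).
#' @export
correlation_stats <- function(pairs) {
  stopifnot(inherits(pairs, "paired_ffr"))
  if (length(pairs$m_ffr) < 3)
    octffr_error("need at least 3 pairs for correlations",
                 "insufficient_data")
  if (stats::sd(pairs$m_ffr) == 0 || stats::sd(pairs$sim_ffr) == 0)
    octffr_error("correlation undefined for a constant vector",
                 "undefined_correlation")
  pearson <- stats::cor(pairs$m_ffr, pairs$sim_ffr)
  spearman <- stats::cor(pairs$m_ffr, pairs$sim_ffr, method = "spearman")
  fit <- stats::lm(pairs$sim_ffr ~ pairs$m_ffr)
  list(pearson = pearson, spearman = spearman,
       r2 = summary(fit)$r.squared, r2_pearson = pearson^2)
}

#' Diagnostic confusion at the clinical FFR cutoff
#'
#' A vessel is "positive" (hemodynamically significant) when its FFR is at
#' or below the cutoff (default 0.8; `boundary = "negative"` switches to a
#' strict `<` convention). Counts are relative to the measured value as
#' ground truth.
#'
#' @param pairs A [paired_ffr()] object.
#' @param cutoff FFR cutoff in (0, 1); default 0.8.
#' @param boundary Whether a value exactly at the cutoff counts as
#'   `"positive"` (default) or `"negative"`.
#' @return Named list `tp`, `tn`, `fp`, `fn`.
#' @export
diagnostic_confusion <- function(pairs, cutoff = 0.8,
                                 boundary = c("positive", "negative")) {
  stopifnot(inherits(pairs, "paired_ffr"))
  boundary <- match.arg(boundary)
  if (cutoff <= 0 || cutoff >= 1)
    octffr_error("cutoff must lie in (0, 1)", "invalid_input")
  pos <- function(x) if (boundary == "positive") x <= cutoff else x < cutoff
  mp <- pos(pairs$m_ffr); sp <- pos(pairs$sim_ffr)
  list(tp = sum(mp & sp), tn = sum(!mp & !sp),
       fp = sum(!mp & sp), fn = sum(mp & !sp))
}

#' Full method-agreement report
#'
#' Combines [bland_altman()], [correlation_stats()] and
#' [diagnostic_confusion()] into one object suitable for JSON export.
#'
#' @inheritParams diagnostic_confusion
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, cutoff = 0.8,
                             boundary = c("positive", "negative")) {
  boundary <- match.arg(boundary)
  ba <- bland_altman(pairs)
  cs <- correlation_stats(pairs)
  cf <- diagnostic_confusion(pairs, cutoff, boundary)
  structure(c(ba, cs, list(confusion = cf, cutoff = cutoff,
                           boundary = boundary)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs (sim - measured):\n", x$n))
  cat(sprintf("  bias %.3f, SD %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$bias, x$sd, x$loa_low, x$loa_high))
  cat(sprintf("  Pearson %.2f, Spearman %.2f, R^2 %.2f\n",
              x$pearson, x$spearman, x$r2))
  cat(sprintf("  cutoff %.2f: TP %d, TN %d, FP %d, FN %d\n",
              x$cutoff, x$confusion$tp, x$confusion$tn, x$confusion$fp,
              x$confusion$fn))
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param report An [agreement_report()].
#' @param path Output path.
#' @export
write_agreement_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
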