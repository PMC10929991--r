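#' Percentage differences between two paired series
#'
#' Per pair, `(a_i - b_i) / b_i * 100`, with `b` the reference series. The
#' "largest" difference is the one of maximum absolute value, sign
#' preserved.
#'
#' @param a Numeric vector (comparison series).
#' @param b Numeric vector (reference series), same length, no zeros.
#' @return A list with `per_pair`, `mean_pct` and `largest_pct`.
#' @export
percent_difference <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop("a and b must have equal length >= 1")
  }
  if (any(b == 0)) stop("reference series contains zeros")
  pct <- (a - b) / b * 100
  list(per_pair = pct,
       mean_pct = mean(pct),
       largest_pct = pct[which.max(abs(pct))])
}

#' Agreement analysis between two SSDE series
#'
#' Ordinary least squares of `a` on `b` (slope, intercept, R^2), Pearson
#' correlation, signed percentage differences, and Bland-Altman bias and
#' 95% limits of agreement (`bias +/- 1.96 * SD` of the pairwise
#' differences, sample SD).
#'
#' @param a Numeric vector (e.g. automated SSDE).
#' @param b Numeric vector (reference SSDE), same length >= 3.
#' @return A list of class `agreement_report` with `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `mean_pct_diff`, `largest_pct_diff`, `bias`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
agreement_analysis <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("a and b must have equal length >= 3")
  }
  if (stats::sd(b) == 0) stop("reference series has zero variance")
  fit <- stats::lm(a ~ b)
  co <- stats::coef(fit)
  r <- stats::cor(a, b)
  tss <- sum((a - mean(a))^2)
  rsq <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  pct <- percent_difference(a, b)
  d <- a - b
  bias <- mean(d)
  half <- 1.96 * stats::sd(d)
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    r_squared = rsq, pearson_r = r,
    mean_pct_diff = pct$mean_pct, largest_pct_diff = pct$largest_pct,
    bias = bias, loa_low = bias - half, loa_high = bias + half,
    n = length(a)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  regression : slope %.3f, intercept %.3f, R^2 %.3f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  Pearson r  : %.3f\n", x$pearson_r))
  cat(sprintf("  %% diff     : mean %+.1f%%, largest %+.1f%%\n",
              x$mean_pct_diff, x$largest_pct_diff))
  cat(sprintf("  Bland-Altman: bias %+.3f, LoA [%+.3f, %+.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

agreement_row <- function(label, rep) {
  data.frame(comparison = label, n = rep$n, slope = rep$slope,
             intercept = rep$intercept, r_squared = rep$r_squared,
             pearson_r = rep$pearson_r, mean_pct_diff = rep$mean_pct_diff,
             largest_pct_diff = rep$largest_pct_diff, bias = rep$bias,
             loa_low = rep$loa_low, loa_high = rep$loa_high,
             stringsAsFactors = FALSE)
}

#' Method-agreement table for SSDE reports
#'
#' Builds the standard three-way comparison between SSDE variants from one
#' or two per-slice reports: within the primary report, the corrected
#' effective diameter SSDE against the water-equivalent diameter SSDE; and
#' when a second (reference) report over the same slices is given, the two
#' reports' corrected-diameter SSDEs and the primary corrected-diameter
#' SSDE against the reference water-equivalent SSDE.
#'
#' @param report Data.frame from [read_report()] (or [report_table()]).
#' @param reference Optional second report over the same slice ids (e.g.
#'   another segmenter).
#' @return A data.frame, one row per comparison, with regression, Pearson,
#'   percentage-difference and Bland-Altman columns.
#' @export
validate_reports <- function(report, reference = NULL) {
  keep <- is.finite(report$ssde_deff) & is.finite(report$ssde_dw)
  rep1 <- report[keep, ]
  if (nrow(rep1) < 3) stop("need >= 3 slices with both SSDE values")
  rows <- list(agreement_row("ssde_deff_vs_ssde_dw",
                             agreement_analysis(rep1$ssde_deff, rep1$ssde_dw)))
  if (!is.null(reference)) {
    m <- merge(rep1, reference, by = "id", suffixes = c("", "_ref"))
    if (nrow(m) < 3) stop("fewer than 3 shared slice ids with the reference")
    rows <- c(rows, list(
      agreement_row("ssde_deff_vs_reference_deff",
                    agreement_analysis(m$ssde_deff, m$ssde_deff_ref)),
      agreement_row("ssde_deff_vs_reference_dw",
                    agreement_analysis(m$ssde_deff, m$ssde_dw_ref))
    ))
  }
  do.call(rbind, rows)
}
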