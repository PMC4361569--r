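#' Genotype-guided dose table
#'
#' Translates fitted metabolic activities into per-genotype dose
#' adjustments under the proportionality rule dose ∝ MR: the adjusted dose
#' is the base dose scaled by the genotype's activity in percent of the
#' homozygous wild type. By default the normalisation uses the
#' model-estimated \*1/\*1 MR (2 beta_1); `normalize = "measured"` instead
#' uses the measured \*1/\*1 group mean, which is how the measured
#' percent-of-wild-type column of a genotype table is defined. Each row also
#' carries the within-genotype coefficient of variation of measured MR,
#' cv = 100 sd/mean, and the dose-scale interval spanned by
#' mean ± k·sd (see [dose_interval()]).
#'
#' @param fit an additive `"allele_fit"`.
#' @param summaries per-genotype summary `data.frame` matching the fit.
#' @param base_dose dose for the homozygous wild type (default 8.75, mg).
#' @param k half-width of the variability interval in SD units (default 1).
#' @param normalize `"model"` (default) or `"measured"` wild-type MR as the
#'   100% reference for the dose columns.
#' @return A `data.frame` of class `"dose_table"`: `genotype`, `n`,
#'   `mean_mr`, `sd_mr`, `cv_pct`, `measured_pct`, `estimate`, `se`,
#'   `percent_wt`, `adjusted_dose`, `interval_lo_pct`, `interval_hi_pct`.
#' @examples
#' fit <- fit_from_summary(reference_summary())
#' dose_table(fit, reference_summary())
#' @export
dose_table <- function(fit, summaries, base_dose = 8.75, k = 1,
                       normalize = c("model", "measured")) {
  normalize <- match.arg(normalize)
  est <- genotype_estimates(fit, summaries$genotype)
  if (!"*1/*1" %in% summaries$genotype) {
    stop("cannot normalize: no *1/*1 group in summaries", call. = FALSE)
  }
  wt_measured <- summaries$mean_mr[summaries$genotype == "*1/*1"]
  wt_model <- est$estimate[est$genotype == "*1/*1"]
  wt <- if (normalize == "model") wt_model else wt_measured
  pct <- 100 * est$estimate / wt
  iv <- t(mapply(dose_interval, summaries$mean_mr, summaries$sd_mr,
                 MoreArgs = list(wildtype_estimate = wt, k = k)))
  out <- data.frame(genotype = summaries$genotype,
                    n = summaries$n,
                    mean_mr = summaries$mean_mr,
                    sd_mr = summaries$sd_mr,
                    cv_pct = 100 * summaries$sd_mr / summaries$mean_mr,
                    measured_pct = 100 * summaries$mean_mr / wt_measured,
                    estimate = est$estimate,
                    se = est$se,
                    percent_wt = pct,
                    adjusted_dose = base_dose * pct / 100,
                    interval_lo_pct = iv[, 1],
                    interval_hi_pct = iv[, 2],
                    stringsAsFactors = FALSE)
  # sd = 0 is a real (degenerate) CV of 0; only missing sd gives NA
  out$cv_pct[is.na(summaries$sd_mr)] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("dose_table", "data.frame")
  attr(out, "base_dose") <- base_dose
  attr(out, "k") <- k
  attr(out, "normalize") <- normalize
  out
}

#' @export
print.dose_table <- function(x, ...) {
  cat("Genotype-guided dose adjustment (dose proportional to MR;",
      "base dose", attr(x, "base_dose"), "for *1/*1;",
      attr(x, "normalize"), "wild-type reference)\n\n")
  df <- data.frame(genotype = x$genotype, n = x$n,
                   `measured MR` = sprintf("%.3f +/- %s", x$mean_mr,
                                           ifelse(is.na(x$sd_mr), "--",
                                                  sprintf("%.3f", x$sd_mr))),
                   `CV%` = ifelse(is.na(x$cv_pct), "--",
                                  sprintf("%.0f", x$cv_pct)),
                   `estimated MR` = sprintf("%.3f +/- %.3f", x$estimate, x$se),
                   `% wild type` = sprintf("%.0f", x$percent_wt),
                   dose = sprintf("%.2f", x$adjusted_dose),
                   `+/-1SD dose range %` =
                     ifelse(is.na(x$interval_lo_pct), "--",
                            sprintf("%.0f-%.0f", x$interval_lo_pct,
                                    x$interval_hi_pct)),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Dose-scale variability interval for one genotype
#'
#' Translates the within-genotype spread of measured MR onto the dose
#' scale: the interval 100 (mean ± k·sd)/wildtype_estimate percent, floored
#' at 0. With k = 1 and a normal MR distribution, about one in three
#' individuals has an optimum dose outside this range.
#'
#' @param mean_mr,sd_mr group mean and SD of measured MR (`sd_mr = NA` for
#'   a singleton group gives an `NA` interval).
#' @param wildtype_estimate MR taken as the 100%-dose reference.
#' @param k half-width in SD units.
#' @return Numeric `c(lo, hi)` in percent of the wild-type dose.
#' @examples
#' dose_interval(1.005, 0.202, 1.192)  # approximately 67-101%
#' @export
dose_interval <- function(mean_mr, sd_mr, wildtype_estimate, k = 1) {
  if (wildtype_estimate <= 0) stop("wildtype_estimate must be > 0",
                                   call. = FALSE)
  if (is.na(sd_mr)) return(c(lo = NA_real_, hi = NA_real_))
  lo <- max(0, 100 * (mean_mr - k * sd_mr) / wildtype_estimate)
  hi <- 100 * (mean_mr + k * sd_mr) / wildtype_estimate
  c(lo = lo, hi = hi)
}

#' Fraction of individuals off their optimum dose
#'
#' Under a normal distribution of individual optimum doses around the
#' genotype mean with relative SD `cv`, the probability that an individual
#' deviates by more than `delta` (relative) is 2 Phi(-delta/cv). With
#' cv = 0.20 and delta = 0.20 this is 2 Phi(-1) = 0.317 — about one in
#' three individuals more than 20% off the genotype-average optimum.
#'
#' @param cv coefficient of variation as a fraction (> 0).
#' @param delta relative deviation threshold (>= 0).
#' @return A `data.frame` with `cv`, `delta`, `probability` and `one_in_n`
#'   (rounded reciprocal, half away from zero). Vectorised over both
#'   arguments.
#' @examples
#' fraction_outside(0.20, c(0.20, 0.40))
#' @export
fraction_outside <- function(cv, delta) {
  if (any(cv <= 0)) stop("cv must be > 0", call. = FALSE)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  p <- 2 * stats::pnorm(-delta / cv)
  data.frame(cv = rep_len(cv, length(p)), delta = rep_len(delta, length(p)),
             probability = p,
             one_in_n = floor(1 / p + 0.5))
}

#' Dose recommendation for one genotype
#'
#' Base dose scaled by the genotype's model-estimated activity in percent
#' of homozygous wild type (full precision; display rounding is up to the
#' caller). Scales linearly with the base dose.
#'
#' @param fit an additive `"allele_fit"`.
#' @param genotype genotype label(s).
#' @param base_dose dose for \*1/\*1 (default 8.75 mg).
#' @return Named numeric vector of adjusted doses.
#' @examples
#' dose_recommendation(fit_from_summary(reference_summary()), "*2/*3", 100)
#' @export
dose_recommendation <- function(fit, genotype, base_dose = 8.75) {
  est <- genotype_estimates(fit, genotype)
  stats::setNames(base_dose * est$percent_wt / 100, est$genotype)
}
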