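#' Run the full genotype-phenotype analysis
#'
#' Composes the whole pipeline on a cohort (individual records) or on a
#' per-genotype summary table: frequency accounting, per-genotype
#' descriptives, the zero-intercept additive allele fit plus its
#' interaction variants and nested F-tests, the response-transformation
#' comparison (records only), Welch ANOVA and Tamhane T2 across
#' multi-subject genotypes, outlier and covariate screens (records only),
#' the dose-adjustment table and the normal-theory variability assessment.
#' Deterministic: every number in the report is a function of the input and
#' the configuration alone.
#'
#' @param records cohort `data.frame` (e.g. from [read_cohort()] or
#'   [simulate_cohort()]); `NULL` when fitting from a summary.
#' @param summaries per-genotype summary; computed from `records` when
#'   omitted.
#' @param base_dose wild-type dose (default 8.75 mg).
#' @param k SD multiple for dose intervals (default 1).
#' @param alpha significance level (default 0.05).
#' @param delta relative dose deviations assessed by the variability
#'   analysis (default 0.2 and 0.4).
#' @param outlier_k SD multiple for the outlier screen (default 3).
#' @param covariates covariate column names to screen; default: every
#'   column beyond the core ones.
#' @return A list of class `"mr_report"`; see the print method for the
#'   blocks.
#' @examples
#' rep <- run_full_analysis(summaries = reference_summary())
#' print(rep)
#' @export
run_full_analysis <- function(records = NULL, summaries = NULL,
                              base_dose = 8.75, k = 1, alpha = 0.05,
                              delta = c(0.2, 0.4), outlier_k = 3,
                              covariates = NULL) {
  if (is.null(records) && is.null(summaries)) {
    stop("supply records and/or summaries", call. = FALSE)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(summaries)) {
    summaries <- stage("cohort_io", summarize_cohort(records))
  }
  freqs <- stage("genotype_stats", allele_frequencies(summaries))
  welch <- stage("genotype_stats", welch_anova(summaries, quiet = TRUE))
  tamhane <- stage("genotype_stats",
                   tamhane_t2(summaries, family_alpha = alpha, quiet = TRUE))

  if (!is.null(records)) {
    fit <- stage("allele_model", allele_fit(records))
    fit_hom <- stage("allele_model",
                     allele_fit(records, variant = "homozygous"))
    fit_gen <- stage("allele_model", allele_fit(records, variant = "genotype"))
    transforms <- stage("allele_model", compare_transformations(records))
    outliers <- stage("genotype_stats", flag_outliers(records, k = outlier_k))
    if (is.null(covariates)) {
      covariates <- setdiff(names(records),
                            c("subject_id", "genotype", "mr",
                              "flb_conc", "ohf_conc"))
    }
    screens <- do.call(rbind, lapply(covariates, function(cc) {
      stage("genotype_stats", covariate_screen(records, cc, alpha = alpha))
    }))
  } else {
    fit <- stage("allele_model", fit_from_summary(summaries))
    fit_hom <- stage("allele_model",
                     fit_from_summary(summaries, variant = "homozygous"))
    fit_gen <- stage("allele_model",
                     fit_from_summary(summaries, variant = "genotype"))
    transforms <- NULL
    outliers <- NULL
    screens <- NULL
  }
  model_comparison <- list(
    homozygous = stage("allele_model", anova.allele_fit(fit, fit_hom)),
    genotype = stage("allele_model", anova.allele_fit(fit, fit_gen)))
  estimates <- stage("allele_model", genotype_estimates(fit))
  dose <- stage("dose_adjust", dose_table(fit, summaries,
                                          base_dose = base_dose, k = k))
  cv_obs <- summaries$sd_mr / summaries$mean_mr
  variability <- stage("dose_adjust",
    do.call(rbind, lapply(delta, function(d) {
      fraction_outside(cv = stats::na.omit(cv_obs), delta = d)
    })))
  variability$genotype <- rep(summaries$genotype[!is.na(cv_obs)],
                              times = length(delta))

  out <- list(summaries = summaries, frequencies = freqs, fit = fit,
              estimates = estimates, model_comparison = model_comparison,
              transformations = transforms, welch = welch, tamhane = tamhane,
              dose = dose, variability = variability, outliers = outliers,
              covariate_screens = screens,
              config = list(base_dose = base_dose, k = k, alpha = alpha,
                            delta = delta, outlier_k = outlier_k,
                            n_subjects = sum(summaries$n),
                            from = if (is.null(records)) "summary"
                                   else "records"))
  class(out) <- "mr_report"
  out
}

#' @export
print.mr_report <- function(x, ...) {
  cat("==== CYP2C9 genotype-phenotype analysis ====\n")
  cat("Input:", x$config$from, "|", x$config$n_subjects, "subjects\n\n")
  print(x$frequencies)
  cat("\n---- Zero-intercept additive allele fit ----\n")
  print(summary(x$fit))
  cat("\n---- Genotype-level estimates ----\n")
  est <- x$estimates
  est$estimate <- round(est$estimate, 3)
  est$se <- round(est$se, 3)
  est$percent_wt <- round(est$percent_wt)
  print(est, row.names = FALSE)
  cat("\n---- Interaction variants vs additive ----\n")
  print(x$model_comparison$homozygous)
  print(x$model_comparison$genotype)
  if (!is.null(x$transformations)) {
    cat("\n")
    print(x$transformations)
  }
  cat("\n---- Group comparison ----\n")
  print(x$welch)
  print(x$tamhane)
  cat("\n---- Dose adjustment ----\n")
  print(x$dose)
  cat("\n---- Variability vs genotype-only dosing ----\n")
  v <- x$variability
  v$probability <- round(v$probability, 4)
  print(v, row.names = FALSE)
  if (!is.null(x$outliers) && any(x$outliers$flagged)) {
    cat("\n---- Outliers (> ", x$config$outlier_k, " SD) ----\n", sep = "")
    print(x$outliers[x$outliers$flagged, ], row.names = FALSE)
  }
  if (!is.null(x$covariate_screens)) {
    cat("\n---- Covariate screens (Welch t) ----\n")
    cs <- x$covariate_screens
    cs$p <- format.pval(cs$p, digits = 3, eps = 1e-15)
    print(cs, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Serialises an `"mr_report"` either as a directory of delimited tables
#' (`format = "tsv"`) or as one flat JSON file (`format = "json"`)
#' containing coefficients, covariance, df, RSS, per-genotype estimates and
#' all test results. Rounding happens only here, at the presentation layer
#' (and only in the TSV tables; JSON keeps full precision).
#'
#' @param report an `"mr_report"`.
#' @param path output directory (tsv) or file (json).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    fit <- report$fit
    payload <- list(
      config = report$config,
      allele_freq_pct = as.list(report$frequencies$allele_pct),
      genotype_summaries = report$summaries,
      coefficients = as.list(stats::coef(fit)),
      se = as.list(fit$se), p = as.list(fit$pval),
      vcov = stats::vcov(fit), rss = fit$rss, df = fit$df.residual,
      genotype_estimates = report$estimates,
      welch = list(F = unname(report$welch$statistic),
                   df1 = unname(report$welch$parameter["df1"]),
                   df2 = unname(report$welch$parameter["df2"]),
                   p = report$welch$p.value),
      tamhane = as.data.frame(report$tamhane),
      dose = as.data.frame(report$dose),
      variability = report$variability)
    if (!is.null(report$transformations)) {
      payload$transformations <- as.data.frame(report$transformations)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(path, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
  }
  wr(report$summaries, "genotype_summaries")
  wr(data.frame(allele = names(report$frequencies$allele_pct),
                count = report$frequencies$allele_counts,
                pct = round(report$frequencies$allele_pct, 1)),
     "allele_frequencies")
  fit <- report$fit
  wr(data.frame(term = names(stats::coef(fit)),
                estimate = round(stats::coef(fit), 3),
                se = round(fit$se, 3), t = round(fit$tval, 2),
                p = format.pval(fit$pval, digits = 3, eps = 1e-15)),
     "allele_fit")
  est <- report$estimates
  est$estimate <- round(est$estimate, 3)
  est$se <- round(est$se, 3)
  est$percent_wt <- round(est$percent_wt)
  wr(est, "genotype_estimates")
  wr(as.data.frame(report$dose), "dose_table")
  wr(as.data.frame(report$tamhane), "tamhane_t2")
  wr(report$variability, "variability")
  if (!is.null(report$transformations)) {
    wr(as.data.frame(report$transformations), "transformations")
  }
  if (!is.null(report$covariate_screens)) {
    wr(report$covariate_screens, "covariate_screens")
  }
  invisible(path)
}
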