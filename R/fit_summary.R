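#' Fit the allele model from per-genotype summary statistics
#'
#' Reproduces the individual-level zero-intercept fit exactly from the
#' sufficient statistics (n, mean MR, SD of MR) of each genotype group.
#' Because all subjects of a genotype share one design row x_g, the normal
#' equations accumulate as X'X = sum_g n_g x_g x_g' and
#' X'y = sum_g n_g mean_g x_g, and the residual sum of squares decomposes
#' into within-group scatter plus group-mean lack of fit:
#' RSS = sum_g (n_g - 1) sd_g^2 + sum_g n_g (mean_g - fitted_g)^2.
#' Coefficients, covariance and degrees of freedom are identical to
#' [allele_fit()] on any individual-level cohort with those exact group
#' moments. Only the identity scale is supported: group means and SDs are
#' not sufficient for a transformed response.
#'
#' @param summaries a `data.frame` with columns `genotype`, `n`, `mean_mr`,
#'   `sd_mr` (as from [summarize_cohort()], [read_summary()] or
#'   [reference_summary()]); `sd_mr` may be `NA` only where `n == 1`.
#' @param variant model variant as in [build_allele_design()].
#' @param drop_unobserved drop (with a message) design columns carried by
#'   no subject instead of raising a singular-design error; see
#'   [allele_fit()].
#' @return An `"allele_fit"` (with `from = "summary"`; group-level fitted
#'   values, no individual residuals).
#' @examples
#' fit <- fit_from_summary(reference_summary())
#' coef(fit)
#' @export
fit_from_summary <- function(summaries,
                             variant = c("additive", "homozygous",
                                         "genotype"),
                             drop_unobserved = FALSE) {
  cl <- match.call()
  variant <- match.arg(variant)
  need <- c("genotype", "n", "mean_mr", "sd_mr")
  if (!all(need %in% names(summaries))) {
    stop("summaries must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g <- parse_genotype(summaries$genotype)
  n_g <- as.integer(summaries$n)
  m_g <- as.numeric(summaries$mean_mr)
  s_g <- as.numeric(summaries$sd_mr)
  if (any(n_g < 1)) stop("group sizes must be >= 1", call. = FALSE)
  bad_sd <- n_g > 1 & is.na(s_g)
  if (any(bad_sd)) {
    stop("missing sd_mr for multi-subject group(s): ",
         paste(g[bad_sd], collapse = ", "), call. = FALSE)
  }
  s_g[n_g == 1] <- 0

  # one design row per genotype group
  xg <- switch(variant,
    additive = allele_counts(g),
    homozygous = cbind(allele_counts(g),
                       hom = as.integer(.is_homozygous(g))),
    genotype = {
      lev <- g
      m <- diag(length(g))
      dimnames(m) <- list(NULL, lev)
      m
    })
  k <- ncol(xg)
  n <- sum(n_g)
  zero_col <- colSums(n_g * abs(xg)) == 0
  if (any(zero_col)) {
    if (!drop_unobserved) {
      stop("singular design: no observations carry ",
           paste(colnames(xg)[zero_col], collapse = ", "),
           "; these coefficients are unidentifiable", call. = FALSE)
    }
    message("dropping unobserved term(s): ",
            paste(colnames(xg)[zero_col], collapse = ", "))
    xg <- xg[, !zero_col, drop = FALSE]
    k <- ncol(xg)
  }
  if (n <= k) stop("not enough subjects (", n, ") for ", k, " parameters",
                   call. = FALSE)
  xtx <- crossprod(xg, n_g * xg)
  xty <- crossprod(xg, n_g * m_g)
  ch <- tryCatch(chol(xtx), error = function(e) {
    stop("singular design: normal-equation matrix is not positive definite",
         call. = FALSE)
  })
  xtx_inv <- chol2inv(ch)
  dimnames(xtx_inv) <- dimnames(xtx)
  beta <- drop(xtx_inv %*% xty)
  names(beta) <- colnames(xg)
  fitted_g <- drop(xg %*% beta)
  rss <- sum((n_g - 1) * s_g^2) + sum(n_g * (m_g - fitted_g)^2)
  df <- n - k
  sigma2 <- rss / df
  vcov <- sigma2 * xtx_inv
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((n_g - 1) * s_g^2) + sum(n_g * m_g^2)
  fit <- list(coefficients = beta, vcov = vcov, se = se, tval = tval,
              pval = pval, sigma2 = sigma2, rss = rss, df.residual = df,
              n = n, xtx = xtx, xtx_inv = xtx_inv,
              r_squared = 1 - rss / tss,
              fitted.values = stats::setNames(fitted_g, g),
              residuals = NULL,
              group_n = stats::setNames(n_g, g),
              variant = variant, transform = "identity",
              genotype = g, from = "summary", call = cl)
  class(fit) <- "allele_fit"
  fit
}

#' Genotype-level activity estimates from an additive fit
#'
#' A genotype's estimated MR is the sum of its two allele contributions,
#' with standard error propagated through the coefficient covariance
#' (se = sqrt(v_i + v_j + 2 cov_ij)), and its activity expressed as percent
#' of the homozygous wild type, 100 (beta_i + beta_j) / (2 beta_1) — exactly
#' 100 for \*1/\*1 by construction.
#'
#' @param fit an additive `"allele_fit"`.
#' @param genotype genotypes to tabulate (default all six).
#' @return A `data.frame` with columns `genotype`, `estimate`, `se`,
#'   `percent_wt` (full precision; round for display).
#' @examples
#' genotype_estimates(fit_from_summary(reference_summary()))
#' @export
genotype_estimates <- function(fit, genotype = genotype_levels()) {
  if (!inherits(fit, "allele_fit") || fit$variant != "additive") {
    stop("genotype_estimates needs an additive allele_fit", call. = FALSE)
  }
  pr <- predict.allele_fit(fit, genotype, se.fit = TRUE)
  wt <- 2 * stats::coef(fit)[["*1"]]
  data.frame(genotype = names(pr$fit),
             estimate = unname(pr$fit),
             se = unname(pr$se.fit),
             percent_wt = 100 * unname(pr$fit) / wt,
             stringsAsFactors = FALSE)
}

#' Nested F-test between allele-model variants
#'
#' Compares a reduced model against a full model with the extra-sum-of-
#' squares F statistic
#' F = ((RSS_r - RSS_f)/(k_f - k_r)) / (RSS_f/(n - k_f)).
#' The additive model is nested in both the homozygous-term and the
#' cell-means (genotype) variants; this is the test of whether either
#' interaction structure improves on the purely additive allele model.
#' Both fits must be on the same response (same n, same transformation).
#'
#' @param object the reduced `"allele_fit"`.
#' @param full the full `"allele_fit"`.
#' @param ... unused.
#' @return A `data.frame` of class `"anova"` with RSS, df, F and p.
#' @examples
#' s <- reference_summary()
#' anova(fit_from_summary(s, "additive"), fit_from_summary(s, "genotype"))
#' @export
anova.allele_fit <- function(object, full, ...) {
  if (missing(full) || !inherits(full, "allele_fit")) {
    stop("supply two allele_fit objects: anova(reduced, full)", call. = FALSE)
  }
  nesting <- list(additive = c("homozygous", "genotype"),
                  homozygous = "genotype")
  ok <- object$variant %in% names(nesting) &&
    full$variant %in% nesting[[object$variant]]
  if (!ok) {
    stop("models are not nested: ", sQuote(object$variant), " vs ",
         sQuote(full$variant), call. = FALSE)
  }
  if (object$n != full$n || object$transform != full$transform) {
    stop("fits are not on the same response (n or transform differ)",
         call. = FALSE)
  }
  k_r <- length(stats::coef(object))
  k_f <- length(stats::coef(full))
  df1 <- k_f - k_r
  df2 <- full$df.residual
  f <- ((object$rss - full$rss) / df1) / (full$rss / df2)
  f <- max(f, 0)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  tab <- data.frame(Res.Df = c(object$df.residual, df2),
                    RSS = c(object$rss, full$rss),
                    Df = c(NA, df1), `Sum of Sq` = c(NA, object$rss - full$rss),
                    F = c(NA, f), `Pr(>F)` = c(NA, p),
                    check.names = FALSE)
  rownames(tab) <- c(paste0("reduced (", object$variant, ")"),
                     paste0("full (", full$variant, ")"))
  structure(tab, class = c("anova", "data.frame"),
            heading = "Extra-sum-of-squares F test, zero-intercept allele model")
}

#' Compare response transformations for the additive fit
#'
#' Fits the additive allele model to MR, 1/MR, log10(MR) and -log10(MR) and
#' reports, per scale: the residual variance on its own scale, the
#' no-intercept coefficient of determination R^2 = 1 - RSS/sum(y^2), and a
#' Shapiro-Wilk normality statistic of the residuals. The ranking (normality
#' first, R^2 as tiebreaker) is a report, not an automatic selection: the
#' scales are not directly comparable by residual variance alone. log10 and
#' -log10 differ only by the sign of the response, so their fits are
#' mirror images with identical diagnostics.
#'
#' @param records cohort `data.frame` with `genotype` and `mr`.
#' @param transforms transformations to compare.
#' @return A `data.frame` of class `"transform_comparison"`, ranked best
#'   first, with columns `transform`, `sigma2`, `r_squared`, `shapiro_w`,
#'   `shapiro_p`, `rank`.
#' @export
compare_transformations <- function(records,
                                    transforms = c("identity", "reciprocal",
                                                   "log10", "neglog10")) {
  rows <- lapply(transforms, function(tr) {
    fit <- allele_fit(records, variant = "additive", transform = tr)
    sw <- stats::shapiro.test(fit$residuals)
    data.frame(transform = tr, sigma2 = fit$sigma2,
               r_squared = fit$r_squared,
               shapiro_w = unname(sw$statistic),
               shapiro_p = sw$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$shapiro_w, -out$r_squared)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("transform_comparison", "data.frame")
  out
}

#' @export
print.transform_comparison <- function(x, digits = 4, ...) {
  cat("Response-scale comparison for the additive allele model\n")
  cat("(ranked by residual normality, then no-intercept R^2)\n\n")
  df <- as.data.frame(x)
  df$sigma2 <- signif(df$sigma2, digits)
  df$r_squared <- signif(df$r_squared, digits)
  df$shapiro_w <- signif(df$shapiro_w, digits)
  df$shapiro_p <- format.pval(df$shapiro_p, digits = 3, eps = 1e-15)
  print(df, row.names = FALSE)
  invisible(x)
}
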