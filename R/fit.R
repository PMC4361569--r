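#' Design matrix for the allele model
#'
#' Builds the model matrix and (possibly transformed) response for the
#' zero-intercept genotype-phenotype regression. Variants:
#' \describe{
#'   \item{`additive`}{three columns of allele copy numbers; each row sums
#'     to 2, so the columns are collinear with a constant and the model must
#'     not have an intercept. Coefficients are per-allele-copy MR
#'     contributions.}
#'   \item{`homozygous`}{the additive columns plus a single indicator that
#'     is 1 for any homozygote — a one-parameter test for dominance.}
#'   \item{`genotype`}{one indicator per observed genotype (cell-means
#'     model, no intercept); its fit equals the per-genotype means.}
#' }
#'
#' @param genotype character vector of genotype labels.
#' @param mr positive metabolic ratios, same length.
#' @param variant model variant, see above.
#' @param transform response transformation: `"identity"`, `"reciprocal"`
#'   (1/MR), `"log10"` or `"neglog10"` (-log10).
#' @return List with the model matrix `x`, transformed response `y`,
#'   `variant` and `transform`.
#' @export
build_allele_design <- function(genotype,
                                mr,
                                variant = c("additive", "homozygous", "genotype"),
                                transform = c("identity", "reciprocal",
                                              "log10", "neglog10")) {
  variant <- match.arg(variant)
  transform <- match.arg(transform)
  if (length(genotype) != length(mr)) {
    stop("genotype and mr must have the same length", call. = FALSE)
  }
  g <- parse_genotype(genotype)
  if (transform != "identity" && any(mr <= 0)) {
    stop("transformation ", sQuote(transform), " needs MR > 0; offending ",
         "position(s): ", paste(which(mr <= 0), collapse = ", "),
         call. = FALSE)
  }
  x <- switch(variant,
    additive = allele_counts(g),
    homozygous = cbind(allele_counts(g), hom = as.integer(.is_homozygous(g))),
    genotype = {
      lev <- intersect(genotype_levels(), unique(g))
      m <- vapply(lev, function(l) as.integer(g == l), integer(length(g)))
      dimnames(m) <- list(NULL, lev)
      m
    })
  y <- switch(transform,
    identity = mr,
    reciprocal = 1 / mr,
    log10 = log10(mr),
    neglog10 = -log10(mr))
  list(x = x, y = y, variant = variant, transform = transform, genotype = g)
}

#' Fit the zero-intercept allele model
#'
#' Ordinary least squares without intercept for the regression of the
#' metabolic ratio on per-subject allele copy numbers,
#' `MR ~ -1 + n(*1) + n(*2) + n(*3)`. The intercept is omitted because each
#' diploid row of allele counts sums to 2, making the three columns
#' collinear with a constant: the coefficients are then directly
#' interpretable as the MR contributed by one copy of each allele, and a
#' genotype's expected MR is the sum of its two allele contributions
#' (co-dominant, additive expression).
#'
#' The solution uses a QR decomposition of the design; the normal-equation
#' quantities (X'X)^-1, the residual variance RSS/(n-k) and the coefficient
#' covariance matrix are exposed for error propagation. Two-tailed
#' per-coefficient p-values use the Student t distribution on n-k degrees
#' of freedom.
#'
#' @param genotype character vector of genotype labels, or a cohort
#'   `data.frame` with `genotype` and `mr` columns (then `mr` is taken from
#'   it).
#' @param mr numeric metabolic ratios (ignored when `genotype` is a
#'   data frame).
#' @param drop_unobserved an allele carried by no subject makes its column
#'   identically zero and the design singular. By default this is an error
#'   naming the column; with `drop_unobserved = TRUE` the column is dropped
#'   (with a message) and the remaining terms are fitted.
#' @inheritParams build_allele_design
#' @return An object of class `"allele_fit"` with components
#'   `coefficients`, `vcov`, `se`, `tval`, `pval`, `sigma2`, `rss`,
#'   `df.residual`, `n`, `xtx`, `xtx_inv`, `fitted.values`, `residuals`,
#'   `variant`, `transform`, `from` (`"records"`).
#' @seealso [fit_from_summary()] for the identical fit from per-genotype
#'   summary statistics; [genotype_estimates()]; [anova.allele_fit()].
#' @examples
#' cohort <- reconstruct_from_summary(reference_summary())
#' fit <- allele_fit(cohort)
#' summary(fit)
#' @export
allele_fit <- function(genotype, mr = NULL,
                       variant = c("additive", "homozygous", "genotype"),
                       transform = c("identity", "reciprocal",
                                     "log10", "neglog10"),
                       drop_unobserved = FALSE) {
  cl <- match.call()
  if (is.data.frame(genotype)) {
    mr <- genotype$mr
    genotype <- genotype$genotype
  }
  d <- build_allele_design(genotype, mr, variant, transform)
  fit <- .ols_no_intercept(d$x, d$y, drop_unobserved = drop_unobserved)
  fit$variant <- d$variant
  fit$transform <- d$transform
  fit$genotype <- d$genotype
  fit$from <- "records"
  fit$call <- cl
  class(fit) <- "allele_fit"
  fit
}

# Core no-intercept OLS via QR; exposes normal-equation quantities.
.ols_no_intercept <- function(x, y, drop_unobserved = FALSE) {
  zero_col <- colSums(abs(x)) == 0
  if (any(zero_col)) {
    if (!drop_unobserved) {
      stop("singular design: no observations carry ",
           paste(colnames(x)[zero_col], collapse = ", "),
           "; these coefficients are unidentifiable", call. = FALSE)
    }
    message("dropping unobserved term(s): ",
            paste(colnames(x)[zero_col], collapse = ", "))
    x <- x[, !zero_col, drop = FALSE]
  }
  k <- ncol(x)
  n <- nrow(x)
  qf <- qr(x)
  if (qf$rank < k) {
    stop("singular design: rank ", qf$rank, " < ", k, " columns (",
         paste(colnames(x), collapse = ", "), ")", call. = FALSE)
  }
  beta <- qr.coef(qf, y)
  res <- y - drop(x %*% beta)
  rss <- sum(res^2)
  df <- n - k
  sigma2 <- rss / df
  # (X'X)^-1 from the R factor; undo any column pivoting
  R <- qr.R(qf)
  inv <- chol2inv(R)
  piv <- qf$pivot
  xtx_inv <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  xtx_inv[piv, piv] <- inv
  vcov <- sigma2 * xtx_inv
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coefficients = beta, vcov = vcov, se = se, tval = tval, pval = pval,
       sigma2 = sigma2, rss = rss, df.residual = df, n = n,
       xtx = crossprod(x), xtx_inv = xtx_inv,
       r_squared = 1 - rss / sum(y^2),
       fitted.values = drop(x %*% beta), residuals = res)
}

#' @export
print.allele_fit <- function(x, digits = 3, ...) {
  cat("Zero-intercept allele model (", x$variant, ", ", x$transform,
      " scale), fitted from ", x$from, "\n", sep = "")
  cat("n =", x$n, " residual df =", x$df.residual,
      " RSS =", format(x$rss, digits = 5), "\n")
  cat("Allele/term contributions (per copy, MR units):\n")
  print(round(stats::coef(x), digits))
  invisible(x)
}

#' @export
summary.allele_fit <- function(object, ...) {
  ct <- cbind(Estimate = stats::coef(object), `Std. Error` = object$se,
              `t value` = object$tval, `Pr(>|t|)` = object$pval)
  out <- list(fit = object, coefficients = ct,
              sigma = sqrt(object$sigma2),
              r.squared = object$r_squared %||% NA_real_)
  class(out) <- "summary.allele_fit"
  out
}

#' @export
print.summary.allele_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, eps.Pvalue = 1e-15)
  cat("\nResidual standard error:", format(x$sigma, digits = digits),
      "on", x$fit$df.residual, "degrees of freedom\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.allele_fit <- function(object, ...) object$coefficients

#' @export
vcov.allele_fit <- function(object, ...) object$vcov

#' @export
fitted.allele_fit <- function(object, ...) object$fitted.values

#' @export
residuals.allele_fit <- function(object, ...) object$residuals

#' @export
confint.allele_fit <- function(object, parm, level = 0.95, ...) {
  cf <- stats::coef(object)
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  tq <- stats::qt(1 - a, object$df.residual)
  ci <- cbind(cf[parm] - tq * object$se[parm], cf[parm] + tq * object$se[parm])
  colnames(ci) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  ci
}

#' Predicted MR for genotypes
#'
#' For an additive (or homozygous-term) fit, a genotype's estimate is the
#' sum of its two allele coefficients; the standard error is propagated
#' through the coefficient covariance, se = sqrt(v_i + v_j + 2 cov_ij).
#'
#' @param object an `allele_fit`.
#' @param genotype genotypes to predict for; defaults to all six (or the
#'   observed ones for the cell-means variant).
#' @param se.fit also return standard errors.
#' @param ... unused.
#' @return Named vector of estimates, or a list with `fit` and `se.fit`.
#' @export
predict.allele_fit <- function(object, genotype = NULL, se.fit = FALSE, ...) {
  if (is.null(genotype)) {
    genotype <- if (object$variant == "genotype") {
      names(stats::coef(object))
    } else genotype_levels()
  }
  g <- parse_genotype(genotype)
  x <- switch(object$variant,
    additive = allele_counts(g),
    homozygous = cbind(allele_counts(g),
                       hom = as.integer(.is_homozygous(g))),
    genotype = {
      lev <- names(stats::coef(object))
      if (!all(g %in% lev)) {
        stop("cell-means fit has no coefficient for genotype(s): ",
             paste(setdiff(g, lev), collapse = ", "), call. = FALSE)
      }
      m <- vapply(lev, function(l) as.integer(g == l), integer(length(g)))
      if (length(g) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, lev))
      m
    })
  est <- drop(x %*% stats::coef(object))
  names(est) <- g
  if (!se.fit) return(est)
  se <- sqrt(rowSums((x %*% stats::vcov(object)) * x))
  names(se) <- g
  list(fit = est, se.fit = se)
}

#' Histograms of MR by genotype with fitted activities
#'
#' One histogram per multi-subject genotype with the model-estimated MR as
#' a dashed vertical line, plus the pooled cohort.
#'
#' @param x an `allele_fit` fitted from records on the identity scale.
#' @param records the cohort the fit came from (needed for the raw MRs).
#' @param breaks passed to [graphics::hist()].
#' @param ... further graphical parameters.
#' @return Invisibly, `x`.
#' @export
plot.allele_fit <- function(x, records, breaks = 20, ...) {
  if (x$transform != "identity") {
    stop("plot is defined for identity-scale fits", call. = FALSE)
  }
  g <- parse_genotype(records$genotype)
  lev <- intersect(genotype_levels(), unique(g))
  lev <- lev[vapply(lev, function(l) sum(g == l) > 1, logical(1))]
  est <- predict.allele_fit(x)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(lev) + 1))
  on.exit(graphics::par(op))
  graphics::hist(records$mr, breaks = breaks, main = "all genotypes",
                 xlab = "MR", ...)
  for (l in lev) {
    graphics::hist(records$mr[g == l], breaks = breaks, main = l,
                   xlab = "MR", ...)
    graphics::abline(v = est[l], lty = 2)
  }
  invisible(x)
}
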