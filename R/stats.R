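#' Allele and genotype frequencies
#'
#' Counts allele copies over the 2n chromosomes of a cohort (each subject
#' contributes two) and reports allele and genotype frequencies in percent.
#'
#' @param x either a cohort `data.frame` with a `genotype` column, or a
#'   per-genotype summary with `genotype` and `n` columns.
#' @return A list of class `"freq_table"` with `allele_counts`,
#'   `allele_pct`, `genotype_n`, `genotype_pct`, `n_subjects`.
#' @examples
#' allele_frequencies(reference_summary())
#' @export
allele_frequencies <- function(x) {
  if (!is.data.frame(x) || !"genotype" %in% names(x)) {
    stop("x must be a data.frame with a 'genotype' column", call. = FALSE)
  }
  if ("n" %in% names(x)) {
    g <- parse_genotype(x$genotype)
    n_g <- as.integer(x$n)
  } else {
    tab <- summarize_cohort(x)
    g <- tab$genotype
    n_g <- tab$n
  }
  if (sum(n_g) < 1) stop("empty cohort", call. = FALSE)
  counts_mat <- allele_counts(g)
  ac <- drop(crossprod(counts_mat, n_g))
  n <- sum(n_g)
  out <- list(allele_counts = ac,
              allele_pct = 100 * ac / (2 * n),
              genotype_n = stats::setNames(n_g, g),
              genotype_pct = stats::setNames(100 * n_g / n, g),
              n_subjects = n)
  class(out) <- "freq_table"
  out
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Cohort of", x$n_subjects, "subjects /", 2 * x$n_subjects,
      "chromosomes\n")
  cat("Allele frequencies (%):\n")
  print(round(x$allele_pct, 1))
  cat("Genotype frequencies (%):\n")
  print(round(x$genotype_pct, 1))
  invisible(x)
}

#' Welch's heteroscedastic one-way ANOVA from group summaries
#'
#' Tests equality of group mean MRs without assuming equal variances,
#' operating on per-group sufficient statistics (n, mean, sd). With weights
#' w_g = n_g/s_g^2 and weighted grand mean m_w = sum(w_g m_g)/sum(w_g):
#' \deqn{F = \frac{\sum_g w_g (m_g - m_w)^2 / (k-1)}
#'            {1 + \frac{2(k-2)}{k^2-1} \sum_g \frac{(1-w_g/\sum w)^2}{n_g-1}}}
#' with df1 = k-1 and Welch-Satterthwaite
#' df2 = (k^2-1) / (3 sum_g (1-w_g/sum w)^2/(n_g-1)).
#'
#' Groups with fewer than `min_n` subjects carry no usable variance and are
#' excluded with a message (e.g. a singleton genotype).
#'
#' @param summaries per-genotype summary `data.frame` (`genotype`, `n`,
#'   `mean_mr`, `sd_mr`).
#' @param min_n smallest group size admitted (default 2).
#' @param quiet suppress the exclusion message.
#' @return An object of class `"htest"` with the F statistic, the two
#'   degrees of freedom and the p-value.
#' @examples
#' welch_anova(reference_summary())
#' @export
welch_anova <- function(summaries, min_n = 2, quiet = FALSE) {
  keep <- summaries$n >= min_n
  if (!quiet && any(!keep)) {
    message("welch_anova: excluding group(s) with n < ", min_n, ": ",
            paste(summaries$genotype[!keep], collapse = ", "))
  }
  s <- summaries[keep, , drop = FALSE]
  k <- nrow(s)
  if (k < 2) stop("need at least two groups with n >= ", min_n, call. = FALSE)
  if (any(is.na(s$sd_mr) | s$sd_mr <= 0)) {
    stop("zero or missing within-group variance for group(s): ",
         paste(s$genotype[is.na(s$sd_mr) | s$sd_mr <= 0], collapse = ", "),
         "; Welch weights are undefined", call. = FALSE)
  }
  w <- s$n / s$sd_mr^2
  mw <- sum(w * s$mean_mr) / sum(w)
  a <- sum(w * (s$mean_mr - mw)^2) / (k - 1)
  h <- sum((1 - w / sum(w))^2 / (s$n - 1))
  f <- a / (1 + 2 * (k - 2) / (k^2 - 1) * h)
  df2 <- (k^2 - 1) / (3 * h)
  p <- stats::pf(f, k - 1, df2, lower.tail = FALSE)
  structure(list(statistic = c(F = f),
                 parameter = c(df1 = k - 1, df2 = df2),
                 p.value = p,
                 method = "Welch one-way ANOVA (summary statistics, unequal variances)",
                 data.name = paste(s$genotype, collapse = ", ")),
            class = "htest")
}

#' Tamhane T2 post-hoc pairwise comparisons
#'
#' All pairwise comparisons of group means under unequal variances: each
#' pair uses a Welch t statistic
#' t = (m_i - m_j)/sqrt(s_i^2/n_i + s_j^2/n_j) with Welch-Satterthwaite
#' degrees of freedom, and the family error rate is controlled with the
#' Sidak bound — a pair is significant iff its two-tailed p-value is at
#' most 1 - (1 - alpha)^(1/m) for m pairs. This is the T2 dialect
#' (pairwise Welch + Sidak); software implementations differ slightly in
#' the df convention.
#'
#' @inheritParams welch_anova
#' @param family_alpha family-wise error rate (default 0.05).
#' @return A `data.frame` of class `"tamhane_t2"`, one row per pair:
#'   `group1`, `group2`, `diff`, `se`, `t`, `df`, `p`, `p_crit`,
#'   `significant`.
#' @examples
#' tamhane_t2(reference_summary())
#' @export
tamhane_t2 <- function(summaries, family_alpha = 0.05, min_n = 2,
                       quiet = FALSE) {
  keep <- summaries$n >= min_n
  if (!quiet && any(!keep)) {
    message("tamhane_t2: excluding group(s) with n < ", min_n, ": ",
            paste(summaries$genotype[!keep], collapse = ", "))
  }
  s <- summaries[keep, , drop = FALSE]
  k <- nrow(s)
  if (k < 2) stop("need at least two groups with n >= ", min_n, call. = FALSE)
  if (any(is.na(s$sd_mr))) {
    stop("missing within-group SD for group(s): ",
         paste(s$genotype[is.na(s$sd_mr)], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  p_crit <- 1 - (1 - family_alpha)^(1 / m)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    vi <- s$sd_mr[i]^2 / s$n[i]
    vj <- s$sd_mr[j]^2 / s$n[j]
    se <- sqrt(vi + vj)
    tt <- (s$mean_mr[i] - s$mean_mr[j]) / se
    df <- (vi + vj)^2 / (vi^2 / (s$n[i] - 1) + vj^2 / (s$n[j] - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(group1 = s$genotype[i], group2 = s$genotype[j],
               diff = s$mean_mr[i] - s$mean_mr[j], se = se, t = tt,
               df = df, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_crit <- p_crit
  out$significant <- out$p <= p_crit
  rownames(out) <- NULL
  class(out) <- c("tamhane_t2", "data.frame")
  attr(out, "family_alpha") <- family_alpha
  out
}

#' @export
print.tamhane_t2 <- function(x, digits = 3, ...) {
  cat("Tamhane T2 pairwise comparisons (pairwise Welch t, Sidak bound)\n")
  cat("family alpha =", attr(x, "family_alpha"),
      " per-pair critical p =", signif(x$p_crit[1], 3), "\n\n")
  df <- as.data.frame(x)
  df$diff <- round(df$diff, digits)
  df$se <- round(df$se, digits)
  df$t <- round(df$t, 2)
  df$df <- round(df$df, 1)
  df$p <- format.pval(df$p, digits = 3, eps = 1e-15)
  df$p_crit <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flag within-genotype outliers
#'
#' Flags subjects whose MR lies more than `k` standard deviations from
#' their genotype's mean, |MR - mean_g| > k sd_g (strict), using the
#' group's own mean and SD including the candidate point. Singleton groups
#' are skipped.
#'
#' @param records cohort `data.frame` with `genotype` and `mr`.
#' @param k flagging threshold in SD units (default 3).
#' @return A `data.frame` with one row per subject in a multi-subject
#'   group: `subject_id`, `genotype`, `mr`, `z` (signed), `flagged`.
#' @export
flag_outliers <- function(records, k = 3) {
  g <- parse_genotype(records$genotype)
  lev <- intersect(genotype_levels(), unique(g))
  rows <- lapply(lev, function(l) {
    idx <- which(g == l)
    if (length(idx) < 2) return(NULL)
    mu <- mean(records$mr[idx])
    sd_g <- stats::sd(records$mr[idx])
    z <- (records$mr[idx] - mu) / sd_g
    data.frame(subject_id = records$subject_id[idx], genotype = l,
               mr = records$mr[idx], z = z, flagged = abs(z) > k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen a covariate for an effect on MR
#'
#' Welch two-sample t-test of MR between the two levels of a binary
#' covariate (sex, smoking, oral contraception, vegetarian diet, ...),
#' optionally within a genotype stratum. Missing covariate values are
#' excluded pairwise. Two-tailed at `alpha`.
#'
#' @param records cohort `data.frame` with `mr` and the covariate column.
#' @param covariate name of the covariate column.
#' @param genotype optional genotype label restricting the comparison to
#'   one stratum.
#' @param alpha significance level (default 0.05).
#' @return A one-row `data.frame`: `covariate`, `level1`, `level2`, `n1`,
#'   `n2`, `mean1`, `mean2`, `t`, `df`, `p`, `significant` — or `NULL`
#'   (with a warning) when a level has fewer than 2 subjects.
#' @export
covariate_screen <- function(records, covariate, genotype = NULL,
                             alpha = 0.05) {
  if (!covariate %in% names(records)) {
    stop("no column ", sQuote(covariate), " in records", call. = FALSE)
  }
  dat <- records
  if (!is.null(genotype)) {
    dat <- dat[parse_genotype(dat$genotype) == parse_genotype(genotype), ,
               drop = FALSE]
  }
  v <- dat[[covariate]]
  ok <- !is.na(v) & !is.na(dat$mr)
  dat <- dat[ok, , drop = FALSE]
  v <- v[ok]
  lev <- sort(unique(v))
  if (length(lev) != 2) {
    warning("covariate ", sQuote(covariate), " is not binary after ",
            "removing missings (", length(lev), " level(s)); skipped")
    return(NULL)
  }
  x1 <- dat$mr[v == lev[1]]
  x2 <- dat$mr[v == lev[2]]
  if (length(x1) < 2 || length(x2) < 2) {
    warning("covariate ", sQuote(covariate), ": a level has < 2 subjects; ",
            "skipped")
    return(NULL)
  }
  tt <- stats::t.test(x1, x2)
  data.frame(covariate = covariate,
             level1 = as.character(lev[1]), level2 = as.character(lev[2]),
             n1 = length(x1), n2 = length(x2),
             mean1 = mean(x1), mean2 = mean(x2),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, significant = tt$p.value < alpha,
             stringsAsFactors = FALSE)
}
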