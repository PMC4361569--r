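#' Default simulation parameters
#'
#' Study-condition defaults for the cohort simulator: allele frequencies as
#' the exact chromosome fractions observed in the reference cohort
#' ((453, 67, 46)/566, i.e. 80.0/11.8/8.1%), per-allele-copy MR
#' contributions (0.596, 0.405, 0.113), and within-genotype coefficients of
#' variation of measured MR (0.26, 0.20, 0.35, 0.34, 0.22 for the five
#' multi-subject genotypes; 0.30 — the midrange — for \*3/\*3, whose CV a
#' single carrier cannot define).
#'
#' @name sim_defaults
NULL

.default_allele_freqs <- c("*1" = 453, "*2" = 67, "*3" = 46) / 566
.default_allele_effects <- c("*1" = 0.596, "*2" = 0.405, "*3" = 0.113)
.default_cv <- c("*1/*1" = 0.26, "*1/*2" = 0.20, "*1/*3" = 0.35,
                 "*2/*2" = 0.34, "*2/*3" = 0.22, "*3/*3" = 0.30)

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Each subject draws two alleles independently from the allele frequency
#' vector, so genotype probabilities are the Hardy-Weinberg products
#' (p^2, 2pq, ...). Reproducible given `seed`.
#'
#' @param n number of subjects.
#' @param allele_freqs frequencies of \*1, \*2, \*3; must be non-negative
#'   and sum to 1 (within 1e-12).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Character vector of `n` canonical genotype labels.
#' @examples
#' sample_genotypes_hwe(5, seed = 1)
#' @export
sample_genotypes_hwe <- function(n, allele_freqs = .default_allele_freqs,
                                 seed = NULL) {
  if (length(allele_freqs) != 3 || any(allele_freqs < 0) ||
      abs(sum(allele_freqs) - 1) > 1e-12) {
    stop("allele_freqs must be 3 non-negative frequencies summing to 1",
         call. = FALSE)
  }
  if (sum(allele_freqs > 0) < 1) stop("degenerate frequency vector",
                                      call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a1 <- sample.int(3, n, replace = TRUE, prob = allele_freqs)
  a2 <- sample.int(3, n, replace = TRUE, prob = allele_freqs)
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  paste(.ALLELES[lo], .ALLELES[hi], sep = "/")
}

#' Simulate metabolic-ratio phenotypes for given genotypes
#'
#' Each subject's expected MR is the sum of its two allele contributions,
#' mu_g = beta_i + beta_j (additive, co-dominant). Noise is multiplicative:
#' with `noise = "normal"`, MR = mu_g (1 + e), e ~ N(0, cv_g), redrawn while
#' MR <= 0 (an error is raised if more than half the draws would be
#' rejected — use lognormal for such large CVs); with `noise = "lognormal"`,
#' MR is lognormal with mean mu_g and coefficient of variation cv_g
#' (sdlog = sqrt(log(1 + cv^2))), reproducing the right skew seen in real
#' MR histograms. Optional binary covariates act multiplicatively, and
#' concentration pairs can be back-filled (FLB uniform on `flb_range` nM,
#' OHF = MR x FLB).
#'
#' @param genotype character vector of genotype labels.
#' @param allele_effects per-copy MR contributions of \*1, \*2, \*3.
#' @param cv within-genotype coefficient of variation: a scalar or a named
#'   vector over genotypes.
#' @param noise `"normal"` (truncated, the default) or `"lognormal"`.
#' @param covariates optional named list; each element
#'   `list(prevalence =, effect =)` adds a 0/1 column with that prevalence
#'   multiplying MR by `effect` when 1.
#' @param concentrations if `TRUE`, back-fill `flb_conc`/`ohf_conc` (nM).
#' @param flb_range uniform range for simulated FLB concentrations, nM.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Cohort `data.frame`: `subject_id`, `genotype`, `flb_conc`,
#'   `ohf_conc`, `mr`, plus covariate columns.
#' @export
simulate_phenotypes <- function(genotype,
                                allele_effects = .default_allele_effects,
                                cv = .default_cv,
                                noise = c("normal", "lognormal"),
                                covariates = NULL,
                                concentrations = FALSE,
                                flb_range = c(820, 64700),
                                seed = NULL) {
  noise <- match.arg(noise)
  if (any(allele_effects <= 0)) stop("allele effects must be > 0",
                                     call. = FALSE)
  if (any(cv <= 0)) stop("cv must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- parse_genotype(genotype)
  n <- length(g)
  counts <- allele_counts(g)
  mu <- drop(counts %*% allele_effects[.ALLELES])
  cv_g <- if (length(cv) == 1) rep(cv, n) else {
    if (!all(g %in% names(cv))) {
      stop("cv must be a scalar or named over all genotypes present",
           call. = FALSE)
    }
    unname(cv[g])
  }
  if (noise == "normal") {
    mr <- mu * (1 + stats::rnorm(n, 0, cv_g))
    attempts <- 1
    while (any(mr <= 0)) {
      bad <- mr <= 0
      if (attempts == 1 && sum(bad) > n / 2) {
        stop("more than half the draws were truncated at MR <= 0; ",
             "use noise = \"lognormal\" for such large CVs", call. = FALSE)
      }
      mr[bad] <- mu[bad] * (1 + stats::rnorm(sum(bad), 0, cv_g[bad]))
      attempts <- attempts + 1
      if (attempts > 1000) stop("truncation did not converge", call. = FALSE)
    }
  } else {
    sdlog <- sqrt(log(1 + cv_g^2))
    meanlog <- log(mu) - sdlog^2 / 2
    mr <- stats::rlnorm(n, meanlog, sdlog)
  }
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    genotype = g, flb_conc = NA_real_, ohf_conc = NA_real_,
                    mr = mr, stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      spec <- covariates[[nm]]
      lvl <- stats::rbinom(n, 1, spec$prevalence)
      out$mr <- out$mr * ifelse(lvl == 1, spec$effect, 1)
      out[[nm]] <- lvl
    }
  }
  if (concentrations) {
    out$flb_conc <- stats::runif(n, flb_range[1], flb_range[2])
    out$ohf_conc <- out$mr * out$flb_conc
  }
  out
}

#' Simulate a complete cohort
#'
#' Draws genotypes under Hardy-Weinberg equilibrium and then phenotypes
#' under the additive allele model with multiplicative within-genotype
#' noise. A single master seed derives fixed per-stage sub-seeds (genotypes:
#' seed + 1; phenotypes: seed + 2), so each stage is independently
#' reproducible.
#'
#' @inheritParams sample_genotypes_hwe
#' @inheritParams simulate_phenotypes
#' @param seed master integer seed.
#' @return Cohort `data.frame` as from [simulate_phenotypes()].
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' summarize_cohort(cohort)
#' @export
simulate_cohort <- function(n = 283,
                            allele_freqs = .default_allele_freqs,
                            allele_effects = .default_allele_effects,
                            cv = .default_cv,
                            noise = c("normal", "lognormal"),
                            covariates = NULL,
                            concentrations = FALSE,
                            flb_range = c(820, 64700),
                            seed = NULL) {
  g <- sample_genotypes_hwe(n, allele_freqs,
                            seed = if (is.null(seed)) NULL else seed + 1L)
  simulate_phenotypes(g, allele_effects, cv, noise, covariates,
                      concentrations, flb_range,
                      seed = if (is.null(seed)) NULL else seed + 2L)
}

#' Deterministic cohort with exact group moments
#'
#' Expands a per-genotype summary back into individual records whose sample
#' mean and sample SD (n-1 denominator) equal the summary exactly: each
#' group of size n is mean + sd * z, where z is the equally spaced sequence
#' 1..n centred and scaled to unit sample SD — a fixed, symmetric,
#' randomness-free pattern. A singleton group becomes its single value.
#' Useful as an exact-moment fixture: any statistic that depends on the
#' data only through (n, mean, sd) — the zero-intercept fit above all — is
#' reproduced exactly on the reconstruction.
#'
#' @param summaries `data.frame` with `genotype`, `n`, `mean_mr`, `sd_mr`
#'   (`sd_mr` must be `NA` where `n == 1`).
#' @return Cohort `data.frame` with `subject_id`, `genotype`, `mr`.
#' @examples
#' cohort <- reconstruct_from_summary(reference_summary())
#' nrow(cohort)  # 283
#' @export
reconstruct_from_summary <- function(summaries) {
  g <- parse_genotype(summaries$genotype)
  rows <- lapply(seq_along(g), function(i) {
    n <- summaries$n[i]
    m <- summaries$mean_mr[i]
    s <- summaries$sd_mr[i]
    if (n < 1) stop("group size must be >= 1", call. = FALSE)
    if (n == 1) {
      if (!is.na(s)) stop("sd given for singleton group ", g[i],
                          call. = FALSE)
      mr <- m
    } else {
      if (is.na(s)) stop("missing sd for group ", g[i], " with n > 1",
                         call. = FALSE)
      z <- seq_len(n) - (n + 1) / 2
      z <- z / stats::sd(z)
      mr <- m + s * z
    }
    data.frame(genotype = g[i], mr = mr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  data.frame(subject_id = sprintf("R%04d", seq_len(nrow(out))),
             genotype = out$genotype, mr = out$mr,
             stringsAsFactors = FALSE)
}
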