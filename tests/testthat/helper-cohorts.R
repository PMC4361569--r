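# Shared fixtures: all built in code, no data files.

# Reference per-genotype summary used throughout (counts, means, SDs of the
# 283-subject flurbiprofen study).
ref_summary <- reference_summary()

# A random small cohort guaranteed to carry every allele, so the additive
# design has full rank. Genotypes are drawn uniformly over the six levels.
random_small_cohort <- function(n = 20) {
  repeat {
    g <- sample(genotype_levels(), n, replace = TRUE)
    if (all(colSums(allele_counts(g)) > 0)) break
  }
  data.frame(subject_id = sprintf("X%03d", seq_len(n)),
             genotype = g,
             mr = stats::runif(n, 0.1, 2.5),
             stringsAsFactors = FALSE)
}

# A cohort guaranteed to contain every genotype class, so every model
# variant (including the homozygosity indicator) is identifiable.
cohort_all_genotypes <- function(n = 120, seed = 1) {
  g <- c(genotype_levels(),
         sample_genotypes_hwe(n - 6, seed = seed))
  simulate_phenotypes(g, seed = seed + 1)
}

# Independent least-squares oracle: numerical minimisation of the residual
# sum of squares, never touching the normal equations.
brute_force_ols <- function(x, y, start = NULL) {
  ssr <- function(b) sum((y - drop(x %*% b))^2)
  if (is.null(start)) start <- rep(mean(y) / 2, ncol(x))
  opt <- stats::optim(start, ssr, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000))
  stats::setNames(opt$par, colnames(x))
}

# A 39-subject group with exact mean 0.728 and sample SD 0.256 that
# contains the value 1.611: the remaining 38 values follow the equally
# spaced zero-mean pattern, rescaled so the group moments come out exact.
group_with_embedded_value <- function(n = 39, mean_g = 0.728, sd_g = 0.256,
                                      value = 1.611) {
  m_rest <- (n * mean_g - value) / (n - 1)
  ss_rest <- (n - 1) * sd_g^2 - (value - mean_g)^2 - (n - 1) * (m_rest - mean_g)^2
  z <- seq_len(n - 1) - n / 2
  z <- z / sqrt(sum(z^2))
  c(value, m_rest + sqrt(ss_rest) * z)
}

expect_rel_equal <- function(actual, expected, digits) {
  expect_equal(actual, expected, tolerance = 10^(-digits))
}
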