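test_that("design matrices encode alleles, homozygosity and cell means", {
  d <- build_allele_design("*1/*2", 1.0)
  expect_equal(unname(d$x[1, ]), c(1L, 1L, 0L))
  dh <- build_allele_design("*3/*3", 0.2, variant = "homozygous")
  expect_equal(unname(dh$x[1, ]), c(0L, 0L, 2L, 1L))
  dg <- build_allele_design(c("*1/*1", "*2/*3", "*1/*1"), c(1, 0.5, 1.2),
                            variant = "genotype")
  expect_equal(colnames(dg$x), c("*1/*1", "*2/*3"))
  expect_equal(rowSums(dg$x), c(1, 1, 1))
  expect_error(build_allele_design("*1/*1", -1, transform = "log10"),
               "MR > 0")
})

test_that("reference-cohort design accumulates the hand-computed X'X", {
  co <- reconstruct_from_summary(ref_summary)
  fit <- allele_fit(co)
  expect_equal(unname(fit$xtx),
               matrix(c(815, 52, 39, 52, 77, 5, 39, 5, 48), 3, 3),
               tolerance = 1e-12)
})

test_that("QR solution equals lm() and the brute-force SSR minimiser", {
  set.seed(101)
  for (i in 1:25) {
    co <- random_small_cohort(n = sample(8:30, 1))
    fit <- allele_fit(co)
    x <- allele_counts(co$genotype)
    lmfit <- lm(co$mr ~ -1 + x)
    expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-10)
    expect_equal(unname(vcov(fit)), unname(vcov(lmfit)), tolerance = 1e-10)
    expect_equal(fit$df.residual, lmfit$df.residual)
    expect_equal(unname(fit$pval),
                 unname(summary(lmfit)$coefficients[, 4]), tolerance = 1e-9)
    bf <- brute_force_ols(x, co$mr)
    expect_equal(unname(coef(fit)), unname(bf), tolerance = 1e-6)
  }
})

test_that("a noiseless additive cohort is interpolated exactly", {
  g <- c(rep("*1/*1", 10), rep("*3/*3", 10), rep("*1/*3", 10))
  mr <- c(rep(1.2, 10), rep(0.2, 10), rep(0.7, 10))
  expect_error(allele_fit(g, mr), "\\*2")
  fit2 <- suppressMessages(allele_fit(g, mr, drop_unobserved = TRUE))
  expect_equal(unname(coef(fit2)), c(0.6, 0.1), tolerance = 1e-12)
  expect_equal(fit2$rss, 0, tolerance = 1e-20)
  g3 <- c(g, rep("*2/*2", 5))
  mr3 <- c(mr, rep(0.8, 5))
  fit3 <- allele_fit(g3, mr3)
  expect_equal(unname(coef(fit3)), c(0.6, 0.4, 0.1), tolerance = 1e-12)
  expect_equal(fit3$rss, 0, tolerance = 1e-18)
})

test_that("six-subject toy fit matches the independent least-squares oracle", {
  g <- genotype_levels()
  mr <- c(1.2, 1.0, 0.7, 0.8, 0.5, 0.2)
  fit <- allele_fit(g, mr)
  bf <- brute_force_ols(allele_counts(g), mr)
  expect_equal(unname(coef(fit)), unname(bf), tolerance = 1e-6)
})

test_that("standard errors, covariance and confint are mutually consistent", {
  fit <- fit_from_summary(ref_summary)
  expect_equal(fit$se, sqrt(diag(vcov(fit))))
  expect_true(isSymmetric(vcov(fit), tol = 1e-12))
  expect_true(all(eigen(vcov(fit), only.values = TRUE)$values > 0))
  ci <- confint(fit)
  expect_equal(unname(ci[, 2] - ci[, 1]),
               unname(2 * qt(0.975, fit$df.residual) * fit$se))
})

test_that("genotype estimates are coefficient sums with propagated SEs", {
  fit <- fit_from_summary(ref_summary)
  est <- genotype_estimates(fit)
  b <- coef(fit)
  v <- vcov(fit)
  expect_equal(est$estimate[est$genotype == "*2/*3"],
               unname(b["*2"] + b["*3"]), tolerance = 1e-14)
  expect_equal(est$se[est$genotype == "*2/*3"],
               sqrt(v["*2", "*2"] + v["*3", "*3"] + 2 * v["*2", "*3"]),
               tolerance = 1e-14)
  expect_equal(est$se[est$genotype == "*1/*1"], 2 * fit$se[["*1"]],
               tolerance = 1e-14)
  expect_identical(est$percent_wt[est$genotype == "*1/*1"], 100)

  # a fit with equal allele effects gives every genotype the same activity
  sym <- fit
  sym$coefficients[] <- 0.5
  est_sym <- genotype_estimates(sym)
  expect_equal(est_sym$estimate, rep(1.0, 6))
  expect_equal(est_sym$percent_wt, rep(100, 6))
})

test_that("genotype estimates are monotone in the allele ordering", {
  set.seed(7)
  for (i in 1:10) {
    co <- simulate_cohort(150, seed = i)
    fit <- allele_fit(co)
    b <- sort(coef(fit), decreasing = TRUE)
    if (!all(names(b) == c("*1", "*2", "*3"))) next
    e <- genotype_estimates(fit)
    e <- setNames(e$estimate, e$genotype)
    expect_true(e["*1/*1"] > e["*1/*2"])
    expect_true(e["*1/*2"] > max(e["*1/*3"], e["*2/*2"]))
    expect_true(min(e["*1/*3"], e["*2/*2"]) > e["*2/*3"])
    expect_true(e["*2/*3"] > e["*3/*3"])
  }
})

test_that("nested F-test: identical models give F = 0, variants are compared", {
  co <- reconstruct_from_summary(ref_summary)
  fit_a <- allele_fit(co)
  fit_g <- allele_fit(co, variant = "genotype")
  # same RSS in both models is the degenerate F = 0, p = 1 case
  fake_full <- fit_g
  fake_full$rss <- fit_a$rss
  tab0 <- anova(fit_a, fake_full)
  expect_equal(tab0$F[2], 0)
  expect_equal(tab0$`Pr(>F)`[2], 1)

  tab <- anova(fit_a, fit_g)
  expect_equal(tab$RSS, c(22.758, 22.677), tolerance = 1e-3)
  expect_equal(tab$Df[2], 3)
  expect_equal(tab$Res.Df[2], 277)
  expect_gt(tab$`Pr(>F)`[2], 0.05)

  fit_h <- allele_fit(co, variant = "homozygous")
  tab_h <- anova(fit_a, fit_h)
  expect_gt(tab_h$`Pr(>F)`[2], 0.05)
  expect_error(anova(fit_g, fit_a), "not nested")
})

test_that("transformation comparison is symmetric in log sign and ranks
          an additive identity-scale truth first", {
  co <- simulate_cohort(200, cv = 0.05, seed = 5)
  cmp <- compare_transformations(co)
  expect_equal(as.character(cmp$transform[1]), "identity")
  l1 <- cmp[cmp$transform == "log10", ]
  l2 <- cmp[cmp$transform == "neglog10", ]
  expect_equal(l1$sigma2, l2$sigma2, tolerance = 1e-12)
  expect_equal(l1$shapiro_w, l2$shapiro_w, tolerance = 1e-12)
  expect_equal(l1$r_squared, l2$r_squared, tolerance = 1e-12)
})

test_that("predict returns per-genotype estimates with standard errors", {
  fit <- fit_from_summary(ref_summary)
  pr <- predict(fit, c("*3/*1", "*2/*3"), se.fit = TRUE)
  expect_equal(names(pr$fit), c("*1/*3", "*2/*3"))
  expect_equal(unname(pr$fit[1]),
               unname(coef(fit)["*1"] + coef(fit)["*3"]))
  expect_true(all(pr$se.fit > 0))
})
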