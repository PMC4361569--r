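test_that("allele frequencies count chromosomes", {
  fr <- allele_frequencies(ref_summary)
  expect_equal(unname(round(fr$allele_pct, 1)), c(80.0, 11.8, 8.1))
  expect_equal(sum(fr$allele_counts), 2 * 283)

  all_wt <- data.frame(genotype = "*1/*1", n = 10)
  expect_equal(unname(allele_frequencies(all_wt)$allele_pct),
               c(100, 0, 0))

  two <- data.frame(genotype = c("*1/*1", "*1/*2"), n = c(1, 1))
  expect_equal(unname(allele_frequencies(two)$allele_pct), c(75, 25, 0))

  # chromosome conservation on random cohorts
  set.seed(9)
  co <- simulate_cohort(77, seed = 9)
  fr2 <- allele_frequencies(co)
  expect_equal(sum(fr2$allele_counts), 2 * 77)
  expect_equal(sum(fr2$allele_pct), 100)
  expect_equal(sum(fr2$genotype_pct), 100)
})

test_that("Welch ANOVA from summaries matches oneway.test on raw data", {
  co <- reconstruct_from_summary(ref_summary)
  s <- summarize_cohort(co)
  w <- welch_anova(s, quiet = TRUE)
  multi <- co[co$genotype != "*3/*3", ]
  ow <- oneway.test(mr ~ genotype, data = multi, var.equal = FALSE)
  expect_equal(unname(w$statistic), unname(ow$statistic), tolerance = 1e-10)
  expect_equal(unname(w$parameter["df2"]),
               unname(ow$parameter["denom df"]), tolerance = 1e-10)
  expect_equal(w$p.value, ow$p.value, tolerance = 1e-9)
})

test_that("Welch ANOVA handles degenerate and two-group cases", {
  same <- data.frame(genotype = c("*1/*1", "*1/*2"), n = c(20, 20),
                     mean_mr = c(1, 1), sd_mr = c(0.3, 0.3))
  w0 <- welch_anova(same, quiet = TRUE)
  expect_equal(unname(w0$statistic), 0)
  expect_equal(w0$p.value, 1)

  # two groups: F is the squared Welch t and p-values agree
  set.seed(21)
  x <- rnorm(25, 1.1, 0.3)
  y <- rnorm(40, 0.8, 0.2)
  s2 <- data.frame(genotype = c("*1/*1", "*1/*3"), n = c(25, 40),
                   mean_mr = c(mean(x), mean(y)), sd_mr = c(sd(x), sd(y)))
  w2 <- welch_anova(s2, quiet = TRUE)
  tt <- t.test(x, y)
  expect_equal(unname(w2$statistic), unname(tt$statistic)^2,
               tolerance = 1e-6)
  expect_equal(w2$p.value, tt$p.value, tolerance = 1e-6)

  zero_var <- data.frame(genotype = c("*1/*1", "*1/*2"), n = c(5, 5),
                         mean_mr = c(1, 2), sd_mr = c(0, 0.1))
  expect_error(welch_anova(zero_var, quiet = TRUE), "variance")
  expect_message(welch_anova(ref_summary), "n < 2.*\\*3/\\*3")
})

test_that("Welch ANOVA approaches the classical F under homoscedasticity", {
  set.seed(31)
  g <- rep(c("*1/*1", "*1/*2", "*1/*3"), each = 400)
  mr <- rnorm(1200, rep(c(1.2, 1.0, 0.7), each = 400), 0.3)
  co <- data.frame(subject_id = seq_along(g), genotype = g, mr = mr)
  w <- welch_anova(summarize_cohort(co), quiet = TRUE)
  cl <- oneway.test(mr ~ genotype, data = co, var.equal = TRUE)
  expect_equal(unname(w$statistic), unname(cl$statistic), tolerance = 0.01)
})

test_that("Tamhane T2 flags pairs like a pairwise-Welch + Sidak oracle", {
  # three groups, one extreme mean: exactly the two pairs against the
  # extreme group are significant
  s3 <- data.frame(genotype = c("*1/*1", "*1/*2", "*1/*3"),
                   n = c(30, 30, 30),
                   mean_mr = c(1.0, 1.05, 2.0),
                   sd_mr = c(0.2, 0.2, 0.25))
  t2 <- tamhane_t2(s3, quiet = TRUE)
  expect_equal(nrow(t2), 3)
  expect_equal(sum(t2$significant), 2)
  sig_pairs <- t2[t2$significant, c("group1", "group2")]
  expect_true(all(sig_pairs == "*1/*3" | sig_pairs == "*1/*1" |
                    sig_pairs == "*1/*2"))
  expect_true(all(t2$group2[t2$significant] == "*1/*3"))

  # oracle: recompute each pair with t.test on exact-moment data and the
  # Sidak bound
  co <- reconstruct_from_summary(s3)
  alpha_pair <- 1 - (1 - 0.05)^(1 / 3)
  for (r in seq_len(nrow(t2))) {
    x <- co$mr[co$genotype == t2$group1[r]]
    y <- co$mr[co$genotype == t2$group2[r]]
    tt <- t.test(x, y)
    expect_equal(t2$t[r], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(t2$df[r], unname(tt$parameter), tolerance = 1e-9)
    expect_equal(t2$p[r], tt$p.value, tolerance = 1e-9)
    expect_equal(t2$significant[r], tt$p.value <= alpha_pair)
  }

  # identical groups: nothing significant
  same <- data.frame(genotype = c("*1/*1", "*1/*2", "*2/*2"),
                     n = rep(10, 3), mean_mr = rep(1, 3),
                     sd_mr = rep(0.2, 3))
  expect_false(any(tamhane_t2(same, quiet = TRUE)$significant))
})

test_that("Tamhane significance is monotone in the mean difference", {
  base <- data.frame(genotype = c("*1/*1", "*1/*2", "*1/*3"),
                     n = c(40, 40, 40),
                     mean_mr = c(1.0, 1.0, 1.0), sd_mr = c(0.25, 0.25, 0.25))
  was_sig <- FALSE
  for (shift in seq(0, 0.6, by = 0.05)) {
    s <- base
    s$mean_mr[3] <- 1.0 + shift
    t2 <- tamhane_t2(s, quiet = TRUE)
    sig <- t2$significant[t2$group2 == "*1/*3" & t2$group1 == "*1/*1"]
    expect_false(was_sig && !sig)  # once significant, stays significant
    was_sig <- sig
  }
  expect_true(was_sig)
})

test_that("outlier flagging uses the group's own moments, strictly > k SD", {
  mr <- group_with_embedded_value()
  co <- data.frame(subject_id = sprintf("s%02d", seq_along(mr)),
                   genotype = "*1/*3", mr = mr)
  # fixture has exact moments (0.728, 0.256) and contains 1.611
  expect_equal(mean(mr), 0.728, tolerance = 1e-12)
  expect_equal(sd(mr), 0.256, tolerance = 1e-12)
  fl <- flag_outliers(co)
  expect_equal(sum(fl$flagged), 1L)
  expect_equal(fl$mr[fl$flagged], 1.611)
  expect_equal(fl$z[fl$flagged], (1.611 - 0.728) / 0.256, tolerance = 1e-10)

  # a value exactly at the group mean has z = 0 and is never flagged
  z0 <- fl$z[abs(fl$mr - 0.728) < 1e-9]
  if (length(z0)) expect_true(all(abs(z0) < 1e-9))

  # boundary: exactly k SD away is kept (strict inequality); with integer
  # MRs 1, 2, 3 the extreme z-scores are exactly +/-1
  co2 <- data.frame(subject_id = c("a", "b", "c"), genotype = "*1/*1",
                    mr = c(1, 2, 3))
  expect_false(any(flag_outliers(co2, k = 1)$flagged))
  expect_equal(sum(flag_outliers(co2, k = 0.99)$flagged), 2L)
})

test_that("covariate screen is a two-sided Welch t with pairwise deletion", {
  co <- data.frame(subject_id = sprintf("s%02d", 1:6), genotype = "*1/*1",
                   mr = c(1, 2, 3, 1, 2, 3), sex = c(0, 0, 0, 1, 1, 1))
  sc <- covariate_screen(co, "sex")
  expect_equal(sc$t, 0)
  expect_equal(sc$p, 1)
  expect_false(sc$significant)

  co$smoker <- c(0, NA, 0, 1, 1, NA)
  sc2 <- covariate_screen(co, "smoker")
  expect_equal(sc2$n1 + sc2$n2, 4)

  co$rare <- c(1, 0, 0, 0, 0, 0)
  expect_warning(sc3 <- covariate_screen(co, "rare"), "skipped")
  expect_null(sc3)
})

test_that("covariate screen keeps its nominal error rate and finds real effects", {
  set.seed(41)
  # null: covariate independent of MR
  rej <- replicate(400, {
    co <- data.frame(subject_id = 1:60, genotype = "*1/*1",
                     mr = rlnorm(60, 0, 0.25),
                     flag = rbinom(60, 1, 0.5))
    sc <- covariate_screen(co, "flag")
    !is.null(sc) && sc$significant
  })
  rate <- mean(rej)
  # 99% binomial band around 0.05 for 400 replicates
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 400) + 1e-9)

  # power: +0.3 MR shift at n = 100 per level, sd 0.3 -> essentially always
  # detected (closed-form power ~ 1)
  hits <- replicate(20, {
    co <- data.frame(subject_id = 1:200, genotype = "*1/*1",
                     mr = rnorm(200, 1, 0.3) +
                       0.3 * rep(c(0, 1), each = 100),
                     oc = rep(c(0, 1), each = 100))
    covariate_screen(co, "oc")$significant
  })
  expect_true(all(hits))
})
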