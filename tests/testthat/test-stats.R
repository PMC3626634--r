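test_that("noiseless additive tables are recovered to machine precision", {
  set.seed(41)
  tab <- simulate_cohort_table(c(10, 8, 8, 6), baseline = 2,
                               beta_asd = -0.5, beta_tsc = 0.3,
                               beta_age = 0.07, sigma = 0)
  fit <- suppressWarnings(fit_ancova(tab, "y"))  # sigma = 0: perfect fit
  co <- fit$coefficients
  est <- setNames(co$estimate, co$term)
  expect_equal(est[["baseline"]], 2, tolerance = 1e-10)
  expect_equal(est[["ASD"]], -0.5, tolerance = 1e-10)
  expect_equal(est[["TSC"]], 0.3, tolerance = 1e-10)
  expect_equal(est[["age"]], 0.07, tolerance = 1e-10)
  expect_equal(fit$df, nrow(tab) - 4)
})

test_that("with constant age and one absent flag the model is a pooled t-test", {
  set.seed(42)
  tab <- data.frame(ASD = rep(c(0, 1), each = 12), TSC = 0, age = 10,
                    y = rnorm(24) + rep(c(0, 0.5), each = 12))
  fit <- fit_ancova(tab, "y")
  expect_setequal(fit$dropped_terms, c("TSC", "age"))
  tt <- t.test(y ~ ASD, data = tab, var.equal = TRUE)
  p_fit <- fit$coefficients$p[fit$coefficients$term == "ASD"]
  expect_equal(p_fit, tt$p.value, tolerance = 1e-12)
})

test_that("group estimates are invariant to shifting the age origin", {
  set.seed(43)
  tab <- simulate_cohort_table(c(8, 8, 8, 8))
  f1 <- fit_ancova(tab, "y")
  tab2 <- tab; tab2$age <- tab2$age + 100
  f2 <- fit_ancova(tab2, "y")
  for (term in c("ASD", "TSC", "age")) {
    expect_equal(f1$coefficients$estimate[f1$coefficients$term == term],
                 f2$coefficients$estimate[f2$coefficients$term == term],
                 tolerance = 1e-9)
  }
  expect_false(isTRUE(all.equal(
    f1$coefficients$estimate[f1$coefficients$term == "baseline"],
    f2$coefficients$estimate[f2$coefficients$term == "baseline"])))
})

test_that("degenerate designs raise informative errors", {
  set.seed(44)
  tab <- simulate_cohort_table(c(10, 10, 10, 10))
  aliased <- tab; aliased$TSC <- aliased$ASD
  expect_error(fit_ancova(aliased, "y"), "aliased|rank")
  none <- tab; none$ASD <- 0; none$TSC <- 0
  expect_error(fit_ancova(none, "y"), "constant")
  expect_error(fit_ancova(tab[1:5, ], "y"), "fewer than 8")
  expect_error(fit_ancova(tab, "nope"), "no such measure")
})

test_that("non-finite measure values are excluded listwise", {
  set.seed(45)
  tab <- simulate_cohort_table(c(10, 10, 10, 10))
  tab$y[c(3, 17)] <- NA
  fit <- fit_ancova(tab, "y")
  expect_equal(fit$n, 38)
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$df, 34)
})

test_that("callosal validation test is one-tailed with the swap identity", {
  same <- c(1, 2, 3, 4, 5)
  expect_equal(acc_validation_test(same, same)$p.value, 0.5)
  set.seed(46)
  a <- rnorm(16, 0.6, 0.1); b <- rnorm(46, 1.0, 0.1)
  t1 <- acc_validation_test(a, b)
  expect_lt(t1$p.value, 0.001)
  t2 <- acc_validation_test(b, a)
  expect_equal(t1$p.value + t2$p.value, 1, tolerance = 1e-12)
})

test_that("Fisher demographics match the hypergeometric enumeration oracle", {
  tab <- data.frame(ASD = rep(c(0, 1), each = 10), TSC = 0,
                    age = rnorm(20, 8),
                    sex = rep(c("M", "F"), 10))
  res <- demographic_tests(tab)
  expect_equal(res$p[res$variable == "sex" & res$condition == "ASD"], 1)

  # oracle: two-sided Fisher p = sum of table probabilities <= observed
  fisher_oracle <- function(m) {
    rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
    support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- dhyper(support, rs[1], rs[2], cs[1])
    obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(47)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher.test(m)$p.value, fisher_oracle(m), tolerance = 1e-9)
  }
})

test_that("age t-test p-values are uniform under the null", {
  set.seed(48)
  p <- replicate(300, {
    tab <- data.frame(ASD = rep(c(0, 1), each = 15), TSC = 0,
                      age = rnorm(30, 8, 2),
                      sex = sample(c("M", "F"), 30, TRUE))
    demographic_tests(tab)$p[2]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("subgroup post-hoc tests behave at the boundaries", {
  set.seed(49)
  tab <- simulate_cohort_table(c(10, 10, 10, 10), sigma = 1)
  res <- subgroup_posthoc(tab, "y", condition = "ASD")
  expect_s3_class(res, "htest")
  # identical subgroups: zero t, p = 1
  tab2 <- tab
  tab2$y <- 1 + tab2$age * 0
  tab2$y[tab2$ASD == 1] <- rep(c(1, 2, 3), length.out = sum(tab2$ASD == 1))
  tab2$y[tab2$ASD == 1 & tab2$TSC == 1] <-
    tab2$y[tab2$ASD == 1 & tab2$TSC == 0]
  expect_equal(subgroup_posthoc(tab2, "y", condition = "ASD")$p.value, 1)
  # empty subgroup is skipped with a message
  tab3 <- tab[!(tab$ASD == 1 & tab$TSC == 1), ]
  expect_message(res3 <- subgroup_posthoc(tab3, "y", condition = "ASD"),
                 "empty subgroup")
  expect_null(res3)
})

test_that("a purely additive condition effect creates no subgroup difference", {
  # ASD effect only: ASD-with-TSC and ASD-without-TSC subgroups share the
  # same distribution, so the post-hoc comparison stays at the alpha level
  set.seed(50)
  rej <- replicate(200, {
    tab <- simulate_cohort_table(c(12, 12, 12, 12), beta_asd = -0.8,
                                 beta_tsc = 0, beta_age = 0)
    subgroup_posthoc(tab, "y", condition = "ASD")$p.value < 0.05
  })
  expect_lt(mean(rej), 0.12)
})

test_that("subgroup detection rate rises with the interaction size", {
  set.seed(52)
  rate <- vapply(c(0, 0.8, 2), function(inter) {
    mean(replicate(100, {
      tab <- simulate_cohort_table(c(12, 12, 12, 12), beta_asd = -0.8,
                                   beta_tsc = 0, beta_age = 0)
      tab$y[tab$ASD == 1 & tab$TSC == 1] <-
        tab$y[tab$ASD == 1 & tab$TSC == 1] + inter
      subgroup_posthoc(tab, "y", condition = "ASD")$p.value < 0.05
    }))
  }, numeric(1))
  expect_lt(rate[1], 0.15)
  expect_gt(rate[3], rate[1])
  expect_gt(rate[3], 0.8)
})

test_that("the null rejection rate of the ASD coefficient is near alpha", {
  set.seed(51)
  rej <- replicate(300, {
    tab <- simulate_cohort_table(beta_asd = 0, beta_tsc = 0, beta_age = 0)
    fit <- fit_ancova(tab, "y")
    fit$coefficients$p[fit$coefficients$term == "ASD"] < 0.05
  })
  expect_gt(mean(rej), 0.015)
  expect_lt(mean(rej), 0.10)
})
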