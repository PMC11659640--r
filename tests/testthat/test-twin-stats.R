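test_that("descriptive table computes n-1 SDs and consistent groupings", {
  cohort <- tibble::tibble(
    twin_id = c("A_1", "A_2", "B_1", "B_2"),
    family_id = rep(c("A", "B"), each = 2),
    zygosity = rep(c("MZ", "DZ"), each = 2),
    sex = c("M", "M", "F", "F"),
    stage = "primary",
    posterior_depth = c(2, 4, 2, 4)
  )
  tab <- descriptive_table(cohort)
  ov <- tab[tab$group == "Overall", ]
  expect_equal(ov$mean, 3)
  expect_equal(ov$sd, sd(c(2, 4, 2, 4)))
  # Overall equals pooled M+F
  m <- tab[tab$group == "M", ]
  f <- tab[tab$group == "F", ]
  expect_equal(ov$n, m$n + f$n)
  expect_equal(ov$mean, (m$n * m$mean + f$n * f$mean) / (m$n + f$n))
})

test_that("simulated cohorts recover the generating stage means", {
  cohort <- simulate_cohort(seed = 12)
  tab <- descriptive_table(cohort, traits = "volume")
  ov <- tab[tab$group == "Overall" & tab$stage == "primary", ]
  se <- 471.7 / sqrt(ov$n) # generating SD (twin clustering inflates this a bit)
  expect_lt(abs(ov$mean - 2630.1), 3 * se)
})

test_that("percent change reproduces the published arithmetic and is scale-free", {
  expect_equal(percent_change(6169.4, 2630.1), 134.6)
  expect_equal(percent_change(1266.8, 753.7), 68.1)
  expect_equal(percent_change(5, 5), 0)
  k <- 3.7
  expect_equal(percent_change(k * 6169.4, k * 2630.1), 134.6)
  expect_error(percent_change(1, 0), class = "palatwin_spec_error")
})

test_that("one-way ICC matches the aov oracle and is exchangeable", {
  # perfect within-pair agreement
  x <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(icc_oneway(x)$icc, 1)

  set.seed(8)
  pairs <- cbind(rnorm(5, 10), rnorm(5, 10))
  res <- icc_oneway(pairs)
  # independent ANOVA-table oracle
  df <- data.frame(
    y = as.vector(t(pairs)),
    pair = factor(rep(1:5, each = 2))
  )
  an <- anova(stats::aov(y ~ pair, data = df))
  msb <- an["pair", "Mean Sq"]
  msw <- an["Residuals", "Mean Sq"]
  expect_equal(res$icc, (msb - msw) / (msb + msw), tolerance = 1e-12)
  expect_equal(res$ms_between, msb, tolerance = 1e-12)
  expect_equal(res$ms_within, msw, tolerance = 1e-12)

  # swapping members within pairs changes nothing
  swapped <- pairs
  swapped[c(2, 4), ] <- swapped[c(2, 4), 2:1]
  expect_equal(icc_oneway(swapped), res)

  expect_warning(icc_oneway(cbind(rep(1, 3), rep(1, 3))), "undefined")
})

test_that("ICC is consistent for the generating pair correlation", {
  p <- simulate_twin_pairs(50000, 2, c(A = 0.84, E = 0.16), seed = 31)
  sp <- split_pairs(p)
  expect_equal(icc_oneway(sp$mz)$icc, 0.84, tolerance = 0.01)
})

test_that("method error separates random from systematic components", {
  expect_equal(
    unlist(method_error(c(1, 2, 3), c(1, 2, 3))[, c("dahlberg", "mme")]),
    c(dahlberg = 0, mme = 0)
  )
  me <- method_error(c(1, 0), c(0, 1)) # d = (+1, -1)
  expect_equal(me$dahlberg, sqrt(2 / 4), tolerance = 1e-12)
  expect_equal(me$mme, 1, tolerance = 1e-12)
  # constant offset: all systematic, no random error
  s1 <- c(4, 7, 9, 12)
  off <- method_error(s1 + 2, s1)
  expect_equal(off$dahlberg, 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(off$mme, 0)
  # algebraic identity: dahlberg^2 = mme^2 (n-1)/n + dbar^2 / 2
  set.seed(99)
  a <- rnorm(20)
  b <- rnorm(20)
  me2 <- method_error(a, b)
  dbar <- mean(a - b)
  expect_equal(me2$dahlberg^2, me2$mme^2 * 19 / 20 + dbar^2 / 2, tolerance = 1e-10)
  expect_error(method_error(1:3, 1:4), class = "palatwin_spec_error")
})

test_that("group comparisons give t = 0 for identical groups and respect Bonferroni", {
  cohort <- tibble::tibble(
    twin_id = paste0("F", rep(1:20, each = 2), "_", rep(1:2, 20)),
    family_id = paste0("F", rep(1:20, each = 2)),
    zygosity = rep(c("MZ", "DZ"), each = 20),
    sex = rep(c("M", "F"), 20),
    stage = "primary",
    posterior_depth = rep(c(9, 10, 11, 12), 10)
  )
  cohort$posterior_depth[cohort$zygosity == "DZ"] <-
    cohort$posterior_depth[cohort$zygosity == "MZ"]
  cmp <- group_comparisons(cohort, comparisons = "MZ_vs_DZ", m_tests = 1)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
})

test_that("the null t-test rejection rate is nominal and Bonferroni controls the family", {
  set.seed(123)
  raw <- vapply(1:1000, function(i) {
    stats::t.test(rnorm(30), rnorm(30))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(raw), 0.035)
  expect_lt(mean(raw), 0.065)

  fam <- vapply(1:400, function(i) {
    any(vapply(1:7, function(j) {
      stats::t.test(rnorm(25), rnorm(25))$p.value < 0.05 / 7
    }, logical(1)))
  }, logical(1))
  expect_lte(mean(fam), 0.09)
})

test_that("the random-intercept model recovers fixed effects and handles boundaries", {
  spec <- dplyr::filter(default_cohort_spec(), .data$trait == "posterior_depth",
    .data$stage == "primary")
  np <- tibble::tibble(stage = "primary", n_mz_pairs = 250L, n_dz_pairs = 250L)
  cohort <- simulate_cohort(spec, n_pairs = np, seed = 77)
  cohort$posterior_depth <- cohort$posterior_depth + ifelse(cohort$sex == "M", 1, 0)
  fit <- fit_twin_lmm(cohort, "posterior_depth")
  sexrow <- fit$fixed[fit$fixed$term == "sexM", ]
  expect_lt(abs(sexrow$estimate - 1), 2 * sexrow$std_error)
  expect_gt(fit$var_family, 0)

  # duplicating every family leaves the coefficients unchanged
  dup <- cohort
  dup$family_id <- paste0(dup$family_id, "bis")
  dup$twin_id <- paste0(dup$twin_id, "bis")
  fit2 <- fit_twin_lmm(dplyr::bind_rows(cohort, dup), "posterior_depth")
  expect_equal(fit2$fixed$estimate, fit$fixed$estimate, tolerance = 1e-6)

  # no family effect: variance estimate collapses towards the boundary
  cohort0 <- cohort
  set.seed(5)
  cohort0$posterior_depth <- rnorm(nrow(cohort0))
  fit0 <- fit_twin_lmm(cohort0, "posterior_depth")
  expect_lt(fit0$var_family / fit0$var_residual, 0.05)
})
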