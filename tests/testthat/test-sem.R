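test_that("expected pair covariance encodes the classical twin correlations", {
  dz_a <- twin_covariance(a = 1, e = 0, zygosity = "DZ")
  expect_equal(dz_a[1, 2] / dz_a[1, 1], 0.5)
  dz_d <- twin_covariance(d = 1, e = 0, zygosity = "DZ")
  expect_equal(dz_d[1, 2] / dz_d[1, 1], 0.25)
  expect_equal(twin_covariance(e = 1, zygosity = "MZ"), diag(2))
  expect_equal(twin_covariance(e = 1, zygosity = "DZ"), diag(2))

  # PSD with correlation <= 1 for arbitrary non-negative paths
  set.seed(2)
  for (i in 1:25) {
    p <- runif(3, 0, 3) # a, c, e (no d alongside c)
    m <- twin_covariance(a = p[1], c = p[2], e = p[3], zygosity = sample(c("MZ", "DZ"), 1))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
    expect_lte(abs(m[1, 2]) / m[1, 1], 1)
  }
})

test_that("independent pairs drive the additive component to the boundary", {
  p <- simulate_twin_pairs(300, 300, c(E = 1), seed = 40)
  sp <- split_pairs(p)
  fit <- fit_twin_model(sp$mz, sp$dz, "AE", conf_int = FALSE)
  expect_lt(fit$standardized[["A"]], 0.08)
  expect_gt(fit$standardized[["E"]], 0.92)
  expect_equal(sum(fit$standardized), 1, tolerance = 1e-9)
})

test_that("the AE optimum matches a dense grid search on a tiny fixture", {
  mz <- cbind(
    c(10.9, 9.8, 11.4, 10.2, 10.8, 9.5),
    c(11.1, 10.0, 11.2, 10.5, 10.4, 9.9)
  )
  dz <- cbind(
    c(10.1, 11.0, 9.2, 10.7, 11.5, 9.9),
    c(10.9, 10.2, 9.8, 11.4, 10.6, 10.4)
  )
  fit <- fit_twin_model(mz, dz, "AE", conf_int = FALSE)

  # three-stage refined grid over (a, e, mu) on the raw likelihood
  lo <- c(0.01, 0.05, 9)
  hi <- c(2, 2, 12)
  best <- c(NA, NA, NA)
  for (stage in 1:3) {
    as <- seq(lo[1], hi[1], length.out = 31)
    es <- seq(lo[2], hi[2], length.out = 31)
    mus <- seq(lo[3], hi[3], length.out = 31)
    vals <- expand.grid(a = as, e = es, mu = mus)
    m2 <- mapply(function(a, e, mu) m2ll_ae_direct(mz, dz, a, e, mu),
      vals$a, vals$e, vals$mu
    )
    b <- vals[which.min(m2), ]
    span <- (hi - lo) / 10
    lo <- pmax(unlist(b) - span, c(1e-4, 1e-3, 8))
    hi <- unlist(b) + span
    best <- list(par = unlist(b), m2ll = min(m2))
  }
  expect_lte(fit$minus2ll, best$m2ll + 1e-6) # optimizer at least as good
  expect_equal(fit$minus2ll, best$m2ll, tolerance = 1e-4)
})

test_that("nesting inequalities hold against sub-models and the saturated model", {
  p <- simulate_twin_pairs(150, 150, c(A = 0.5, C = 0.2, E = 0.3), seed = 55)
  sp <- split_pairs(p)
  fits <- lapply(c("ACE", "ADE", "AE", "CE", "E"), function(m) {
    fit_twin_model(sp$mz, sp$dz, m, conf_int = FALSE)
  })
  names(fits) <- c("ACE", "ADE", "AE", "CE", "E")
  sat <- saturated_m2ll(sp$mz, sp$dz)
  for (f in fits) expect_gte(f$minus2ll, sat - 1e-6)
  expect_gte(fits$AE$minus2ll, fits$ACE$minus2ll - 1e-6)
  expect_gte(fits$AE$minus2ll, fits$ADE$minus2ll - 1e-6)
  expect_gte(fits$CE$minus2ll, fits$ACE$minus2ll - 1e-6)
  expect_gte(fits$E$minus2ll, fits$AE$minus2ll - 1e-6)
  for (f in fits) {
    expect_equal(sum(f$standardized), 1, tolerance = 1e-9)
    expect_equal(f$aic, f$minus2ll + 2 * f$n_free)
    expect_true(all(f$standardized >= 0))
  }
})

test_that("the saturated closed form equals direct density evaluation", {
  p <- simulate_twin_pairs(40, 40, c(A = 0.6, E = 0.4), seed = 60)
  sp <- split_pairs(p)
  direct <- function(x) {
    x <- as.matrix(x)
    mu <- colMeans(x)
    S <- crossprod(sweep(x, 2, mu)) / nrow(x)
    Sinv <- solve(S)
    -2 * sum(apply(x, 1, function(r) {
      d <- r - mu
      -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(d) %*% Sinv %*% d)
    }))
  }
  expect_equal(
    saturated_m2ll(sp$mz, sp$dz),
    direct(sp$mz) + direct(sp$dz),
    tolerance = 1e-8
  )
})

test_that("the likelihood is exactly exchangeable in twin order", {
  p <- simulate_twin_pairs(50, 50, c(A = 0.7, E = 0.3), seed = 70)
  sp <- split_pairs(p)
  fit1 <- fit_twin_model(sp$mz, sp$dz, "AE", conf_int = FALSE)
  mz_sw <- as.matrix(sp$mz)[, 2:1]
  dz_sw <- as.matrix(sp$dz)
  dz_sw[seq(1, 50, 2), ] <- dz_sw[seq(1, 50, 2), 2:1]
  fit2 <- fit_twin_model(mz_sw, dz_sw, "AE", conf_int = FALSE)
  expect_identical(fit1$minus2ll, fit2$minus2ll)
  expect_identical(fit1$standardized, fit2$standardized)
})

test_that("heritability is the standardized additive share, excluding dominance", {
  p <- simulate_twin_pairs(200, 200, c(A = 0.5, D = 0.3, E = 0.2), seed = 80)
  sp <- split_pairs(p)
  fit <- fit_twin_model(sp$mz, sp$dz, "ADE", conf_int = FALSE)
  expect_equal(heritability(fit), fit$standardized[["A"]])
  expect_lt(heritability(fit), fit$standardized[["A"]] + fit$standardized[["D"]] + 1e-12)
  f0 <- fit_twin_model(split_pairs(simulate_twin_pairs(50, 50, c(E = 1), seed = 81))$mz,
    split_pairs(simulate_twin_pairs(50, 50, c(E = 1), seed = 81))$dz, "E",
    conf_int = FALSE
  )
  expect_equal(heritability(f0), 0)
})

test_that("tidy and glance return the broom-shaped summaries", {
  p <- simulate_twin_pairs(60, 60, c(A = 0.8, E = 0.2), seed = 90)
  sp <- split_pairs(p)
  fit <- fit_twin_model(sp$mz, sp$dz, "AE")
  td <- tidy(fit)
  expect_identical(td$component, c("A", "E"))
  expect_true(all(td$estimate >= td$conf.low & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_identical(gl$model, "AE")
  expect_equal(gl$aic, fit$aic)
  expect_true(gl$converged)
})
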