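test_that("twin-pair simulation is deterministic and validates components", {
  a <- simulate_twin_pairs(20, 30, c(A = 0.6, E = 0.4), mean = 10, sd = 2, seed = 9)
  b <- simulate_twin_pairs(20, 30, c(A = 0.6, E = 0.4), mean = 10, sd = 2, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 50L)
  expect_equal(sum(a$zygosity == "MZ"), 20L)

  expect_error(
    simulate_twin_pairs(5, 5, c(A = 0.5, E = 0.4), seed = 1),
    class = "palatwin_spec_error"
  )
  expect_error(
    simulate_twin_pairs(5, 5, c(A = 0.2, C = 0.2, D = 0.2, E = 0.4), seed = 1),
    class = "palatwin_spec_error"
  )
  expect_error(
    simulate_twin_pairs(5, 5, c(A = -0.1, E = 1.1), seed = 1),
    class = "palatwin_spec_error"
  )
})

test_that("sample ICCs converge to the model-implied twin correlations", {
  # E-only: independence
  p0 <- simulate_twin_pairs(10000, 2, c(E = 1), seed = 21)
  sp0 <- split_pairs(p0)
  expect_lt(abs(icc_oneway(sp0$mz)$icc), 3 / sqrt(10000))

  # strong additive model: r_MZ = 0.89, r_DZ = 0.445
  p1 <- simulate_twin_pairs(50000, 50000, c(A = 0.89, E = 0.11), seed = 22)
  sp1 <- split_pairs(p1)
  expect_equal(icc_oneway(sp1$mz)$icc, 0.89, tolerance = 0.01)
  expect_equal(icc_oneway(sp1$dz)$icc, 0.445, tolerance = 0.01)
})

test_that("the default longitudinal cohort reproduces the study record counts", {
  cohort <- simulate_cohort(seed = 4)
  counts <- table(cohort$stage)
  expect_equal(as.integer(counts[c("primary", "mixed", "permanent")]), c(456L, 450L, 340L))
  # exactly two twins per family-stage, constant zygosity
  expect_identical(validate_cohort(cohort), cohort)
  # MZ co-twins share sex
  mz <- cohort[cohort$zygosity == "MZ", ]
  sex_per_pair <- tapply(mz$sex, paste(mz$family_id, mz$stage), dplyr::n_distinct)
  expect_true(all(sex_per_pair == 1L))
  # determinism
  expect_identical(cohort, simulate_cohort(seed = 4))
  expect_false(identical(cohort, simulate_cohort(seed = 5)))
})

test_that("families are nested across stages when counts shrink", {
  spec <- dplyr::filter(default_cohort_spec(), .data$trait == "posterior_depth")
  np <- tibble::tibble(
    stage = c("primary", "mixed", "permanent"),
    n_mz_pairs = c(30L, 30L, 20L), n_dz_pairs = c(40L, 40L, 25L)
  )
  cohort <- simulate_cohort(spec, n_pairs = np, seed = 6)
  fam <- function(st) unique(cohort$family_id[cohort$stage == st])
  expect_true(all(fam("permanent") %in% fam("mixed")))
  expect_setequal(fam("mixed"), fam("primary"))
})

test_that("attrition is completely at random (nominal type-I error of the follow-up test)", {
  # an E-only trait keeps co-twins independent, so the individual-level
  # t-test is exact and its null rejection rate should be nominal
  spec <- tibble::tibble(
    trait = "posterior_depth", stage = c("mixed", "permanent"),
    mean = c(10.6, 13.2), sd = c(1.7, 2.1), A = 0, C = 0, D = 0, E = 1
  )
  np <- tibble::tibble(
    stage = c("mixed", "permanent"),
    n_mz_pairs = c(30L, 18L), n_dz_pairs = c(30L, 18L)
  )
  rejections <- vapply(1:400, function(i) {
    cohort <- simulate_cohort(spec, n_pairs = np, seed = 1000 + i)
    cmp <- group_comparisons(cohort,
      traits = "posterior_depth",
      comparisons = "attrited_vs_retained", m_tests = 1
    )
    cmp$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})
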