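test_that("linear predictor matches the dot-product oracle", {
  single <- clock_definition("one", intercept = 0,
                             coefficients = c(cg1 = 1))
  b <- matrix(0.5, 1, 1, dimnames = list("cg1", "s1"))
  expect_equal(unname(linear_predictor(b, single)), 0.5)

  set.seed(8)
  w <- setNames(rnorm(20), sprintf("cg%02d", 1:20))
  clock <- clock_definition("c20", intercept = 1.7, coefficients = w)
  bm <- matrix(runif(20 * 6), nrow = 20,
               dimnames = list(names(w), paste0("s", 1:6)))
  oracle <- 1.7 + drop(t(bm) %*% w)
  expect_equal(unname(linear_predictor(bm, clock)), unname(oracle),
               tolerance = 1e-12)
  # all-zero betas return the intercept
  expect_equal(unname(linear_predictor(bm * 0, clock)), rep(1.7, 6))
})

test_that("missing CpGs are mean-imputed and coverage is enforced", {
  w <- setNames(c(1, 1, 1, 1), paste0("cg", 1:4))
  clock <- clock_definition("m", intercept = 0, coefficients = w)
  bm <- matrix(0.25, 4, 3, dimnames = list(names(w), paste0("s", 1:3)))
  bm[1, 1] <- NA                     # imputed from samples 2-3 -> 0.25
  expect_equal(unname(linear_predictor(bm, clock)), rep(1, 3))
  bm[1:3, 2] <- NA
  expect_error(linear_predictor(bm, clock, min_coverage = 0.5), "s2")
})

test_that("age anti-transform is the piecewise inverse and monotone", {
  expect_equal(inverse_age_transform(0), 20)
  expect_equal(inverse_age_transform(1), 41)
  grid <- seq(-5, 5, by = 0.01)
  v <- inverse_age_transform(grid)
  expect_true(all(diff(v) > 0))
  ages <- seq(1, 95, by = 0.5)
  expect_equal(inverse_age_transform(forward_age_transform(ages)), ages,
               tolerance = 1e-10)
})

test_that("age adjustment reproduces the closed-form OLS residuals", {
  ages <- c(30, 40, 50)
  est <- c(32, 40, 54)
  # slope 1.1, intercept -2 -> fitted (31, 42, 53)
  expect_equal(unname(age_adjust(est, ages)), c(1, -2, 1),
               tolerance = 1e-12)
  expect_equal(unname(age_adjust(ages, ages)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(age_adjust(ages + 5, ages)), rep(0, 3),
               tolerance = 1e-12)
  expect_error(age_adjust(est, rep(40, 3)), "constant")
})

test_that("IEAA purges cell composition and matches the OLS oracle", {
  set.seed(9)
  n <- 30
  ages <- runif(n, 20, 80)
  cells <- matrix(rgamma(n * 4, 2), n)
  cells <- cells / rowSums(cells)
  colnames(cells) <- paste0("c", 1:4)
  est <- 0.9 * ages + 3 * cells[, 1] - 2 * cells[, 2]
  r <- ieaa(est, ages, cells)
  expect_lt(max(abs(r)), 1e-8)       # pure function of age + cells
  est2 <- est + rnorm(n)
  oracle <- residuals(lm(est2 ~ ages + cells[, 1:3]))
  expect_equal(unname(ieaa(est2, ages, cells)), unname(oracle),
               tolerance = 1e-10)
  # equal cell fractions reduce to plain age adjustment
  flat <- matrix(0.25, n, 4)
  expect_equal(unname(ieaa(est2, ages, flat)),
               unname(age_adjust(est2, ages)), tolerance = 1e-10)
})

test_that("EEAA with weight (1,0,0,0) equals plain age adjustment", {
  set.seed(10)
  n <- 24
  ages <- runif(n, 20, 80)
  hannum <- ages + rnorm(n, sd = 3)
  cells <- matrix(rnorm(n * 3), n)
  expect_equal(unname(eeaa(hannum, ages, cells, weights = c(1, 0, 0, 0))),
               unname(age_adjust(hannum, ages)), tolerance = 1e-10)
  # explicit-weight oracle recomputation
  wts <- c(2, 1, 1, 1)
  comp <- cbind(hannum, cells)
  z <- scale(comp)
  wavg <- drop(z %*% wts) / sum(wts)
  oracle <- age_adjust(wavg * sd(hannum) + mean(hannum), ages)
  expect_equal(unname(eeaa(hannum, ages, cells, weights = wts)),
               unname(oracle), tolerance = 1e-10)
})

test_that("compute_all yields residual columns orthogonal to age", {
  spec <- cohort_spec()
  cohort <- gen_cohort(spec, seed = 13)
  clocks <- gen_default_clocks(seed = 14)
  betas <- gen_betas(cohort, clocks, spec, noise_sd = 0.02, seed = 15)
  est <- compute_all(betas, clocks, cohort)
  expect_equal(dim(est), c(48, 6))
  for (cn in setdiff(names(est), "sample_id")) {
    expect_lt(abs(mean(est[[cn]])), 1e-10)
    expect_lt(abs(cor(est[[cn]], cohort$age)), 1e-8)
  }
  # DNAm age correlates strongly with age at low noise
  hannum <- clocks[["AgeAccelHannum"]]
  expect_gt(cor(dnam_estimate(betas, hannum), cohort$age), 0.9)
})
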