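test_that("single-predictor LMG equals the simple-regression R2", {
  set.seed(50)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30)
  res <- lmg(y, matrix(x, dimnames = list(NULL, "x")))
  expect_equal(unname(res$lmg_raw), summary(lm(y ~ x))$r.squared,
               tolerance = 1e-12)
})

test_that("orthogonal standardised predictors get their marginal R2", {
  set.seed(51)
  n <- 64
  raw <- matrix(rnorm(n * 3), n)
  X <- qr.Q(qr(scale(raw, scale = FALSE)))[, 1:3]   # exactly orthogonal
  colnames(X) <- c("a", "b", "c")
  y <- X %*% c(3, 2, 1) + rnorm(n)
  res <- lmg(y, X)
  marginal <- vapply(1:3, function(k) {
    summary(lm(y ~ X[, k]))$r.squared
  }, numeric(1))
  expect_equal(unname(res$lmg_raw), marginal, tolerance = 1e-10)
})

test_that("LMG equals the ordering-enumeration oracle on correlated designs", {
  set.seed(52)
  for (p in 2:4) {
    n <- 40
    base <- matrix(rnorm(n * p), n)
    X <- base + rnorm(n)               # induce correlation between columns
    colnames(X) <- paste0("x", 1:p)
    y <- X %*% runif(p, -1, 1) + rnorm(n)
    res <- lmg(y, X)
    expect_equal(unname(res$lmg_raw), lmg_ordering_oracle(y, X),
                 tolerance = 1e-10)
    expect_equal(sum(res$lmg_raw), res$r2_full, tolerance = 1e-10)
    expect_equal(sum(res$lmg_norm), 1, tolerance = 1e-10)
  }
})

test_that("LMG is equivariant under predictor permutation", {
  set.seed(53)
  X <- matrix(rnorm(120), 40)
  colnames(X) <- c("a", "b", "c")
  y <- X %*% c(1, 2, 3) + rnorm(40)
  r1 <- lmg(y, X)
  perm <- c("c", "a", "b")
  r2 <- lmg(y, X[, perm])
  expect_equal(r2$lmg_raw[colnames(X)], r1$lmg_raw[colnames(X)],
               tolerance = 1e-12)
})

test_that("degenerate designs are rejected with named columns", {
  set.seed(54)
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(lmg(rnorm(20), X), "constant.*b")
  X2 <- cbind(a = rnorm(20), b = rnorm(20))
  X2 <- cbind(X2, c = X2[, "a"] + X2[, "b"])
  expect_error(lmg(rnorm(20), X2), "collinear")
  expect_error(lmg(rnorm(20), matrix(rnorm(20 * 16), 20)), "p > 15|n > p")
})

test_that("model frames apply the stated encodings", {
  cohort <- tiny_cohort(n_per_group = 8)
  cohort$inbreeding_f <- runif(16, 0, 0.1)
  cohort$anc_AMR <- ifelse(cohort$population == "groupA", 1,
                           runif(16, 0.4, 0.7))
  cohort$anc_EUR <- 1 - cohort$anc_AMR
  frames <- build_model_frames(cohort)
  expect_named(frames, c("joint", "group1", "group2"))
  expect_identical(colnames(frames$joint$X), c("Pop", "Female", "T.cruzi"))
  expect_equal(frames$joint$X[, "Pop"],
               as.numeric(cohort$population == "groupA"))
  expect_equal(frames$joint$X[, "Female"], as.numeric(cohort$sex == "F"))
  expect_identical(colnames(frames$group1$X),
                   c("Inbreed", "Paraje", "Female", "T.cruzi"))
  rows_a <- frames$group1$rows
  expect_equal(frames$group1$X[, "Paraje"],
               as.numeric(cohort$paraje[rows_a] == "urban"))
  expect_identical(colnames(frames$group2$X),
                   c("EUR", "AMR", "Female", "T.cruzi"))
  cohort2 <- cohort
  cohort2$inbreeding_f <- NULL
  expect_error(build_model_frames(cohort2), "inbreeding_f")
})

test_that("planted effects surface as the top predictor", {
  set.seed(55)
  cohort <- gen_cohort(cohort_spec(), seed = 56)
  cohort$inbreeding_f <- runif(48, 0, 0.1)
  cohort$anc_AMR <- ifelse(cohort$population == "groupA", 1,
                           runif(48, 0.4, 0.7))
  cohort$anc_EUR <- 1 - cohort$anc_AMR
  est <- data.frame(
    sample_id = cohort$sample_id,
    pop_driven = 3 * (cohort$population == "groupA") + rnorm(48, sd = 0.5),
    noise = rnorm(48))
  class(est) <- c("estimator_table", class(est))
  frames <- build_model_frames(cohort)
  rep <- importance_report(frames, est)
  joint_pop <- rep[rep$model == "joint" & rep$estimator == "pop_driven", ]
  expect_identical(joint_pop$top_predictor, "Pop")
  noise_row <- rep[rep$model == "joint" & rep$estimator == "noise", ]
  expect_lt(noise_row$pct_total_variance, 0.25)
  # paraje planted within the indigenous-role group
  est$paraje_driven <- 2 * (cohort$paraje == "urban") + rnorm(48, sd = 0.3)
  rep2 <- importance_report(frames, est)
  g1 <- rep2[rep2$model == "group1" & rep2$estimator == "paraje_driven", ]
  expect_identical(g1$top_predictor, "Paraje")
})
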