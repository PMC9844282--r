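test_that("prepare_phenotypes applies sleep cuts and seeded answer selection", {
  raw <- data.frame(sample = c("a", "b", "c", "d", "d"),
                    age = c(30, 40, 50, 60, 71),
                    sex = c(0, 1, 0, 1, 1),
                    sleep_duration = c(3.0, 16.0, 3.5, 7, 8),
                    stringsAsFactors = FALSE)
  ph <- prepare_phenotypes(raw, seed = 99)
  expect_equal(nrow(ph), 4)
  expect_true(is.na(ph$sleep_duration[ph$sample == "a"]))  # 3.0 excluded
  expect_true(is.na(ph$sleep_duration[ph$sample == "b"]))  # 16.0 excluded
  expect_equal(ph$sleep_duration[ph$sample == "c"], 3.5)   # retained
  expect_equal(unname(attr(ph, "exclusions")["sleep_range"]), 2L)
  # duplicate-wave participant: exactly one answer survives, reproducibly
  expect_true(ph$sleep_duration[ph$sample == "d"] %in% c(7, 8))
  ph2 <- prepare_phenotypes(raw, seed = 99)
  expect_identical(ph$sleep_duration, ph2$sleep_duration)
  # covariates come from the first row per sample
  expect_equal(ph$age[ph$sample == "d"], 60)
  # a different seed can pick the other answer; both draws stay in range
  picks <- vapply(1:20, function(s) {
    prepare_phenotypes(raw, seed = s)$sleep_duration[4]
  }, numeric(1))
  expect_true(all(picks %in% c(7, 8)))
  expect_true(length(unique(picks)) == 2)  # both answers reachable

  # non-numeric trait values dropped and counted
  raw2 <- data.frame(sample = c("a", "b"), sleep_duration = c("7.5", "lots"),
                     stringsAsFactors = FALSE)
  ph3 <- prepare_phenotypes(raw2, seed = 1)
  expect_equal(unname(attr(ph3, "exclusions")["non_numeric"]), 1L)
  expect_equal(ph3$sleep_duration, c(7.5, NA))
})

test_that("dichotomize implements every rule and partitions its input", {
  # chronotype: extremes only
  ct <- dichotomize(c(1, 2, 3, 4, NA), "chronotype_extremes")
  expect_equal(as.integer(ct), c(1L, NA, NA, 0L, NA))
  expect_error(dichotomize(5, "chronotype_extremes"), "5")
  # sleep: boundaries are inclusive
  sl <- dichotomize(c(6.0, 9.0, 7.5, 4, 10), "sleep_extremes")
  expect_equal(as.integer(sl), c(1L, 0L, NA, 1L, 0L))
  # FINRISK insomnia: 1 severe, 3 none, 2 excluded
  fi <- dichotomize(c(1, 2, 3), "insomnia_finrisk")
  expect_equal(as.integer(fi), c(1L, NA, 0L))
  # Health insomnia: 4/5 severe, 1 none, 2/3 excluded
  he <- dichotomize(c(1, 2, 3, 4, 5), "insomnia_health")
  expect_equal(as.integer(he), c(0L, NA, NA, 1L, 1L))
  # partition: cases + controls + excluded = n, for every rule
  vals <- list(chronotype_extremes = sample(1:4, 50, TRUE),
               sleep_extremes = runif(50, 3, 12),
               insomnia_finrisk = sample(1:3, 50, TRUE),
               insomnia_health = sample(1:5, 50, TRUE))
  for (rule in names(vals)) {
    lab <- dichotomize(vals[[rule]], rule)
    expect_equal(sum(lab == 1, na.rm = TRUE) + sum(lab == 0, na.rm = TRUE) +
                   sum(is.na(lab)), 50)
  }
})

test_that("linear incremental R2 matches the normal-equations oracle and its null/perfect limits", {
  withr::with_seed(50, {
    n <- 40
    covars <- data.frame(age = runif(n, 25, 74), sex = rbinom(n, 1, 0.5),
                         pc1 = rnorm(n))
    prs <- rnorm(n)
    y <- 0.5 * prs + 0.01 * covars$age + 0.3 * covars$sex + rnorm(n)
  })
  rep <- linear_incremental_r2(y, prs, covars)
  X_full <- cbind(1, prs, as.matrix(covars))
  X_base <- cbind(1, as.matrix(covars))
  expect_equal(rep$r2_full, oracle_ols_r2(X_full, y), tolerance = 1e-10)
  expect_equal(rep$r2_base, oracle_ols_r2(X_base, y), tolerance = 1e-10)
  expect_equal(rep$r2_incremental, rep$r2_full - rep$r2_base, tolerance = 1e-12)
  expect_equal(rep$n, 40)

  # y = PRS exactly, no covariates: increment is 1
  rep2 <- suppressWarnings(linear_incremental_r2(prs, prs))
  expect_equal(rep2$r2_incremental, 1, tolerance = 1e-9)

  # permuted PRS: increment ~ 0 at large n
  withr::with_seed(51, {
    n <- 5000
    prs_big <- rnorm(n)
    y_big <- rnorm(n)
  })
  rep3 <- linear_incremental_r2(y_big, prs_big)
  expect_lt(rep3$r2_incremental, 0.005)

  # exact collinearity is a named error
  cov_bad <- data.frame(a = covars$age, b = covars$age * 2)
  expect_error(linear_incremental_r2(y, prs, cov_bad), "collinear")
})

test_that("ΔR2 and pseudo-R2 are invariant to affine rescaling of the PRS", {
  withr::with_seed(52, {
    n <- 300
    prs <- rnorm(n)
    y <- 0.3 * prs + rnorm(n)
    yb <- rbinom(n, 1, plogis(0.8 * prs))
    covars <- data.frame(age = runif(n, 20, 80))
  })
  r1 <- linear_incremental_r2(y, prs, covars)
  r2 <- linear_incremental_r2(y, 3.7 * prs - 11, covars)
  expect_equal(r1$r2_incremental, r2$r2_incremental, tolerance = 1e-10)
  l1 <- logistic_pseudo_r2(yb, prs, covars)
  l2 <- logistic_pseudo_r2(yb, 3.7 * prs - 11, covars)
  expect_equal(l1$pseudo_r2, l2$pseudo_r2, tolerance = 1e-8)
})

test_that("logistic pseudo-R2: zero for constant PRS, non-negative, matches IRLS oracle", {
  withr::with_seed(53, {
    n <- 200
    prs <- rnorm(n)
    covars <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
    yb <- rbinom(n, 1, plogis(-0.3 + prs))
  })
  # constant PRS -> d1 = d0 -> exactly 0
  rep0 <- logistic_pseudo_r2(yb, rep(1, n), covars)
  expect_identical(rep0$pseudo_r2, 0)
  rep <- logistic_pseudo_r2(yb, prs, covars)
  expect_gte(rep$pseudo_r2, 0)
  expect_lt(rep$pseudo_r2, 1)
  X_full <- cbind(1, prs, covars$age, covars$sex)
  X_base <- cbind(1, covars$age, covars$sex)
  expect_equal(rep$deviance_full, oracle_irls(X_full, yb)$deviance,
               tolerance = 1e-8)
  expect_equal(rep$deviance_base, oracle_irls(X_base, yb)$deviance,
               tolerance = 1e-8)
})

test_that("group_prs_compare reproduces the Welch formulas and degenerate cases", {
  a <- c(1.2, 0.8, 1.1, 0.9, 1.3, 1.0, 1.15, 0.95, 1.05, 1.1)
  b <- c(0.7, 0.9, 0.6, 0.8, 0.75, 0.85, 0.65, 0.9, 0.7, 0.8)
  prs <- c(a, b)
  labels <- rep(c(1L, 0L), each = 10)
  got <- group_prs_compare(prs, labels)
  ora <- oracle_welch(a, b)
  expect_equal(got$t, ora$t, tolerance = 1e-12)
  expect_equal(got$df, ora$df, tolerance = 1e-12)
  expect_equal(got$pvalue, ora$p, tolerance = 1e-12)
  expect_equal(got$difference, mean(a) - mean(b))

  # identical constant groups: difference 0, p = 1
  same <- group_prs_compare(rep(c(1, 1), each = 5), rep(c(1L, 0L), each = 5))
  expect_equal(same$difference, 0)
  expect_equal(same$pvalue, 1)

  expect_error(group_prs_compare(prs, c(1L, rep(0L, 19))), "at least 2")

  # consistency: groups shifted by delta recover delta at large n
  withr::with_seed(54, {
    x0 <- rnorm(4000); x1 <- rnorm(4000) + 0.5
  })
  sh <- group_prs_compare(c(x1, x0), rep(c(1L, 0L), each = 4000))
  expect_equal(sh$difference, 0.5, tolerance = 3 * sqrt(2 / 4000) * 1.1)
})

test_that("tail_contrast nearest-rank tails behave at the edges", {
  # constant trait -> difference 0
  prs <- 1:100
  tc0 <- tail_contrast(prs, rep(7, 100), q = 0.05)
  expect_equal(tc0$difference, 0)
  expect_equal(unname(tc0$n), c(5, 5))
  # trait = prs: top mean > bottom mean
  tc1 <- tail_contrast(prs, as.numeric(prs), q = 0.05)
  expect_gt(tc1$difference, 0)
  expect_equal(unname(tc1$mean["top"]), 98)
  expect_equal(unname(tc1$mean["bottom"]), 3)
  # ties kept: groups may exceed q*n
  tc2 <- tail_contrast(c(rep(0, 10), 1:90), c(rep(1, 10), rep(0, 90)), q = 0.05)
  expect_equal(unname(tc2$n["bottom"]), 10)
  # degenerate PRS errors
  expect_error(tail_contrast(rep(1, 100), rnorm(100)), "degenerate")
  expect_error(tail_contrast(1:10, rnorm(10), q = 0.05), "too few")
})

test_that("tail_contrast agrees with the truncated-normal closed form at q = 0.5", {
  # symmetric bivariate normal: E[top - bottom] = 2*rho*sigma*phi(0)/0.5
  rho <- 0.3; sigma <- 1
  withr::with_seed(55, {
    n <- 40000
    prs <- rnorm(n)
    trait <- rho * prs + sqrt(1 - rho^2) * rnorm(n)
  })
  tc <- tail_contrast(prs, trait, q = 0.5)
  expected <- 2 * rho * sigma * dnorm(0) / 0.5
  se <- sqrt(tc$sd["top"]^2 / tc$n["top"] + tc$sd["bottom"]^2 / tc$n["bottom"])
  expect_lt(abs(tc$difference - expected), 3 * se)
})
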