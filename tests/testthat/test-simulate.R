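small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_discovery = 500, n_target = 300, n_variants = 100,
                   block_size = 20, rho = 0.8, seed = 7)
  defaults[names(args)] <- args
  if (is.null(defaults$traits)) {
    tr <- default_sim_traits()
    for (nm in names(tr)) {
      tr[[nm]]$m_causal <- min(tr[[nm]]$m_causal, defaults$n_variants %/% 2)
    }
    defaults$traits <- tr
  }
  do.call(sim_config, defaults)
}

test_that("simulate_genotypes is seed-deterministic with valid dosages and metadata", {
  cfg <- small_cfg()
  g1 <- simulate_genotypes(cfg, n = 50)
  g2 <- simulate_genotypes(cfg, n = 50)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))
  expect_true(all(g1$variants$info >= 0 & g1$variants$info <= 1))
  expect_false(any(is_strand_ambiguous(g1$variants$counted, g1$variants$other)))
  # different stage labels give independent cohorts
  g3 <- simulate_genotypes(cfg, n = 50, stage = "discovery-genotypes")
  expect_false(identical(g1$dosages, g3$dosages))
})

test_that("AR(1) block LD: rho = 0 gives independence, rho = 0.9 gives decaying LD", {
  cfg0 <- small_cfg(rho = 0, n_variants = 60, block_size = 30)
  g0 <- simulate_genotypes(cfg0, n = 5000)
  r2_adj0 <- mean(sapply(1:29, function(j) ld_r2(g0$dosages[, j],
                                                 g0$dosages[, j + 1])))
  expect_lt(r2_adj0, 0.01)  # ~1/n under independence

  cfg9 <- small_cfg(rho = 0.9, n_variants = 60, block_size = 30, seed = 8)
  g9 <- simulate_genotypes(cfg9, n = 5000)
  r2_adj <- mean(sapply(1:29, function(j) ld_r2(g9$dosages[, j],
                                                g9$dosages[, j + 1])))
  r2_far <- mean(sapply(1:20, function(j) ld_r2(g9$dosages[, j],
                                                g9$dosages[, j + 10])))
  expect_gt(r2_adj, 0.3)
  expect_gt(r2_adj, r2_far + 0.1)  # decays with distance
  # blocks are independent
  r2_cross <- ld_r2(g9$dosages[, 30], g9$dosages[, 31])
  expect_lt(r2_cross, 0.01)
})

test_that("simulate_phenotypes hits the configured heritability", {
  # h2 = 0: regression of y on g gives ~0
  cfg0 <- small_cfg(traits = list(t = list(h2 = 0, m_causal = 20,
                                           model = "continuous")))
  g <- simulate_genotypes(cfg0, n = 2000)
  ph0 <- simulate_phenotypes(g, cfg0, trait = "t")
  expect_true(all(ph0$truth$beta_allele == 0))
  expect_equal(ph0$truth$h2_realized, 0)

  # h2 = 0.5 at n = 10,000: sample R2 of y on g within 3 MC SE of 0.5
  cfg5 <- small_cfg(n_variants = 200, block_size = 20,
                    traits = list(t = list(h2 = 0.5, m_causal = 50,
                                           model = "continuous")),
                    seed = 9)
  g5 <- simulate_genotypes(cfg5, n = 10000)
  ph5 <- simulate_phenotypes(g5, cfg5, trait = "t")
  r2 <- summary(lm(ph5$latent ~ ph5$truth$genetic))$r.squared
  # var of sample R2 ~ 4 r2 (1-r2)^2 / n
  mc_se <- sqrt(4 * 0.5 * 0.25 / 10000)
  expect_lt(abs(r2 - 0.5), 3 * mc_se)
  expect_equal(ph5$truth$h2_realized, r2, tolerance = 0.02)

  # quantile cutpoints give the configured category frequencies
  cfgq <- small_cfg(traits = list(t = list(h2 = 0.3, m_causal = 20,
                                           model = "ordinal",
                                           cutpoints = c(0.25, 0.5, 0.75))))
  gq <- simulate_genotypes(cfgq, n = 4000)
  phq <- simulate_phenotypes(gq, cfgq, trait = "t")
  freq <- as.numeric(table(phq$value)) / 4000
  expect_equal(freq, rep(0.25, 4), tolerance = 0.02)
})

test_that("run_discovery_gwas equals the closed-form slope and its invariances", {
  # 6-sample worked case
  x <- c(0, 1, 2, 2, 1, 0)
  y <- c(1.0, 1.5, 2.5, 2.0, 1.2, 0.8)
  g <- dosage_matrix(matrix(x, ncol = 1),
                     data.frame(chrom = "1", pos = 100L, counted = "A",
                                other = "G", info = 0.97))
  ss <- run_discovery_gwas(g, y)
  beta_hand <- cov(x, y) / (var(x))
  expect_equal(ss$beta, beta_hand, tolerance = 1e-12)
  expect_equal(ss$eaf, mean(x) / 2)
  expect_equal(ss$info, 0.97)
  # SE against lm
  fit <- summary(lm(y ~ x))$coefficients
  expect_equal(ss$se, fit["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(ss$pvalue, fit["x", "Pr(>|t|)"], tolerance = 1e-10)

  # duplicating every sample leaves beta_hat unchanged
  g2 <- dosage_matrix(matrix(c(x, x), ncol = 1),
                      data.frame(chrom = "1", pos = 100L, counted = "A",
                                 other = "G", info = 0.97))
  expect_equal(run_discovery_gwas(g2, c(y, y))$beta, beta_hand,
               tolerance = 1e-12)

  # monomorphic variant flagged with NA beta
  gm <- dosage_matrix(cbind(x, 0),
                      data.frame(chrom = "1", pos = c(100L, 200L),
                                 counted = "A", other = "G", info = 1))
  expect_warning(ssm <- run_discovery_gwas(gm, y), "monomorphic")
  expect_true(is.na(ssm$beta[2]) && ssm$monomorphic[2])

  # null variants: beta ~ 0, p roughly uniform
  gn <- random_geno(2000, 50, seed = 60)
  yn <- withr::with_seed(61, rnorm(2000))
  ssn <- run_discovery_gwas(gn, yn)
  expect_lt(max(abs(ssn$beta)), 0.2)
  expect_gt(ks.test(ssn$pvalue, "punif")$p.value, 0.01)
})

test_that("discovery effects track true effects at rho = 0 and large n", {
  cfg <- small_cfg(rho = 0, n_variants = 150, block_size = 15,
                   traits = list(t = list(h2 = 0.4, m_causal = 150,
                                          model = "continuous")), seed = 10)
  g <- simulate_genotypes(cfg, n = 20000)
  ph <- simulate_phenotypes(g, cfg, trait = "t")
  ss <- run_discovery_gwas(g, ph$latent)
  slope <- coef(lm(ss$beta ~ ph$truth$beta_allele))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("make_portability_experiment wires the cohorts together", {
  cfg <- small_cfg(seed = 11)
  exp <- make_portability_experiment(cfg)
  expect_named(exp$sumstats, names(cfg$traits))
  expect_equal(length(exp$target$samples), 300)
  expect_equal(nrow(exp$phenotypes), 300)
  expect_false(any(exp$target$samples %in% paste0("discovery_", 1:500)))
  expect_true(all(c("age", "sex", "sleep_duration", "chronotype", "insomnia")
                  %in% names(exp$phenotypes)))
  expect_true(all(exp$phenotypes$chronotype %in% 1:4))
  expect_true(all(exp$phenotypes$insomnia %in% 1:3))
  # determinism of the whole experiment
  exp2 <- make_portability_experiment(small_cfg(seed = 11))
  expect_identical(exp$sumstats, exp2$sumstats)
  expect_identical(exp$target$dosages, exp2$target$dosages)
})
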