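#' Simulation configuration
#'
#' Describes a two-cohort portability experiment: a discovery cohort that
#' yields noisy marginal GWAS effect estimates, and an independent target
#' cohort with LD-blocked genotypes and questionnaire-style phenotypes.
#' Genotypes come in blocks with AR(1) latent correlation `rho`; each trait
#' is additive with a fixed SNP heritability.
#'
#' Trait defaults mirror the three sleep traits and their reported SNP
#' heritabilities: chronotype 13.7% (4-level ordinal, 15/35/35/15%
#' prevalences), sleep duration 9.8% (hours, mean 7.5, SD ~1.05 h), insomnia
#' 16.7% (3-level ordinal, severe 15% / sometimes 35% / none 50%, coded
#' 1 = often ... 3 = not at all).
#'
#' @param n_discovery,n_target cohort sizes.
#' @param n_variants total variant count.
#' @param block_size variants per LD block. Default 50.
#' @param rho within-block AR(1) latent correlation in \[0, 1). Default 0.8.
#' @param maf_range minor-allele-frequency range for the uniform MAF draw.
#'   Default c(0.05, 0.5).
#' @param traits named list of per-trait settings; each entry is a list with
#'   `h2` in \[0, 1), `m_causal`, `model` ("continuous" or "ordinal"),
#'   `cutpoints` (latent quantile probabilities, ordinal only, strictly
#'   increasing), `mean`/`sd` (continuous scale), `reverse` (ordinal: TRUE
#'   codes the highest latent values as category 1).
#' @param info_beta shape parameters of the Beta distribution INFO values are
#'   drawn from. Default c(30, 1) (median ~0.98, occasional low-quality
#'   variants), resembling well-imputed common variants.
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_discovery = 20000, n_target = 5000,
                       n_variants = 2000, block_size = 50, rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       traits = default_sim_traits(),
                       info_beta = c(30, 1), seed = 1) {
  stopifnot(n_discovery > 0, n_target > 0, n_variants > 0, block_size > 0,
            rho >= 0, rho < 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  for (tr in names(traits)) {
    t <- traits[[tr]]
    stopifnot(t$h2 >= 0, t$h2 < 1, t$m_causal >= 1, t$m_causal <= n_variants)
    if (identical(t$model, "ordinal")) {
      stopifnot(!is.null(t$cutpoints), all(diff(t$cutpoints) > 0),
                all(t$cutpoints > 0), all(t$cutpoints < 1))
    }
  }
  structure(list(n_discovery = n_discovery, n_target = n_target,
                 n_variants = n_variants, block_size = block_size, rho = rho,
                 maf_range = maf_range, traits = traits,
                 info_beta = info_beta, seed = seed),
            class = "sim_config")
}

#' Default trait settings for the simulator
#' @return named list suitable for the `traits` argument of [sim_config()].
#' @export
default_sim_traits <- function() {
  list(
    sleep_duration = list(h2 = 0.098, m_causal = 100, model = "continuous",
                          mean = 7.5, sd = 1.05),
    chronotype = list(h2 = 0.137, m_causal = 100, model = "ordinal",
                      cutpoints = c(0.15, 0.50, 0.85), reverse = FALSE),
    insomnia = list(h2 = 0.167, m_causal = 100, model = "ordinal",
                    cutpoints = c(0.50, 0.85), reverse = TRUE)
  )
}

# Shared variant frame for one experiment: positions in 50-block stretches
# separated by 1 Mb so physical windows line up with LD blocks; MAF uniform;
# INFO ~ Beta(info_beta).
sim_variant_frame <- function(config) {
  with_seed(stream_seed(config$seed, "variants"), {
    m <- config$n_variants
    block <- ((seq_len(m) - 1L) %/% config$block_size)
    within <- (seq_len(m) - 1L) %% config$block_size
    pos <- 1000000L + block * 1250000L + within * 5000L
    data.frame(
      chrom = rep("1", m),
      pos = pos,
      counted = sample(c("A", "C", "G", "T"), m, replace = TRUE),
      other = NA_character_,
      info = stats::rbeta(m, config$info_beta[1], config$info_beta[2]),
      maf = stats::runif(m, config$maf_range[1], config$maf_range[2]),
      block = block,
      stringsAsFactors = FALSE)
  })
}

# non-complementary partner so no simulated variant is strand-ambiguous by
# construction (ambiguous ones are planted explicitly in tests)
other_allele_for <- function(counted) {
  pick <- c(A = "C", C = "A", G = "T", T = "G")
  unname(pick[counted])
}

#' Simulate LD-blocked genotype dosages
#'
#' Per block, draws a latent Gaussian AR(1) process per haplotype
#' (`z_j = rho * z_(j-1) + sqrt(1 - rho^2) * eps`), thresholds each of the two
#' haplotype draws at the allele-frequency quantile, and sums them to a
#' dosage in \{0, 1, 2\}. Adjacent variants in a block therefore show LD that
#' decays with distance; blocks are independent. Deterministic given the
#' seed.
#'
#' @param config a [sim_config()].
#' @param n number of samples (defaults to `config$n_target`).
#' @param stage seed-stream label, so discovery and target cohorts are
#'   independent draws from the same process.
#' @param variants optional pre-built variant frame (internal).
#' @return a [dosage_matrix()] with `info`, `freq` and `maf` metadata.
#' @export
simulate_genotypes <- function(config, n = config$n_target,
                               stage = "target-genotypes", variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  v <- variants %||% sim_variant_frame(config)
  m <- nrow(v)
  thr <- stats::qnorm(v$maf)  # haplotype carries the minor allele iff z < thr
  rho <- config$rho
  dos <- with_seed(stream_seed(config$seed, stage), {
    d <- matrix(0, nrow = n, ncol = m)
    for (hap in 1:2) {
      z <- matrix(0, nrow = n, ncol = m)
      for (j in seq_len(m)) {
        eps <- stats::rnorm(n)
        new_block <- v$block[j] != (if (j > 1L) v$block[j - 1L] else -1L)
        z[, j] <- if (new_block) eps else rho * z[, j - 1L] + sqrt(1 - rho^2) * eps
      }
      d <- d + (z < matrix(thr, n, m, byrow = TRUE))
    }
    d
  })
  v$other <- other_allele_for(v$counted)
  g <- dosage_matrix(dos, v[, c("chrom", "pos", "counted", "other", "info",
                                "maf", "block")],
                     samples = paste0(sub("-genotypes$", "", stage), "_",
                                      seq_len(n)))
  g$variants$freq <- variant_freq(g)
  g
}

#' Simulate additive phenotypes at fixed heritability
#'
#' Draws causal effects `beta ~ N(0, 1/m_causal)` on standardized genotypes
#' (so the genetic variance is 1 in expectation), forms the genetic value
#' `g_i`, and adds Gaussian noise scaled so that `var(g)/var(y)` equals the
#' configured h2 exactly on the simulated sample. Ordinal traits threshold
#' the same latent phenotype at the configured latent quantiles. With
#' `h2 = 0` the trait is pure noise and all true effects are zero.
#'
#' Causal standardization uses the design MAFs (not realized frequencies) so
#' a discovery and a target cohort share identical per-allele true effects.
#'
#' @param geno a simulated [dosage_matrix()] (must carry `maf` metadata).
#' @param config a [sim_config()].
#' @param trait trait name from `config$traits`.
#' @param stage seed-stream label for the environmental draw.
#' @return list: `latent` (continuous latent phenotype), `value` (scaled
#'   continuous trait or ordinal codes), `truth` (list: causal index, per-
#'   allele betas, genetic values, realized h2).
#' @export
simulate_phenotypes <- function(geno, config, trait = "sleep_duration",
                                stage = paste0(trait, "-phenotype")) {
  stopifnot(inherits(config, "sim_config"), trait %in% names(config$traits))
  tc <- config$traits[[trait]]
  maf <- geno$variants$maf
  m <- config$n_variants
  causal <- with_seed(stream_seed(config$seed, paste0(trait, "-architecture")), {
    idx <- sort(sample.int(m, tc$m_causal))
    list(idx = idx,
         beta_std = stats::rnorm(tc$m_causal, 0, sqrt(1 / tc$m_causal)))
  })
  # per-allele effect = standardized effect / sd(dosage) at the design MAF
  sd_x <- sqrt(2 * maf[causal$idx] * (1 - maf[causal$idx]))
  beta_allele <- if (tc$h2 > 0) causal$beta_std / sd_x else rep(0, tc$m_causal)
  g <- as.vector(geno$dosages[, causal$idx, drop = FALSE] %*% beta_allele)

  latent <- with_seed(stream_seed(config$seed, stage), {
    if (tc$h2 > 0) {
      vg <- stats::var(g)
      g + stats::rnorm(length(g), 0, sqrt(vg * (1 - tc$h2) / tc$h2))
    } else {
      stats::rnorm(length(g))
    }
  })
  value <- if (identical(tc$model, "ordinal")) {
    cuts <- stats::quantile(latent, probs = tc$cutpoints, type = 1)
    codes <- findInterval(latent, cuts) + 1L
    if (isTRUE(tc$reverse)) codes <- max(codes) + 1L - codes
    codes
  } else {
    (tc$mean %||% 0) + (tc$sd %||% 1) * (latent - mean(latent)) / stats::sd(latent)
  }
  list(latent = latent, value = value,
       truth = list(causal_idx = causal$idx, beta_allele = beta_allele,
                    genetic = g,
                    h2_realized = if (tc$h2 > 0) stats::var(g) / stats::var(latent) else 0))
}

#' Marginal discovery GWAS
#'
#' Per variant, the simple-regression slope of the phenotype on dosage:
#' `beta_hat = cov(x, y)/var(x)`, SE from the residual variance, two-sided
#' normal/t p-value. EAF is taken from the genotype matrix and INFO carried
#' from simulation. Monomorphic variants are emitted with NA beta and
#' flagged. Fully vectorized.
#'
#' @param geno a [dosage_matrix()].
#' @param y continuous (or 0/1) phenotype vector.
#' @return data.frame in [read_sumstats()] layout (chrom, pos, effect_allele,
#'   other_allele, beta, se, pvalue, eaf, info) plus `monomorphic`.
#' @export
run_discovery_gwas <- function(geno, y) {
  stopifnot(inherits(geno, "dosage_matrix"), length(y) == nrow(geno$dosages))
  x <- geno$dosages
  n <- length(y)
  xm <- colMeans(x)
  ym <- mean(y)
  sxx <- colSums(x^2) - n * xm^2
  sxy <- as.vector(crossprod(x, y)) - n * xm * ym
  syy <- sum(y^2) - n * ym^2
  mono <- sxx <= 0
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  rss <- syy - ifelse(mono, 0, sxy^2 / sxx)
  se <- ifelse(mono, NA_real_, sqrt(pmax(rss, 0) / (n - 2) / sxx))
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  if (any(mono)) warning(sprintf("run_discovery_gwas: %d monomorphic variant(s) flagged", sum(mono)))
  v <- geno$variants
  data.frame(chrom = v$chrom, pos = v$pos,
             effect_allele = v$counted, other_allele = v$other,
             beta = beta, se = se,
             pvalue = pmin(pmax(pval, .Machine$double.xmin), 1),
             eaf = xm / 2,
             info = v$info %||% rep(1, nrow(v)),
             monomorphic = mono,
             stringsAsFactors = FALSE)
}

#' Build a full two-cohort portability experiment
#'
#' Draws one shared variant frame and causal architecture, simulates an
#' independent discovery and target cohort from the same generative process,
#' runs the marginal discovery GWAS per trait on the discovery cohort, and
#' assembles a target phenotype/covariate table (age ~ U(25, 74), sex ~
#' Bernoulli(0.5), both independent of the traits).
#'
#' @param config a [sim_config()].
#' @param traits traits to simulate (default: all configured).
#' @return list: `sumstats` (named list of discovery GWAS tables),
#'   `target` (a `dosage_matrix`), `phenotypes` (data.frame: sample, age,
#'   sex, cohort, one column per trait), `truth` (named list of per-trait
#'   SimTruth), `config`.
#' @export
make_portability_experiment <- function(config, traits = names(config$traits)) {
  stopifnot(inherits(config, "sim_config"))
  variants <- sim_variant_frame(config)
  disc <- simulate_genotypes(config, n = config$n_discovery,
                             stage = "discovery-genotypes", variants = variants)
  targ <- simulate_genotypes(config, n = config$n_target,
                             stage = "target-genotypes", variants = variants)

  sumstats <- list()
  truth <- list()
  pheno <- data.frame(sample = targ$samples, stringsAsFactors = FALSE)
  with_seed(stream_seed(config$seed, "covariates"), {
    pheno$age <- round(stats::runif(config$n_target, 25, 74), 1)
    pheno$sex <- stats::rbinom(config$n_target, 1, 0.5)
  })
  pheno$cohort <- "target"
  for (tr in traits) {
    dph <- simulate_phenotypes(disc, config, trait = tr,
                               stage = paste0(tr, "-discovery-phenotype"))
    sumstats[[tr]] <- run_discovery_gwas(disc, dph$latent)
    tph <- simulate_phenotypes(targ, config, trait = tr,
                               stage = paste0(tr, "-target-phenotype"))
    pheno[[tr]] <- tph$value
    truth[[tr]] <- tph$truth
  }
  list(sumstats = sumstats, target = targ, phenotypes = pheno,
       truth = truth, config = config)
}
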