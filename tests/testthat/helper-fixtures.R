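# Small in-code fixtures shared across test files.

# random dosage matrix with simple metadata; optionally sprinkle missingness
random_geno <- function(n, m, seed, chrom = "1", spacing = 10000L,
                        miss_frac = 0, maf_range = c(0.1, 0.5)) {
  withr::with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    d <- sapply(maf, function(p) rbinom(n, 2, p))
    d <- matrix(as.double(d), nrow = n)
    if (miss_frac > 0) {
      d[runif(length(d)) < miss_frac] <- NA_real_
    }
    v <- data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                    counted = "A", other = "G", info = runif(m, 0.9, 1),
                    stringsAsFactors = FALSE)
    dosage_matrix(d, v)
  })
}

# correlated (LD-blocked) dosage matrix via the package-independent
# "duplicate with noise" trick: adjacent variants share most of their calls
correlated_geno <- function(n, m, seed, flip_prob = 0.1, spacing = 10000L) {
  withr::with_seed(seed, {
    d <- matrix(0, n, m)
    d[, 1] <- rbinom(n, 2, 0.4)
    for (j in 2:m) {
      redraw <- runif(n) < flip_prob
      d[, j] <- ifelse(redraw, rbinom(n, 2, 0.4), d[, j - 1])
    }
    v <- data.frame(chrom = "1", pos = seq_len(m) * spacing,
                    counted = "A", other = "G", info = 1,
                    stringsAsFactors = FALSE)
    dosage_matrix(d, v)
  })
}

# write a sumstats TSV from a data.frame and return the path
write_sumstats_fixture <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                                    .local_envir = parent.frame())) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

# a fully valid sumstats frame to perturb in tests
valid_sumstats <- function(n = 10, seed = 42) {
  withr::with_seed(seed, {
    data.frame(chrom = as.character(sample(1:22, n, replace = TRUE)),
               pos = sample.int(1e6, n),
               effect_allele = sample(c("A", "T"), n, replace = TRUE),
               other_allele = "G",
               beta = rnorm(n, 0, 0.05),
               se = runif(n, 0.01, 0.05),
               pvalue = runif(n),
               eaf = runif(n, 0.05, 0.95),
               info = runif(n, 0.85, 1),
               stringsAsFactors = FALSE)
  })
}
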