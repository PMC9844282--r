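#' Variant-level QC for the target cohort
#'
#' Keeps autosomal variants (chromosomes 1-22) with imputation INFO >=
#' `info_min`. Note the boundary differs from the summary-statistics filter:
#' here the exclusion rule is "INFO < info_min", so the boundary value is
#' retained.
#'
#' @param geno a [dosage_matrix()]; variant metadata must carry `info` and
#'   `chrom`.
#' @param info_min minimum imputation quality (inclusive). Default 0.9.
#' @param autosomes_only drop non-autosomal variants. Default TRUE.
#' @return the filtered `dosage_matrix`.
#' @export
filter_variants_target <- function(geno, info_min = 0.9, autosomes_only = TRUE) {
  stopifnot(inherits(geno, "dosage_matrix"))
  info <- geno$variants$info
  if (is.null(info)) stop("variant metadata lacks an 'info' column")
  keep <- info >= info_min
  if (autosomes_only) {
    keep <- keep & (as.character(geno$variants$chrom) %in% as.character(1:22))
  }
  subset_dosage(geno, variants = which(keep))
}

#' Per-sample heterozygosity F coefficient
#'
#' Method-of-moments inbreeding coefficient from hard genotype calls:
#' `F_i = (O_hom_i - E_hom_i) / (M_i - E_hom_i)` where, over the `M_i`
#' non-missing sites of sample i, `O_hom` counts genotypes in \{0, 2\} and
#' `E_hom = sum_j (1 - 2 p_j (1 - p_j))` under Hardy-Weinberg at the cohort
#' allele frequencies `p_j`. Excess heterozygosity (contamination) drives F
#' negative; inbreeding/genotyping artifacts drive it positive.
#'
#' Dosages are rounded to the nearest hard call for this computation, since F
#' is defined on genotype counts.
#'
#' @param geno a `dosage_matrix`.
#' @param freq optional per-variant counted-allele frequencies; recomputed
#'   from the (rounded) dosages when NULL.
#' @return named numeric vector of F, NA (flagged) where the denominator is 0.
#' @export
heterozygosity_f <- function(geno, freq = NULL) {
  stopifnot(inherits(geno, "dosage_matrix"))
  hard <- round(geno$dosages)
  obs <- !is.na(hard)
  p <- freq %||% (colMeans(hard, na.rm = TRUE) / 2)
  exp_hom_j <- 1 - 2 * p * (1 - p)
  m_i <- rowSums(obs)
  o_hom <- rowSums(hard != 1, na.rm = TRUE)
  e_hom <- as.vector(obs %*% exp_hom_j)
  denom <- m_i - e_hom
  f <- ifelse(abs(denom) < .Machine$double.eps * m_i, NA_real_,
              (o_hom - e_hom) / denom)
  if (anyNA(f)) warning("F undefined (M == E_hom) for some sample(s); flagged NA")
  names(f) <- geno$samples
  f
}

#' Flag heterozygosity outliers
#'
#' A sample is removed when its F lies more than `sd_mult` standard deviations
#' from the cohort mean; mean and SD are computed once on all samples (no
#' iterative re-centering). Samples with undefined F are removed.
#'
#' @param f numeric vector of F coefficients (NA = undefined).
#' @param sd_mult multiplier on the SD. Default 3.
#' @return logical vector, TRUE = kept.
#' @export
exclude_het_outliers <- function(f, sd_mult = 3) {
  stopifnot(length(f) >= 2L)
  mu <- mean(f, na.rm = TRUE)
  sdev <- stats::sd(f, na.rm = TRUE)
  if (is.na(sdev) || sdev == 0) {
    keep <- !is.na(f)
    return(keep)
  }
  keep <- !is.na(f) & abs(f - mu) <= sd_mult * sdev
  keep[is.na(keep)] <- FALSE
  keep
}

#' Genomic relationship matrix
#'
#' `A_ik = (1/M) * sum_j (x_ij - 2 p_j)(x_kj - 2 p_j) / (2 p_j (1 - p_j))`
#' over the M polymorphic variants; missing dosages are mean-imputed as
#' `2 p_j`. Off-diagonal entries approximate twice the kinship coefficient
#' (0.5 for duplicates/MZ twins, ~0.25 first-degree, ~0.125 second-degree).
#'
#' @param geno a `dosage_matrix`.
#' @param freq optional counted-allele frequencies; recomputed when NULL.
#' @return symmetric n x n matrix with sample-id dimnames.
#' @export
grm <- function(geno, freq = NULL) {
  stopifnot(inherits(geno, "dosage_matrix"))
  x <- geno$dosages
  p <- freq %||% (colMeans(x, na.rm = TRUE) / 2)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!all(poly)) {
    warning(sprintf("grm: excluding %d monomorphic variant(s)", sum(!poly)))
  }
  if (sum(poly) == 0L) stop("grm: no polymorphic variants")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2, 2 * p, "-")
  z[is.na(z)] <- 0  # mean imputation: x = 2p  =>  centered value 0
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  a <- tcrossprod(z) / ncol(z)
  dimnames(a) <- list(geno$samples, geno$samples)
  a
}

#' Greedy relatedness pruning
#'
#' Removes samples until no kept pair has relatedness above `cutoff`
#' (0.125 ~ the second-degree boundary, so duplicates and first/second-degree
#' relatives go). Greedy: repeatedly drop the sample with the most
#' above-cutoff partners; ties broken by larger mean above-cutoff relatedness,
#' then by input order. Deterministic.
#'
#' @param a symmetric relationship matrix (e.g. from [grm()]).
#' @param cutoff maximum allowed pairwise relatedness. Default 0.125.
#' @return logical vector, TRUE = kept.
#' @export
rel_cutoff <- function(a, cutoff = 0.125) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  n <- nrow(a)
  high <- a > cutoff
  diag(high) <- FALSE
  keep <- rep(TRUE, n)
  repeat {
    deg <- rowSums(high[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1L) {
      mean_rel <- vapply(worst, function(i) {
        part <- keep & high[i, ]
        mean(a[i, part])
      }, numeric(1))
      worst <- worst[mean_rel == max(mean_rel)]
    }
    drop <- worst[1L]  # remaining ties: input order
    keep[drop] <- FALSE
    high[drop, ] <- FALSE
    high[, drop] <- FALSE
  }
  names(keep) <- rownames(a)
  keep
}

#' Sample-level QC: heterozygosity then relatedness
#'
#' Runs [heterozygosity_f()] + [exclude_het_outliers()] first, then [grm()] +
#' [rel_cutoff()] on the survivors (order configurable). Duplicate samples are
#' a special case of relatedness (A_ik near A_ii) and need no separate
#' detector.
#'
#' @param geno a post-variant-QC `dosage_matrix`.
#' @param het_sd_mult SD multiplier for the F filter. Default 3.
#' @param rel_cutoff_value relatedness cutoff. Default 0.125.
#' @param het_first apply the heterozygosity filter before relatedness.
#'   Default TRUE.
#' @return list: `geno` (filtered `dosage_matrix`), `report` (data.frame
#'   sample/F/kept/reason), `grm` (relationship matrix on the samples that
#'   entered the relatedness step).
#' @export
run_sample_qc <- function(geno, het_sd_mult = 3, rel_cutoff_value = 0.125,
                          het_first = TRUE) {
  stopifnot(inherits(geno, "dosage_matrix"))
  n <- length(geno$samples)
  f <- heterozygosity_f(geno)
  reason <- rep(NA_character_, n)

  if (het_first) {
    keep_het <- exclude_het_outliers(f, sd_mult = het_sd_mult)
    reason[!keep_het] <- "heterozygosity"
    g1 <- subset_dosage(geno, samples = which(keep_het))
    a <- grm(g1)
    keep_rel <- rel_cutoff(a, cutoff = rel_cutoff_value)
    reason[which(keep_het)[!keep_rel]] <- "relatedness"
  } else {
    a <- grm(geno)
    keep_rel <- rel_cutoff(a, cutoff = rel_cutoff_value)
    reason[!keep_rel] <- "relatedness"
    f_sub <- f[keep_rel]
    keep_het <- exclude_het_outliers(f_sub, sd_mult = het_sd_mult)
    reason[which(keep_rel)[!keep_het]] <- "heterozygosity"
  }
  kept <- is.na(reason)
  report <- data.frame(sample = geno$samples, f = unname(f), kept = kept,
                       reason = reason, stringsAsFactors = FALSE)
  list(geno = subset_dosage(geno, samples = which(kept)),
       report = report, grm = a)
}
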