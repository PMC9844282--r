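#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over their
#' pairwise-complete entries. Sign-free, so it is invariant to which allele
#' either variant counts.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or NA when either vector has zero variance
#'   (or fewer than 2 complete pairs); callers treat NA as 0 with a warning.
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r^2 of one dosage column against many, pairwise complete, vectorized.
# Zero-variance columns give NA.
ld_r2_vec <- function(x, m) {
  if (length(m) == 0L || ncol(m) == 0L) return(numeric(0))
  suppressWarnings(as.vector(stats::cor(x, m, use = "pairwise.complete.obs"))^2)
}

#' Greedy LD pruning
#'
#' Produces an approximately LD-independent variant subset for structure
#' analyses (PCA). Per chromosome, variants are scanned in position order and
#' a variant is retained only if its r-squared with every already-retained
#' variant within `window_kb` upstream is at or below `r2_max` — so of any
#' correlated pair the later-positioned member is dropped, and the retained
#' set provably contains no pair within the window span above `r2_max`.
#'
#' @param geno a [dosage_matrix()], variants position-sorted within
#'   chromosome.
#' @param window_kb window radius in kilobases. Default 250.
#' @param step_variants accepted for interface compatibility with
#'   fixed-step window tools; the scan advances one variant at a time, which
#'   makes the post-condition hold for every pair regardless of step.
#' @param r2_max maximum allowed r-squared between retained variants.
#'   Default 0.1.
#' @return integer vector of retained variant indices (ascending).
#' @export
ld_prune <- function(geno, window_kb = 250, step_variants = 1, r2_max = 0.1) {
  stopifnot(inherits(geno, "dosage_matrix"))
  v <- geno$variants
  window_bp <- window_kb * 1000
  retained <- integer(0)
  warned <- FALSE
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    idx <- idx[order(v$pos[idx])]
    kept_chr <- integer(0)
    for (j in idx) {
      near <- kept_chr[v$pos[j] - v$pos[kept_chr] <= window_bp]
      if (length(near) > 0L) {
        r2 <- ld_r2_vec(geno$dosages[, j], geno$dosages[, near, drop = FALSE])
        if (anyNA(r2) && !warned) {
          warning("ld_prune: zero-variance variant(s); r2 treated as 0")
          warned <- TRUE
        }
        r2[is.na(r2)] <- 0
        if (any(r2 > r2_max)) next
      }
      kept_chr <- c(kept_chr, j)
    }
    retained <- c(retained, kept_chr)
  }
  sort(retained)
}

#' Principal components on pruned variants
#'
#' Computes the leading left singular directions of the standardized dosage
#' matrix — the usual population-structure covariates. Each variant is
#' centered at `2p` and scaled by `sqrt(2p(1-p))`; missing dosages are
#' mean-imputed (0 after centering); monomorphic variants are dropped. The
#' sign of each component is fixed by making its largest-magnitude variant
#' loading positive, so results are fully deterministic.
#'
#' @param geno a `dosage_matrix`.
#' @param variants optional variant index (e.g. from [ld_prune()]); all
#'   variants when NULL.
#' @param k number of components. Default 6.
#' @return list of class `pc_scores`: `scores` (n x k matrix, columns
#'   `PC1..PCk`), `varfrac` (per-component variance fractions,
#'   non-increasing), `loadings` (variants x k), `variant_idx`.
#' @export
pca_scores <- function(geno, variants = NULL, k = 6) {
  stopifnot(inherits(geno, "dosage_matrix"))
  vi <- variants %||% seq_len(nrow(geno$variants))
  x <- geno$dosages[, vi, drop = FALSE]
  n <- nrow(x)
  if (n <= k) stop("pca_scores: need more samples than components")
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2, 2 * p, "-")
  z[is.na(z)] <- 0
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")

  sv <- svd(z)
  tol <- max(dim(z)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < k) {
    warning(sprintf("pca_scores: rank %d < k = %d; returning %d component(s)",
                    rank, k, rank))
    k <- rank
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    s <- sign(v[which.max(abs(v[, j])), j])
    if (s < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- sweep(u, 2, d, "*")
  dimnames(scores) <- list(geno$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 varfrac = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 loadings = v,
                 variant_idx = vi[which(poly)]),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("pc_scores: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$varfrac), collapse = " "), "\n")
  invisible(x)
}

#' Write PC scores as TSV
#'
#' @param pcs a `pc_scores` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pc_scores <- function(pcs, path) {
  df <- data.frame(sample = rownames(pcs$scores), pcs$scores,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
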