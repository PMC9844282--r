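# Independent oracles used by the derived-value and acceptance tests.
# These are deliberately naive (loops, closed forms, enumeration) and share
# no code with the implementation paths they check.

# -- brute-force clumping: after every index promotion, re-scan *all*
#    remaining candidate pairs from scratch. O(k * m^2).
oracle_clump <- function(cand, panel, p_max = 5e-4, window_kb = 250, r2 = 0.1) {
  cand <- cand[cand$pvalue < p_max, , drop = FALSE]
  pkey <- paste0(panel$variants$chrom, ":", panel$variants$pos)
  ckey <- paste0(cand$chrom, ":", cand$pos)
  col <- match(ckey, pkey)
  cand <- cand[!is.na(col), , drop = FALSE]
  col <- col[!is.na(col)]
  remaining <- order(cand$pvalue, cand$chrom, cand$pos)
  index <- integer(0)
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    index <- c(index, i)
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    drop <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      if (cand$chrom[j] != cand$chrom[i]) next
      if (abs(cand$pos[j] - cand$pos[i]) > window_kb * 1000) next
      x <- panel$dosages[, col[i]]
      y <- panel$dosages[, col[j]]
      okp <- !is.na(x) & !is.na(y)
      r2ij <- if (sum(okp) < 2 || var(x[okp]) == 0 || var(y[okp]) == 0) 0 else
        cor(x[okp], y[okp])^2
      if (r2ij >= r2) drop[k] <- TRUE
    }
    remaining <- remaining[!drop]
  }
  idx <- cand[index, c("chrom", "pos"), drop = FALSE]
  idx[order(idx$chrom, idx$pos), , drop = FALSE]
}

# -- naive scoring: double loop over samples and variants.
oracle_prs_sum <- function(dosages, weights, freq = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(freq)) freq <- colMeans(dosages, na.rm = TRUE) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) {
      d <- dosages[i, j]
      if (is.na(d)) d <- 2 * freq[j]
      s <- s + weights[j] * d
    }
    out[i] <- s
  }
  out
}

# -- loop-based heterozygosity F, straight from the definition.
oracle_het_f <- function(hard, p) {
  n <- nrow(hard)
  f <- numeric(n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(hard[i, ]))
    m <- length(obs)
    o_hom <- sum(hard[i, obs] %in% c(0, 2))
    e_hom <- sum(1 - 2 * p[obs] * (1 - p[obs]))
    f[i] <- (o_hom - e_hom) / (m - e_hom)
  }
  f
}

# -- double-loop GRM on mean-imputed dosages.
oracle_grm <- function(dosages, p) {
  poly <- p > 0 & p < 1
  x <- dosages[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(x); m <- ncol(x)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (j in seq_len(m)) {
        xi <- x[i, j]; xk <- x[k, j]
        if (is.na(xi)) xi <- 2 * p[j]
        if (is.na(xk)) xk <- 2 * p[j]
        s <- s + (xi - 2 * p[j]) * (xk - 2 * p[j]) / (2 * p[j] * (1 - p[j]))
      }
      a[i, k] <- s / m
    }
  }
  a
}

# -- plain-R IRLS for logistic regression; returns coefficients and deviance
#    (-2 log-likelihood). Independent of stats::glm's C fitter.
oracle_irls <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(beta = as.vector(beta), deviance = dev)
}

# -- OLS via the normal equations; returns R^2.
oracle_ols_r2 <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  fit <- as.vector(X %*% b)
  1 - sum((y - fit)^2) / sum((y - mean(y))^2)
}

# -- Welch t statistic and p from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}
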