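#' Greedy p-value ordered LD clumping
#'
#' Reduces a set of associated variants to approximately independent index
#' signals. Candidates with `pvalue < p_max` are visited in ascending p
#' (ties broken by chromosome, then position); each still-unassigned
#' candidate is promoted to an index, and every other unassigned candidate on
#' the same chromosome within `window_kb` of it with r-squared at or above
#' `r2` (computed in the LD panel) is assigned to it as a clump member and
#' removed from candidacy. The r-squared comparison is inclusive.
#'
#' @param sumstats harmonized records from [harmonize_weights()] (must carry
#'   `chrom`, `pos`, `pvalue`), or any data.frame with those columns.
#' @param ld_panel a [dosage_matrix()] providing the LD structure; candidates
#'   missing from the panel are dropped with a warning and counted in the
#'   result's `n_missing_panel`.
#' @param p_max candidate p-value threshold (exclusive). Default 5e-4.
#' @param window_kb window radius in kilobases. Default 250.
#' @param r2 member r-squared threshold (inclusive). Default 0.1.
#' @return object of class `clump_set`: `index` (data.frame chrom/pos/pvalue
#'   in promotion order), `members` (list of data.frames chrom/pos/r2, one
#'   per index), `n_missing_panel`.
#' @export
clump <- function(sumstats, ld_panel, p_max = 5e-4, window_kb = 250, r2 = 0.1) {
  stopifnot(inherits(ld_panel, "dosage_matrix"))
  cand <- sumstats[sumstats$pvalue < p_max, , drop = FALSE]
  pkey <- variant_key(ld_panel$variants$chrom, ld_panel$variants$pos)
  ckey <- variant_key(cand$chrom, cand$pos)
  col <- match(ckey, pkey)
  n_missing <- sum(is.na(col))
  if (n_missing > 0L) {
    warning(sprintf("clump: %d candidate(s) absent from LD panel; dropped",
                    n_missing))
    cand <- cand[!is.na(col), , drop = FALSE]
    col <- col[!is.na(col)]
  }
  ord <- order(cand$pvalue, cand$chrom, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  col <- col[ord]

  window_bp <- window_kb * 1000
  n <- nrow(cand)
  assigned <- rep(FALSE, n)
  index <- list()
  members <- list()
  warned <- FALSE
  for (i in seq_len(n)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    near <- which(!assigned & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= window_bp)
    mem <- data.frame(chrom = character(0), pos = integer(0),
                      r2 = numeric(0), stringsAsFactors = FALSE)
    if (length(near) > 0L) {
      r2v <- ld_r2_vec(ld_panel$dosages[, col[i]],
                       ld_panel$dosages[, col[near], drop = FALSE])
      if (anyNA(r2v) && !warned) {
        warning("clump: zero-variance variant(s) in LD panel; r2 treated as 0")
        warned <- TRUE
      }
      r2v[is.na(r2v)] <- 0
      hit <- r2v >= r2
      if (any(hit)) {
        assigned[near[hit]] <- TRUE
        mem <- data.frame(chrom = cand$chrom[near[hit]],
                          pos = cand$pos[near[hit]],
                          r2 = r2v[hit], stringsAsFactors = FALSE)
      }
    }
    index[[length(index) + 1L]] <- cand[i, , drop = FALSE]
    members[[length(members) + 1L]] <- mem
  }
  index_df <- if (length(index) > 0L) do.call(rbind, index) else
    cand[0, , drop = FALSE]
  rownames(index_df) <- NULL
  structure(list(index = index_df, members = members,
                 n_missing_panel = n_missing),
            class = "clump_set")
}

#' @export
print.clump_set <- function(x, ...) {
  cat(sprintf("clump_set: %d index variant(s), %d clumped member(s)\n",
              nrow(x$index), sum(vapply(x$members, nrow, integer(1)))))
  invisible(x)
}

#' Flatten a clump set to a TSV-friendly table
#'
#' @param x a `clump_set`.
#' @return data.frame with one row per index variant: chrom, pos, pvalue,
#'   n_members, members ("chrom:pos(r2)" comma-joined).
#' @export
clump_table <- function(x) {
  stopifnot(inherits(x, "clump_set"))
  mem_str <- vapply(x$members, function(m) {
    if (nrow(m) == 0L) return("")
    paste(sprintf("%s:%d(%.3f)", m$chrom, m$pos, m$r2), collapse = ",")
  }, character(1))
  data.frame(x$index,
             n_members = vapply(x$members, nrow, integer(1)),
             members = mem_str, stringsAsFactors = FALSE)
}

#' Compute polygenic risk scores
#'
#' Weighted allele-dosage sum: `raw_i = sum_j w_j d_ij` over the variants
#' shared between the weight table and the genotype matrix. The default
#' report is the per-allele average `raw_i / (2 M)` (the convention of the
#' standard scoring tool, giving scores on the ~1e-3 scale for thousands of
#' variants); `mode = "sum"` reports the raw weighted sum. Missing dosages
#' are mean-imputed as `2 * freq` by default, or omitted with the denominator
#' rescaled per sample (`missing = "omit"`).
#'
#' @param geno a [dosage_matrix()].
#' @param weights harmonized weights (e.g. the index variants of a clump),
#'   with columns `chrom`, `pos`, `counted`, `weight`.
#' @param mode "average" (default) or "sum".
#' @param missing "impute" (default) or "omit".
#' @return data.frame of class `score_table`: `sample`, `score_avg`,
#'   `score_sum`, `n_variants`.
#' @export
compute_prs <- function(geno, weights, mode = c("average", "sum"),
                        missing = c("impute", "omit")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  stopifnot(inherits(geno, "dosage_matrix"))
  gkey <- variant_key(geno$variants$chrom, geno$variants$pos)
  wkey <- variant_key(weights$chrom, weights$pos)
  idx <- match(wkey, gkey)
  ok <- !is.na(idx)
  if (!is.null(weights$counted)) {
    ok <- ok & weights$counted == geno$variants$counted[idx]
  }
  m <- sum(ok)
  if (m == 0L) stop("compute_prs: no overlapping variants between weights and genotypes")
  w <- weights$weight[ok]
  d <- geno$dosages[, idx[ok], drop = FALSE]

  if (missing == "impute") {
    freq <- colMeans(d, na.rm = TRUE) / 2
    na_idx <- which(is.na(d), arr.ind = TRUE)
    if (nrow(na_idx) > 0L) d[na_idx] <- 2 * freq[na_idx[, 2]]
    raw <- as.vector(d %*% w)
    denom <- rep(2 * m, nrow(d))
  } else {
    obs <- !is.na(d)
    d0 <- d
    d0[!obs] <- 0
    raw <- as.vector(d0 %*% w)
    denom <- 2 * rowSums(obs)
  }
  out <- data.frame(sample = geno$samples,
                    score_avg = ifelse(denom > 0, raw / denom, NA_real_),
                    score_sum = raw,
                    n_variants = m,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' The score column selected by a score table's mode
#' @param scores a `score_table`.
#' @return numeric vector.
#' @export
score_values <- function(scores) {
  if (identical(attr(scores, "mode"), "sum")) scores$score_sum else scores$score_avg
}
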