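#' Prepare questionnaire phenotypes
#'
#' Collapses a raw phenotype table (possibly several questionnaire waves per
#' participant) to one row per sample:
#' * for a participant with multiple non-missing answers to the same
#'   question, exactly one is retained, chosen by a seeded uniform draw
#'   (reproducible given the seed);
#' * sleep-duration reports of 3 h or less, or 16 h or more, are removed
#'   (set missing) and counted;
#' * non-numeric trait values are dropped and counted.
#'
#' @param raw data.frame with a `sample` column, any of the trait columns
#'   `sleep_duration` (hours), `chronotype` (1-4), `insomnia` (ordinal), and
#'   covariates (`age`, `sex`, `cohort`, ...) taken from each sample's first
#'   row.
#' @param seed integer seed for the answer selection.
#' @param traits trait columns to collapse (defaults to those present).
#' @return data.frame, one row per sample; attribute `exclusions` is a named
#'   integer vector (sleep_range, non_numeric).
#' @export
prepare_phenotypes <- function(raw, seed,
                               traits = intersect(c("sleep_duration",
                                                    "chronotype", "insomnia"),
                                                  names(raw))) {
  stopifnot("sample" %in% names(raw))
  n_nonnum <- 0L
  for (tr in traits) {
    v <- raw[[tr]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      n_nonnum <- n_nonnum + sum(!is.na(v) & v != "NA" & is.na(vn))
      raw[[tr]] <- vn
    }
  }
  ids <- unique(raw$sample)
  first <- raw[match(ids, raw$sample), setdiff(names(raw), traits), drop = FALSE]
  out <- first
  with_seed(stream_seed(seed, "phenotype-answer-selection"), {
    for (tr in traits) {
      picked <- vapply(ids, function(id) {
        vals <- raw[[tr]][raw$sample == id]
        vals <- vals[!is.na(vals)]
        if (length(vals) == 0L) return(NA_real_)
        if (length(vals) == 1L) return(vals)
        vals[sample.int(length(vals), 1L)]
      }, numeric(1))
      out[[tr]] <- picked
    }
  })
  n_sleep <- 0L
  if ("sleep_duration" %in% names(out)) {
    bad <- !is.na(out$sleep_duration) &
      (out$sleep_duration <= 3 | out$sleep_duration >= 16)
    n_sleep <- sum(bad)
    out$sleep_duration[bad] <- NA_real_
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(sleep_range = n_sleep, non_numeric = n_nonnum)
  out
}

#' Dichotomize an ordinal or continuous sleep trait
#'
#' Implements the extreme-group definitions used for the logistic models:
#' * `chronotype_extremes`: 1 ("absolutely a morning person") -> case 1;
#'   4 ("absolutely an evening person") -> 0; 2/3 excluded.
#' * `sleep_extremes`: <= 6 h ("short sleeper") -> 1; >= 9 h ("long
#'   sleeper") -> 0; otherwise excluded.
#' * `insomnia_finrisk` (1 often - 2 sometimes - 3 not at all): 1 (severe)
#'   -> 1; 3 (none) -> 0; 2 excluded.
#' * `insomnia_health` (1 none ... 5 severe): 4 or 5 -> 1; 1 -> 0; 2/3
#'   excluded.
#'
#' @param values numeric trait vector.
#' @param rule one of the rule names above.
#' @return integer vector (1 = case, 0 = control, NA = excluded) with a
#'   `labels` attribute naming the two groups; input NAs stay NA.
#' @export
dichotomize <- function(values, rule = c("chronotype_extremes", "sleep_extremes",
                                         "insomnia_finrisk", "insomnia_health")) {
  rule <- match.arg(rule)
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  check_codes <- function(allowed) {
    bad <- ok & !(values %in% allowed)
    if (any(bad)) {
      stop(sprintf("dichotomize(%s): out-of-range code(s): %s", rule,
                   paste(unique(values[bad]), collapse = ", ")))
    }
  }
  labels <- switch(rule,
    chronotype_extremes = {
      check_codes(1:4)
      out[ok & values == 1] <- 1L
      out[ok & values == 4] <- 0L
      c(case = "absolutely_morning", control = "absolutely_evening")
    },
    sleep_extremes = {
      out[ok & values <= 6] <- 1L
      out[ok & values >= 9] <- 0L
      c(case = "short_sleeper", control = "long_sleeper")
    },
    insomnia_finrisk = {
      check_codes(1:3)
      out[ok & values == 1] <- 1L
      out[ok & values == 3] <- 0L
      c(case = "severe_insomnia", control = "no_insomnia")
    },
    insomnia_health = {
      check_codes(1:5)
      out[ok & values >= 4] <- 1L
      out[ok & values == 1] <- 0L
      c(case = "severe_insomnia", control = "no_insomnia")
    })
  attr(out, "labels") <- labels
  out
}

# Welch t-test that degrades gracefully when both groups have zero variance
# (equal means -> t = 0, p = 1; unequal -> infinite t, p = 0).
welch_or_degenerate <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
                parameter = c(df = NA_real_),
                p.value = if (d == 0) 1 else 0))
  }
  stats::t.test(a, b)
}

# Build the design data.frame of complete cases shared by the two regression
# helpers. covars: data.frame or matrix of covariates (age, sex, PCs ...).
eval_frame <- function(y, prs, covars = NULL) {
  df <- data.frame(y = y, prs = prs)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    stopifnot(nrow(covars) == length(y))
    names(covars) <- make.names(names(covars), unique = TRUE)
    df <- cbind(df, covars)
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Incremental variance explained by the PRS (linear model)
#'
#' Fits ordinary least squares with and without the PRS; the headline figure
#' is the R-squared increment `R2_full - R2_base`. Covariates are typically
#' age, sex and the first six principal components. Complete cases only.
#'
#' @param y continuous trait.
#' @param prs per-sample scores (same order as `y`).
#' @param covars data.frame of covariates, or NULL.
#' @return list of class `eval_report`: `n`, `r2_incremental`, `r2_full`,
#'   `r2_base`, `coef` (PRS estimate), `se`, `pvalue` (two-sided),
#'   `model = "linear"`.
#' @export
linear_incremental_r2 <- function(y, prs, covars = NULL) {
  df <- eval_frame(y, prs, covars)
  k <- ncol(df)  # intercept + prs + covars <= n required
  if (nrow(df) <= k) stop("linear_incremental_r2: too few complete cases")
  full <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "))
  }
  base <- stats::lm(y ~ ., data = df[, setdiff(names(df), "prs"), drop = FALSE])
  sfull <- summary(full)
  r2f <- sfull$r.squared
  r2b <- summary(base)$r.squared
  ct <- sfull$coefficients["prs", ]
  structure(list(n = nrow(df),
                 r2_incremental = r2f - r2b,
                 r2_full = r2f, r2_base = r2b,
                 coef = unname(ct["Estimate"]), se = unname(ct["Std. Error"]),
                 pvalue = unname(ct["Pr(>|t|)"]),
                 model = "linear"),
            class = "eval_report")
}

#' McFadden pseudo-R-squared of the PRS (logistic model)
#'
#' Fits maximum-likelihood logistic regressions with covariates only
#' (deviance d0) and covariates plus PRS (deviance d1) and reports
#' `1 - d1/d0`, with the PRS Wald p-value. Deviance is -2 times the model
#' log-likelihood (the saturated-model constant cancels in the ratio). A
#' non-converged or separated fit is flagged, not hidden.
#'
#' @param y binary trait (0/1); both classes must be present.
#' @param prs per-sample scores.
#' @param covars data.frame of covariates, or NULL.
#' @return list of class `eval_report`: `n`, `pseudo_r2`, `deviance_full`,
#'   `deviance_base`, `coef`, `se`, `pvalue`, `converged`,
#'   `model = "logistic"`.
#' @export
logistic_pseudo_r2 <- function(y, prs, covars = NULL) {
  df <- eval_frame(y, prs, covars)
  if (length(unique(df$y)) < 2L) stop("logistic_pseudo_r2: only one class present")
  full <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  base <- suppressWarnings(
    stats::glm(y ~ ., data = df[, setdiff(names(df), "prs"), drop = FALSE],
               family = stats::binomial()))
  d1 <- stats::deviance(full)
  d0 <- stats::deviance(base)
  converged <- full$converged && base$converged
  if (!converged) warning("logistic_pseudo_r2: fit did not converge (possible separation)")
  cm <- summary(full)$coefficients
  aliased <- !("prs" %in% rownames(cm))  # constant PRS is dropped by the fit
  ct <- if (!aliased) cm["prs", ] else
    c(Estimate = NA_real_, `Std. Error` = NA_real_, `Pr(>|z|)` = NA_real_)
  structure(list(n = nrow(df),
                 pseudo_r2 = if (aliased) 0 else 1 - d1 / d0,
                 deviance_full = d1, deviance_base = d0,
                 coef = unname(ct["Estimate"]), se = unname(ct["Std. Error"]),
                 pvalue = unname(ct["Pr(>|z|)"]),
                 converged = converged,
                 model = "logistic"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s), n = %d\n", x$model, x$n))
  if (x$model == "linear") {
    cat(sprintf("  incremental R2 = %.6f (full %.6f, base %.6f)\n",
                x$r2_incremental, x$r2_full, x$r2_base))
  } else {
    cat(sprintf("  McFadden pseudo-R2 = %.6f (d1 %.2f, d0 %.2f)\n",
                x$pseudo_r2, x$deviance_full, x$deviance_base))
  }
  cat(sprintf("  PRS coef = %.4g (SE %.3g), p = %.3g\n", x$coef, x$se, x$pvalue))
  invisible(x)
}

#' Compare PRS distributions between two phenotype groups
#'
#' Welch two-sample t-test on the scores of cases vs controls (e.g. short vs
#' long sleepers), with group means and SDs at full precision.
#'
#' @param prs numeric scores.
#' @param labels binary labels as from [dichotomize()] (1/0, NA dropped).
#' @return list: per-group `n`, `mean`, `sd`; `difference` (case - control),
#'   `t`, `df`, `pvalue`.
#' @export
group_prs_compare <- function(prs, labels) {
  ok <- !is.na(prs) & !is.na(labels)
  a <- prs[ok & labels == 1]
  b <- prs[ok & labels == 0]
  if (length(a) < 2L || length(b) < 2L) {
    stop("group_prs_compare: each group needs at least 2 members")
  }
  tt <- welch_or_degenerate(a, b)
  list(n = c(case = length(a), control = length(b)),
       mean = c(case = mean(a), control = mean(b)),
       sd = c(case = stats::sd(a), control = stats::sd(b)),
       difference = mean(a) - mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value)
}

#' Trait contrast between the extreme tails of the PRS distribution
#'
#' Compares the mean trait value of samples in the top and bottom `q`
#' fraction of the score distribution (nearest-rank quantiles, ties kept, so
#' groups may exceed `q*n`). Means are raw — no covariate adjustment. When
#' the trait is in hours the difference is also reported in minutes.
#'
#' @param prs numeric scores (must not be constant).
#' @param trait continuous trait (e.g. sleep duration in hours).
#' @param q tail fraction. Default 0.05.
#' @return list: per-tail `n`, `mean`, `sd`; `difference` (top - bottom),
#'   `difference_minutes`, `t`, `pvalue` (Welch).
#' @export
tail_contrast <- function(prs, trait, q = 0.05) {
  ok <- !is.na(prs) & !is.na(trait)
  prs <- prs[ok]; trait <- trait[ok]
  n <- length(prs)
  if (n < 2 / q) stop("tail_contrast: too few samples for the requested tails")
  if (max(prs) == min(prs)) stop("tail_contrast: degenerate (constant) PRS")
  srt <- sort(prs)
  k <- ceiling(q * n)  # nearest-rank
  lo_thr <- srt[k]
  hi_thr <- srt[n - k + 1L]
  bottom <- prs <= lo_thr
  top <- prs >= hi_thr
  mt <- mean(trait[top]); mb <- mean(trait[bottom])
  tt <- welch_or_degenerate(trait[top], trait[bottom])
  list(n = c(top = sum(top), bottom = sum(bottom)),
       mean = c(top = mt, bottom = mb),
       sd = c(top = stats::sd(trait[top]), bottom = stats::sd(trait[bottom])),
       difference = mt - mb,
       difference_minutes = (mt - mb) * 60,
       t = unname(tt$statistic),
       pvalue = tt$p.value)
}
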