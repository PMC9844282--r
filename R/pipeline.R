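#' Default pipeline configuration
#'
#' Every threshold of the analysis is a named key so the defaults are
#' self-documenting: summary-stat filters INFO > 0.8 and MAF > 0.01; target
#' variant filter INFO >= 0.9, autosomes only; heterozygosity outliers at
#' 3 SD; relatedness cutoff 0.125; clumping p < 5e-4 within a 250 kb radius
#' at r2 0.1; pruning mirrors the clumping geometry; 6 principal components;
#' 5% score tails.
#'
#' @param seed master seed.
#' @return a named list; pass (possibly modified) to [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_discovery = 20000, n_target = 5000, n_variants = 2000,
                    block_size = 50, rho = 0.8),
    sumstats_info_min = 0.8,
    sumstats_maf_min = 0.01,
    target_info_min = 0.9,
    autosomes_only = TRUE,
    het_sd_mult = 3,
    rel_cutoff = 0.125,
    clump_p_max = 5e-4,
    clump_window_kb = 250,
    clump_r2 = 0.1,
    prune_window_kb = 250,
    prune_step = 1,
    prune_r2 = 0.1,
    n_pcs = 6,
    tail_q = 0.05,
    score_mode = "average"
  )
}

#' Read a pipeline configuration from JSON
#'
#' Flat key/value JSON; keys absent from the file take the
#' [default_config()] values. Round-trips losslessly (`digits = NA`).
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(seed = user$seed %||% 1)
  if (!("simulate" %in% names(user))) cfg$simulate <- NULL
  cfg[names(user)] <- user
  cfg
}

#' Write a pipeline configuration to JSON
#' @param config configuration list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

stage_entry <- function(manifest, name, n_in, n_out, detail = NULL) {
  manifest$stages[[name]] <- c(list(n_in = n_in, n_out = n_out), detail)
  manifest
}

#' Run the full portability pipeline
#'
#' Executes summary-statistic QC, target cohort QC, structure (pruning +
#' PCA), clumping + scoring, and evaluation, in that order, failing fast
#' with the offending stage named. Inputs are either simulated (a
#' `simulate` stanza in the config) or loaded from the configured paths
#' (`sumstats_path` — one file or a named list per trait; `dosage_path` +
#' `variants_path` or `vcf_path`; `phenotype_path`).
#'
#' @param config configuration list (see [default_config()]), or a path to a
#'   JSON config file.
#' @param out_dir optional directory; when given, scores, PC scores, clump
#'   tables, QC reports and the JSON manifest are written there.
#' @return list of class `prs_run`: `manifest`, `reports` (per trait:
#'   linear/logistic/tails/groups as applicable), `scores` (named list of
#'   score tables), `pcs`, `clumps`, `qc`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- default_config(seed = config$seed %||% 1)
  # the simulate stanza is opt-in: only honored when the caller's config
  # carries it (default_config() does), so path-based configs never silently
  # fall back to simulation
  cfg$simulate <- NULL
  cfg[names(config)] <- config
  config <- cfg
  manifest <- list(config_hash = hash_config(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("prsport")),
                   stages = list())

  stage <- "inputs"
  res <- tryCatch({
    # ---- inputs -------------------------------------------------------------
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sc <- sim_config(n_discovery = sim$n_discovery %||% 20000,
                       n_target = sim$n_target %||% 5000,
                       n_variants = sim$n_variants %||% 2000,
                       block_size = sim$block_size %||% 50,
                       rho = sim$rho %||% 0.8,
                       traits = if (!is.null(sim$traits)) sim$traits else default_sim_traits(),
                       seed = config$seed)
      exp <- make_portability_experiment(sc)
      sumstats_raw <- exp$sumstats
      target <- exp$target
      pheno_raw <- exp$phenotypes
    } else {
      if (is.null(config$sumstats_path)) stop("config names neither inputs nor a simulate stanza")
      paths <- config$sumstats_path
      if (!is.list(paths)) paths <- list(trait = paths)
      sumstats_raw <- lapply(paths, read_sumstats)
      target <- if (!is.null(config$vcf_path)) {
        read_dosage_vcf(config$vcf_path)
      } else {
        read_dosage_tsv(config$dosage_path, config$variants_path)
      }
      pheno_raw <- data.table::fread(config$phenotype_path, sep = "\t",
                                     data.table = FALSE)
    }
    traits <- names(sumstats_raw)

    # ---- cohort_qc ----------------------------------------------------------
    stage <- "cohort_qc"
    n0 <- nrow(target$variants)
    target <- filter_variants_target(target, info_min = config$target_info_min,
                                     autosomes_only = config$autosomes_only)
    sqc <- run_sample_qc(target, het_sd_mult = config$het_sd_mult,
                         rel_cutoff_value = config$rel_cutoff)
    target <- sqc$geno
    manifest <- stage_entry(manifest, "cohort_qc", n0, nrow(target$variants),
                            list(n_samples_in = nrow(sqc$report),
                                 n_samples_out = length(target$samples),
                                 n_het_removed = sum(sqc$report$reason %in% "heterozygosity"),
                                 n_rel_removed = sum(sqc$report$reason %in% "relatedness")))

    # ---- sumstats_qc --------------------------------------------------------
    stage <- "sumstats_qc"
    weights_by_trait <- list()
    ss_detail <- list()
    for (tr in traits) {
      flt <- filter_sumstats(sumstats_raw[[tr]],
                             info_min = config$sumstats_info_min,
                             maf_min = config$sumstats_maf_min)
      weights_by_trait[[tr]] <- harmonize_weights(flt$kept, target$variants)
      ss_detail[[tr]] <- list(n_in = nrow(sumstats_raw[[tr]]),
                              n_kept = nrow(flt$kept),
                              exclusions = as.list(flt$counts),
                              n_mismatch = attr(weights_by_trait[[tr]], "n_mismatch"))
    }
    manifest <- stage_entry(manifest, "sumstats_qc",
                            sum(vapply(sumstats_raw, nrow, integer(1))),
                            sum(vapply(weights_by_trait, nrow, integer(1))),
                            list(per_trait = ss_detail))

    # ---- structure ----------------------------------------------------------
    stage <- "structure"
    pruned <- ld_prune(target, window_kb = config$prune_window_kb,
                       step_variants = config$prune_step,
                       r2_max = config$prune_r2)
    pcs <- pca_scores(target, variants = pruned, k = config$n_pcs)
    manifest <- stage_entry(manifest, "structure", nrow(target$variants),
                            length(pruned), list(n_pcs = ncol(pcs$scores)))

    # ---- clump_score --------------------------------------------------------
    stage <- "clump_score"
    clumps <- list()
    scores <- list()
    for (tr in traits) {
      cs <- clump(weights_by_trait[[tr]], target,
                  p_max = config$clump_p_max,
                  window_kb = config$clump_window_kb, r2 = config$clump_r2)
      if (nrow(cs$index) == 0L) stop("no eligible variants after clumping")
      ikey <- variant_key(cs$index$chrom, cs$index$pos)
      wkey <- variant_key(weights_by_trait[[tr]]$chrom, weights_by_trait[[tr]]$pos)
      w <- weights_by_trait[[tr]][match(ikey, wkey), , drop = FALSE]
      scores[[tr]] <- compute_prs(target, w, mode = config$score_mode)
      clumps[[tr]] <- cs
    }
    manifest <- stage_entry(manifest, "clump_score",
                            sum(vapply(weights_by_trait, nrow, integer(1))),
                            sum(vapply(clumps, function(x) nrow(x$index), integer(1))))

    # ---- evaluate -----------------------------------------------------------
    stage <- "evaluate"
    pheno <- prepare_phenotypes(pheno_raw, seed = config$seed)
    covars <- data.frame(age = pheno$age, sex = pheno$sex)
    covars <- cbind(covars, as.data.frame(
      pcs$scores[match(pheno$sample, rownames(pcs$scores)), , drop = FALSE]))
    reports <- list()
    for (tr in traits) {
      prs <- score_values(scores[[tr]])[match(pheno$sample, scores[[tr]]$sample)]
      y <- pheno[[tr]]
      rep_tr <- list()
      if (tr != "insomnia") {  # insomnia is evaluated with the logistic model only
        rep_tr$linear <- linear_incremental_r2(y, prs, covars)
      }
      rule <- switch(tr, chronotype = "chronotype_extremes",
                     sleep_duration = "sleep_extremes",
                     insomnia = "insomnia_finrisk", NULL)
      if (!is.null(rule)) {
        labels <- dichotomize(y, rule)
        if (length(unique(stats::na.omit(labels))) == 2L) {
          rep_tr$logistic <- logistic_pseudo_r2(labels, prs, covars)
          rep_tr$groups <- group_prs_compare(prs, labels)
        }
      }
      if (tr == "sleep_duration") {
        rep_tr$tails <- tail_contrast(prs, y, q = config$tail_q)
      }
      reports[[tr]] <- rep_tr
    }
    manifest <- stage_entry(manifest, "evaluate", nrow(pheno_raw), nrow(pheno))

    list(manifest = manifest, reports = reports, scores = scores, pcs = pcs,
         clumps = clumps, qc = sqc$report)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_run(res, out_dir)
  class(res) <- "prs_run"
  res
}

#' Write a pipeline run to disk
#'
#' Emits per-trait score TSVs and clump tables, PC scores, the sample QC
#' report, per-trait evaluation JSON and the run manifest JSON. All output is
#' deterministic for a fixed config + seed (no timestamps).
#'
#' @param res a `prs_run` (or the list [run_pipeline()] builds).
#' @param out_dir output directory (created if absent).
#' @return invisibly, `out_dir`.
#' @export
write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in names(res$scores)) {
    data.table::fwrite(res$scores[[tr]],
                       file.path(out_dir, paste0("scores_", tr, ".tsv")),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(clump_table(res$clumps[[tr]]),
                       file.path(out_dir, paste0("clumps_", tr, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  write_pc_scores(res$pcs, file.path(out_dir, "pcs.tsv"))
  data.table::fwrite(res$qc, file.path(out_dir, "sample_qc.tsv"), sep = "\t",
                     quote = FALSE)
  jsonlite::write_json(res$reports, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.prs_run <- function(x, ...) {
  cat("prs_run, config", x$manifest$config_hash, "\n")
  for (tr in names(x$reports)) {
    r <- x$reports[[tr]]
    cat(sprintf("- %s:", tr))
    if (!is.null(r$linear)) {
      cat(sprintf(" dR2 = %.4f (p = %.2g)", r$linear$r2_incremental,
                  r$linear$pvalue))
    }
    if (!is.null(r$logistic)) {
      cat(sprintf(" pseudo-R2 = %.4f (p = %.2g)", r$logistic$pseudo_r2,
                  r$logistic$pvalue))
    }
    if (!is.null(r$tails)) {
      cat(sprintf(" tail diff = %.1f min", r$tails$difference_minutes))
    }
    cat("\n")
  }
  invisible(x)
}
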