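#' Default summary-statistics column map
#'
#' Maps the canonical field names used internally to the column names found in
#' the input file. Override any entry to read files with different headers.
#'
#' @return named character vector.
#' @export
sumstats_cols <- function() {
  c(chrom = "chrom", pos = "pos", effect_allele = "effect_allele",
    other_allele = "other_allele", beta = "beta", se = "se",
    pvalue = "pvalue", eaf = "eaf", info = "info")
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file (gzip accepted) into one row
#' per variant. Rows that cannot be parsed into a valid record — non-numeric
#' beta/SE/p, indel or non-ACGT alleles, identical alleles, non-autosomal
#' chromosome, out-of-range p/EAF/INFO/SE — are rejected and reported with
#' their line numbers in the `"rejected"` attribute.
#'
#' @param path input file path.
#' @param col_map named character vector mapping canonical names (see
#'   [sumstats_cols()]) to the file's column names.
#' @return data.frame with columns `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, `eaf`, `info`; attribute
#'   `rejected` is a data.frame of (line, reason).
#' @export
read_sumstats <- function(path, col_map = sumstats_cols()) {
  defaults <- sumstats_cols()
  col_map <- c(col_map, defaults[setdiff(names(defaults), names(col_map))])
  raw <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           colClasses = "character")
  missing_cols <- col_map[!(col_map %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop("summary statistics file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- data.frame(
    chrom = sub("^chr", "", raw[[col_map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(raw[[col_map[["pos"]]]])),
    effect_allele = toupper(raw[[col_map[["effect_allele"]]]]),
    other_allele = toupper(raw[[col_map[["other_allele"]]]]),
    beta = suppressWarnings(as.numeric(raw[[col_map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[col_map[["se"]]]])),
    pvalue = suppressWarnings(as.numeric(raw[[col_map[["pvalue"]]]])),
    eaf = suppressWarnings(as.numeric(raw[[col_map[["eaf"]]]])),
    info = suppressWarnings(as.numeric(raw[[col_map[["info"]]]])),
    stringsAsFactors = FALSE)

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(!(x$chrom %in% as.character(1:22)), "non-autosomal chromosome")
  reason <- flag(is.na(x$pos) | x$pos < 1, "invalid position")
  reason <- flag(!(x$effect_allele %in% c("A", "C", "G", "T")) |
                   !(x$other_allele %in% c("A", "C", "G", "T")),
                 "non-SNV or non-ACGT allele")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reason <- flag(is.na(x$beta), "non-numeric beta")
  reason <- flag(is.na(x$se) | x$se <= 0, "invalid SE")
  reason <- flag(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1, "invalid p-value")
  reason <- flag(is.na(x$eaf) | x$eaf <= 0 | x$eaf >= 1, "EAF outside (0,1)")
  reason <- flag(is.na(x$info) | x$info < 0 | x$info > 1, "INFO outside [0,1]")

  bad <- !is.na(reason)
  rejected <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    message(sprintf("read_sumstats: rejected %d of %d row(s)",
                    nrow(rejected), nrow(x)))
  }
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Is a variant strand-ambiguous?
#'
#' A/T and C/G SNVs read the same on both strands, so strand alignment between
#' a discovery and a target dataset is undecidable without frequency matching.
#'
#' @param a1,a2 allele characters (vectorized).
#' @return logical vector: TRUE iff \{a1, a2\} is \{A,T\} or \{C,G\}.
#' @export
is_strand_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  assert_single_base(c(a1, a2))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[a1] == a2)
}

#' Filter summary statistics for scoring
#'
#' Keeps variants passing, in this fixed attribution order: not multiallelic
#' (its chrom:pos occurs once in the input), not strand-ambiguous,
#' INFO > `info_min`, MAF > `maf_min` (strict inequalities). A removed variant
#' is counted against the first rule it fails, so the exclusion counts always
#' partition the removed set.
#'
#' @param stats data.frame from [read_sumstats()].
#' @param info_min minimum imputation quality (exclusive). Default 0.8.
#' @param maf_min minimum minor allele frequency (exclusive). Default 0.01.
#' @return list with `kept` (data.frame) and `counts` (named integer:
#'   multiallelic, ambiguous, low_info, low_maf).
#' @export
filter_sumstats <- function(stats, info_min = 0.8, maf_min = 0.01) {
  key <- variant_key(stats$chrom, stats$pos)
  multi <- key %in% key[duplicated(key)]
  ambiguous <- if (nrow(stats) > 0L) {
    is_strand_ambiguous(stats$effect_allele, stats$other_allele)
  } else logical(0)
  low_info <- stats$info <= info_min
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  low_maf <- maf <= maf_min

  reason <- rep(NA_character_, nrow(stats))
  reason[low_maf] <- "low_maf"
  reason[low_info] <- "low_info"
  reason[ambiguous] <- "ambiguous"
  reason[multi] <- "multiallelic"

  counts <- c(multiallelic = sum(reason == "multiallelic", na.rm = TRUE),
              ambiguous = sum(reason == "ambiguous", na.rm = TRUE),
              low_info = sum(reason == "low_info", na.rm = TRUE),
              low_maf = sum(reason == "low_maf", na.rm = TRUE))
  kept <- stats[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejected") <- NULL
  list(kept = kept, counts = counts)
}

#' Harmonize summary-statistic weights to target-counted alleles
#'
#' Aligns each summary-statistic effect to the allele the target cohort
#' counts: if the effect allele is the counted allele the weight is `beta`;
#' if the allele pair is swapped the weight is `-beta` (flipped); any other
#' allele-set mismatch drops the variant. Variants absent from the target are
#' simply not returned (they cannot be scored).
#'
#' @param stats filtered summary statistics.
#' @param target_variants data.frame with `chrom`, `pos`, `counted`, `other`
#'   (e.g. the `variants` element of a [dosage_matrix()]).
#' @return data.frame (`chrom`, `pos`, `counted`, `other`, `weight`,
#'   `flipped`, `pvalue`); attribute `n_mismatch` counts allele-set
#'   mismatches.
#' @export
harmonize_weights <- function(stats, target_variants) {
  tkey <- variant_key(target_variants$chrom, target_variants$pos)
  if (anyDuplicated(tkey)) stop("duplicate variant keys in target")
  skey <- variant_key(stats$chrom, stats$pos)
  idx <- match(skey, tkey)
  present <- !is.na(idx)
  s <- stats[present, , drop = FALSE]
  t <- target_variants[idx[present], , drop = FALSE]

  same <- s$effect_allele == t$counted & s$other_allele == t$other
  swapped <- s$effect_allele == t$other & s$other_allele == t$counted
  mism <- !(same | swapped)

  out <- data.frame(chrom = s$chrom, pos = s$pos,
                    counted = t$counted, other = t$other,
                    weight = ifelse(same, s$beta, -s$beta),
                    flipped = swapped,
                    pvalue = s$pvalue,
                    stringsAsFactors = FALSE)
  out <- out[!mism, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_mismatch") <- sum(mism)
  out
}

#' Write filtered summary statistics and a QC report
#'
#' @param filtered result of [filter_sumstats()].
#' @param tsv_path output TSV for the kept records.
#' @param json_path output JSON QC report (exclusion counts).
#' @return invisibly, the two paths.
#' @export
write_sumstats_qc <- function(filtered, tsv_path, json_path) {
  data.table::fwrite(filtered$kept, tsv_path, sep = "\t", quote = FALSE)
  report <- list(n_kept = nrow(filtered$kept),
                 n_excluded = sum(filtered$counts),
                 exclusions = as.list(filtered$counts))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv_path, json_path))
}
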