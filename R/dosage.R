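#' Dosage matrix container
#'
#' The package's genotype container: an `n_samples x n_variants` matrix of
#' effect-allele dosages in \[0, 2\] (NA = missing) plus per-variant metadata.
#' The counted allele is the allele whose copies the dosage counts; `freq` is
#' its frequency.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns; values
#'   in \[0, 2\] or NA.
#' @param variants data.frame with columns `chrom` (autosome label, or "X"
#'   etc. pre-QC), `pos` (1-based), `counted`, `other` (single bases), and
#'   optionally `info` (imputation quality in \[0, 1\]) and `freq`.
#' @param samples character vector of sample ids (defaults to rownames or
#'   `S1..Sn`).
#' @return an object of class `dosage_matrix` with elements `dosages`,
#'   `variants`, `samples`.
#' @export
dosage_matrix <- function(dosages, variants, samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(ncol(dosages) == nrow(variants))
  req <- c("chrom", "pos", "counted", "other")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L) {
    stop("variant metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  key <- variant_key(variants$chrom, variants$pos)
  if (anyDuplicated(key)) stop("duplicate variant keys in dosage matrix")
  if (is.null(samples)) {
    samples <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  }
  stopifnot(length(samples) == nrow(dosages))
  dimnames(dosages) <- list(samples, key)
  structure(list(dosages = dosages, variants = variants,
                 samples = as.character(samples)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  if (!is.null(x$variants$info)) {
    cat(sprintf("  INFO range: [%.3f, %.3f]\n",
                min(x$variants$info), max(x$variants$info)))
  }
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Subset a dosage matrix
#'
#' @param x a `dosage_matrix`.
#' @param samples sample index (logical/integer/character) or NULL for all.
#' @param variants variant index or NULL for all.
#' @return a `dosage_matrix`.
#' @export
subset_dosage <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "dosage_matrix"))
  si <- samples %||% seq_along(x$samples)
  vi <- variants %||% seq_len(nrow(x$variants))
  dosage_matrix(x$dosages[si, vi, drop = FALSE],
                x$variants[vi, , drop = FALSE],
                samples = x$samples[si])
}

#' Counted-allele frequencies recomputed from dosages
#'
#' Mean dosage over non-missing entries, halved. Variants that are entirely
#' missing get NA.
#'
#' @param geno a `dosage_matrix`.
#' @return numeric vector, one frequency per variant.
#' @export
variant_freq <- function(geno) {
  stopifnot(inherits(geno, "dosage_matrix"))
  colMeans(geno$dosages, na.rm = TRUE) / 2
}

# ---- text I/O ---------------------------------------------------------------

#' Read a dosage matrix from TSV
#'
#' The primary on-disk representation: a dosage TSV (first column `sample`,
#' one column per variant keyed `chrom:pos`) with a sidecar variant-metadata
#' TSV (`chrom`, `pos`, `counted`, `other`, optional `info`, `freq`).
#'
#' @param dosage_path path to the dosage TSV (gzip accepted).
#' @param variants_path path to the variant metadata TSV.
#' @return a `dosage_matrix`.
#' @export
read_dosage_tsv <- function(dosage_path, variants_path) {
  d <- data.table::fread(dosage_path, sep = "\t", data.table = FALSE)
  v <- data.table::fread(variants_path, sep = "\t", data.table = FALSE)
  if (names(d)[1] != "sample") stop("dosage TSV must start with a 'sample' column")
  m <- as.matrix(d[, -1, drop = FALSE])
  key <- variant_key(v$chrom, v$pos)
  if (!identical(colnames(m), key)) {
    idx <- match(colnames(m), key)
    if (anyNA(idx)) stop("dosage columns do not match variant metadata keys")
    v <- v[idx, , drop = FALSE]
  }
  dosage_matrix(m, v, samples = d$sample)
}

#' Write a dosage matrix to TSV
#'
#' @param geno a `dosage_matrix`.
#' @param dosage_path,variants_path output paths.
#' @return invisibly, the two paths.
#' @export
write_dosage_tsv <- function(geno, dosage_path, variants_path) {
  stopifnot(inherits(geno, "dosage_matrix"))
  d <- data.frame(sample = geno$samples, geno$dosages, check.names = FALSE)
  data.table::fwrite(d, dosage_path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(geno$variants, variants_path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(c(dosage_path, variants_path))
}

#' Read target genotypes from VCF
#'
#' Uses Bioconductor VariantAnnotation. The DS (dosage) FORMAT field is
#' preferred; GT is used otherwise (dosages counted on the ALT allele). INFO
#' quality is read from the `INFO`-named INFO field when present, else 1.
#' Multiallelic records are dropped with a warning.
#'
#' @param path path to a VCF (text or bgzip).
#' @return a `dosage_matrix` counting the ALT allele.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_dosage_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  keep <- n_alt == 1L
  if (!all(keep)) {
    warning(sprintf("dropping %d multiallelic VCF record(s)", sum(!keep)))
    vcf <- vcf[keep, ]
    alt <- alt[keep]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    dos <- t(geno$DS)
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    dos <- t(apply(gt, c(1, 2), function(g) {
      if (g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    }))
  } else {
    stop("VCF has neither DS nor GT FORMAT fields")
  }
  info_df <- VariantAnnotation::info(vcf)
  info <- if ("INFO" %in% names(info_df)) as.numeric(info_df$INFO) else rep(1, nrow(vcf))
  variants <- data.frame(
    chrom = sub("^chr", "", as.character(GenomeInfoDb::seqnames(rr))),
    pos = BiocGenerics::start(rr),
    counted = as.character(unlist(alt)),
    other = as.character(rr$REF),
    info = info,
    stringsAsFactors = FALSE)
  g <- dosage_matrix(dos, variants, samples = colnames(vcf))
  g$variants$freq <- variant_freq(g)
  g
}

#' Write a dosage matrix as a minimal VCF
#'
#' Emits a VCFv4.2 text file with a DS FORMAT field (REF = other allele,
#' ALT = counted allele) and an INFO=<imputation quality> INFO field.
#'
#' @param geno a `dosage_matrix`.
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
write_dosage_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "dosage_matrix"))
  v <- geno$variants
  info <- v$info %||% rep(1, nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Counted-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- geno$dosages[, j]
    ds_chr <- ifelse(is.na(ds), ".", formatC(ds, format = "g", digits = 6))
    paste(c(v$chrom[j], v$pos[j], ".", v$other[j], v$counted[j], ".", "PASS",
            sprintf("INFO=%s", formatC(info[j], format = "g", digits = 6)),
            "DS", ds_chr), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
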