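`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' operations (phenotype preparation, simulation stages) never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 32-bit FNV-1a over a character string; pure-R, exact (products kept < 2^53
# by splitting the hash into 16-bit halves).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# bitwXor for doubles in [0, 2^32): R's bitwXor works on 32-bit signed ints.
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

#' Derive a per-stage seed from a master seed
#'
#' All randomness in the package flows through one master seed; each stage
#' (genotype simulation, phenotype simulation, answer selection, ...) draws
#' from its own stream labelled by name, so any stage is reproducible in
#' isolation. The derived seed is kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  as.integer(fnv1a32(paste0(format(seed, scientific = FALSE), "/", label)) %% 2147483647)
}

#' Hash a configuration list
#'
#' Deterministic 32-bit hash of the canonical JSON serialization; used in run
#' manifests so identical configurations are recognizable across runs.
#'
#' @param config a list.
#' @return 8-character hex string.
#' @export
hash_config <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  h <- fnv1a32(as.character(json))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# variant key used for joins throughout: build-identical match on position.
# (paste0 recycles the literal ":" to length 1 on empty input, hence the guard.)
variant_key <- function(chrom, pos) {
  if (length(chrom) == 0L) return(character(0))
  paste0(chrom, ":", pos)
}

assert_single_base <- function(a, what = "allele") {
  bad <- !(a %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop(sprintf("%s must be one of A/C/G/T, got: %s", what,
                 paste(unique(a[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
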