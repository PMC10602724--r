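## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Stable 31-bit string hash (FNV-1a)
#'
#' Deterministic across platforms and sessions; used to derive per-entity
#' sub-seeds so results do not depend on iteration order.
#' @noRd
stable_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\r")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # XOR on the low 31 bits, keeping the top bit additively (R's bitwXor is
    # restricted to ints); b < 2^8 so only low bits participate.
    top <- h - h %% 2147483648
    h <- top + bitwXor(as.integer(h %% 2147483648), as.integer(b))
    # multiply by the FNV prime mod 2^32 via 16-bit split (stays < 2^53)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * prime + ((h1 * prime) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

#' Derive a child seed from a parent seed and a character key
#' @noRd
derive_seed <- function(seed, key) {
  as.integer((as.double(seed) * 48271 + stable_hash(key)) %% 2147483647)
}

#' Equal-frequency binning into `n_bins` bins
#'
#' Ties broken by first occurrence (stable); returns integer bin codes in
#' `1..n_bins`. A constant vector maps entirely to bin 1.
#' @noRd
ef_bin <- function(x, n_bins) {
  n <- length(x)
  if (length(unique(x)) == 1L) return(rep(1L, n))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

#' Default bin count: floor(sqrt(n/5)) clamped to [2, 10]
#' @noRd
default_bins <- function(n) {
  max(2L, min(10L, as.integer(floor(sqrt(n / 5)))))
}

#' Shannon entropy (bits) of a count vector
#' @noRd
entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Overlap wrappers that tolerate query/subject on disjoint chromosome sets
## (GenomeInfoDb warns when merging Seqinfo with no common levels; here that
## simply means "no overlap" and the warning is noise).
quiet_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

quiet_overlaps_any <- function(query, subject) {
  suppressWarnings(IRanges::overlapsAny(query, subject))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
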