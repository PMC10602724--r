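## PWM scanning with exact p-values.
##
## Scores are log-odds (bits) against a mononucleotide background, quantized
## to a fixed step; the null score distribution is computed exactly by
## dynamic programming (convolution over PWM columns under the background),
## so the p < 1e-4 hit gate is deterministic — no shuffling involved.

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

dna_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- BASE_CODE[chars]
  code[is.na(code)] <- 0L  # N or other ambiguity codes
  unname(code)
}

revcomp_pwm_matrix <- function(m) {
  # complement rows (A<->T, C<->G) and reverse columns
  m[c(4, 3, 2, 1), rev(seq_len(ncol(m))), drop = FALSE]
}

## Quantized log-odds matrix and the exact tail distribution of the total
## quantized score under the background model.
pwm_score_model <- function(pwm, step = 0.01) {
  lo <- log2(pwm_probs(pwm) / pwm$background)
  q <- round(lo / step)
  L <- ncol(q)
  cmin <- apply(q, 2, min)
  cmax <- apply(q, 2, max)
  total_min <- sum(cmin)
  total_max <- sum(cmax)
  # DP over offsets from total_min
  dist <- 1
  off <- 0L
  for (j in seq_len(L)) {
    width <- cmax[j] - cmin[j]
    newdist <- numeric(length(dist) + width)
    for (b in 1:4) {
      o <- q[b, j] - cmin[j]
      idx <- seq_along(dist) + o
      newdist[idx] <- newdist[idx] + pwm$background[b] * dist
    }
    dist <- newdist
  }
  stopifnot(abs(sum(dist) - 1) < 1e-9)
  tail_p <- rev(cumsum(rev(dist)))  # tail_p[k] = P(score_int >= total_min+k-1)
  list(q = q, step = step, total_min = total_min, total_max = total_max,
       tail_p = tail_p, L = L)
}

## p-value for integer quantized scores under a score model.
model_pvalue <- function(model, s_int) {
  k <- s_int - model$total_min + 1
  k <- pmax(1, pmin(length(model$tail_p), k))
  out <- model$tail_p[k]
  out[s_int < model$total_min] <- 1
  out
}

scan_one_strand <- function(codes, q) {
  L <- ncol(q)
  n <- length(codes)
  if (n < L) return(integer(0))
  npos <- n - L + 1L
  s <- rep(0L, npos)
  valid <- rep(TRUE, npos)
  for (j in seq_len(L)) {
    cj <- codes[j:(npos + j - 1L)]
    ok <- cj > 0L
    valid <- valid & ok
    cj[!ok] <- 1L
    s <- s + q[cbind(cj, j)]
  }
  s[!valid] <- NA_integer_
  s
}

#' Scan a DNA sequence with a PWM, exact p-values per hit
#'
#' Scores every position on both strands by quantized log-odds against the
#' PWM's background model; each score's p-value is exact under the
#' background, computed by dynamic programming over the PWM's discretized
#' score distribution (quantization step <= 0.01 bits). Positions containing
#' ambiguity codes (N) are skipped.
#'
#' @param sequence DNA string over ACGTN.
#' @param pwm A [new_pwm()] object.
#' @param p_thresh Report positions with p-value strictly below this.
#' @param model Optional precomputed score model (internal reuse).
#' @return data.frame with `pwm_id`, `offset` (0-based, on the given
#'   sequence), `strand`, `score` (bits), `p_value`; one row per hit,
#'   overlapping hits reported individually.
#' @export
scan_pwm <- function(sequence, pwm, p_thresh = 1e-4, model = NULL) {
  model <- model %||% pwm_score_model(pwm)
  codes <- dna_codes(sequence)
  empty <- data.frame(pwm_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (length(codes) < model$L) return(empty)
  q_rc <- revcomp_pwm_matrix(model$q)
  out <- list()
  for (strand in c("+", "-")) {
    s <- scan_one_strand(codes, if (strand == "+") model$q else q_rc)
    ok <- which(!is.na(s))
    if (length(ok) == 0) next
    pv <- model_pvalue(model, s[ok])
    hit <- pv < p_thresh
    if (!any(hit)) next
    out[[strand]] <- data.frame(
      pwm_id = pwm$motif_id,
      offset = ok[hit] - 1L,
      strand = strand,
      score = s[ok][hit] * model$step,
      p_value = pv[hit],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) empty else do.call(rbind, c(out, make.row.names = FALSE))
}

#' Scan genomic regions with a set of PWMs
#'
#' Extracts region sequences from the genome and applies [scan_pwm()] per
#' PWM, mapping hits back to genomic coordinates.
#'
#' @param genome `DNAStringSet` from [read_fasta()].
#' @param regions `GRanges` with a `name` column.
#' @param pwms Named list of `pwm` objects.
#' @param p_thresh Hit p-value gate.
#' @return data.frame with `pwm_id`, `region`, `chrom`, `start`, `end`
#'   (0-based half-open genomic), `strand`, `score`, `p_value`.
#' @export
scan_regions <- function(genome, regions, pwms, p_thresh = 1e-4) {
  seqs <- extract_sequences(genome, regions)
  rnames <- S4Vectors::mcols(regions)$name
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  rstart0 <- GenomicRanges::start(regions) - 1L
  res <- list()
  for (p in pwms) {
    model <- pwm_score_model(p)
    for (i in seq_along(seqs)) {
      h <- scan_pwm(seqs[i], p, p_thresh, model = model)
      if (nrow(h) == 0) next
      res[[length(res) + 1L]] <- data.frame(
        pwm_id = h$pwm_id, region = rnames[i], chrom = rchrom[i],
        start = rstart0[i] + h$offset,
        end = rstart0[i] + h$offset + ncol(p$counts),
        strand = h$strand, score = h$score, p_value = h$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0) {
    return(data.frame(pwm_id = character(), region = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Genome mononucleotide background frequencies
#' @param genome `DNAStringSet`.
#' @return Length-4 probability vector over A, C, G, T.
#' @export
genome_background <- function(genome) {
  freq <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                                        drop = FALSE])
  as.numeric(freq / sum(freq))
}
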