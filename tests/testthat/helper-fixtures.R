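# Shared fixtures, built in code at test time.

# Small cohort used by module tests; 50/50 samples so the stage-2
# significance gates are attainable at this scale.
small_cohort_config <- function(seed = 11) {
  cohort_config(n_cancer = 50, n_normal = 50, n_se = 40,
                frac_activated = 0.25, n_genes = 200, frac_linked = 0.5,
                n_tfs = 12, n_crc_tfs = 2, n_ctp_triples = 8, seed = seed)
}

# Generated once per test session and reused (read-only) across test files.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "secrc_small_cohort")
      cache <<- generate_cohort(small_cohort_config(), dir)
    }
    cache
  }
})

# A sharply informative PWM whose consensus is `consensus`.
test_pwm <- function(id, consensus, strength = 85) {
  L <- nchar(consensus)
  counts <- matrix((100 - strength) / 3, 4, L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  ch <- strsplit(consensus, "")[[1]]
  for (j in seq_len(L)) counts[ch[j], j] <- strength
  new_pwm(id, counts)
}

# Brute-force plug-in MI (bits) over a contingency table: the independent
# oracle for the package's MI implementation.
oracle_mi_bits <- function(joint) {
  n <- sum(joint)
  out <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      pij <- joint[i, j] / n
      if (pij > 0) {
        out <- out + pij * log2(pij / (sum(joint[i, ]) / n *
                                         sum(joint[, j]) / n))
      }
    }
  }
  out
}

# Equal-frequency binning identical in contract to the package's
# (first-occurrence tie-breaking), reimplemented for oracle use.
oracle_bin <- function(x, nb) {
  as.integer(ceiling(rank(x, ties.method = "first") * nb / length(x)))
}

# Independent step-up BH implementation (oracle for bh_adjust).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
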