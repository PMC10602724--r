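## Statistical primitives: trimmed one-tailed rank test, BH adjustment,
## Fisher enrichment, mutual information with permutation Fisher-Z p-values,
## partial Spearman correlation, and a permutation conditional-independence
## test. These are the building blocks every pipeline stage calls.

## Cache of Monte-Carlo null tables for the trimmed-U statistic, keyed by
## (n1, n2, k1, k2, n_null). The trimmed subsets are lowest-order statistics
## and therefore NOT exchangeable between groups, so the classical MWU null
## badly overstates significance (empirical type-I ~0.15 at nominal 0.05);
## the null of the trimmed U under group-label exchangeability is
## distribution-free for continuous data and is sampled exactly here.
.trim_null_cache <- new.env(parent = emptyenv())

trimmed_u_null <- function(n1, n2, k1, k2, n_null = 200000L) {
  key <- paste(n1, n2, k1, k2, n_null, sep = "_")
  tab <- .trim_null_cache[[key]]
  if (!is.null(tab)) return(tab)
  n <- n1 + n2
  ## Positions of group-1 members within the sorted combined sample are a
  ## uniform random n1-subset of 1..n; if sa_i is the i-th smallest such
  ## position, the number of group-2 values below the i-th smallest group-1
  ## value is sa_i - i, capped at k2 once group 2 is trimmed.
  tab <- with_seed(derive_seed(976371L, key), {
    vapply(seq_len(n_null), function(b) {
      sa <- sort.int(sample.int(n, n1))[seq_len(k1)]
      sum(pmin(sa - seq_len(k1), k2))
    }, 0)
  })
  tab <- sort.int(tab)
  .trim_null_cache[[key]] <- tab
  tab
}

#' Trimmed-group one-tailed rank test
#'
#' Compares the low tails of two sample groups: the `floor(trim_fraction*n)`
#' lowest values (minimum 1) are selected from each group and the
#' Mann-Whitney U statistic between the trimmed subsets is computed (average
#' ranks under ties). Because trimmed subsets are order statistics, the
#' classical U null does not apply; the p-value is taken from the exact null
#' distribution of the trimmed U under group-label exchangeability, sampled
#' once per (n1, n2, k1, k2) configuration (2e5 deterministic Monte-Carlo
#' draws, cached). Comparing trimmed low tails is robust to prevalently low
#' signal (e.g. eRNA transcription) while retaining power against genuine
#' group shifts.
#'
#' @param cancer_values,normal_values Numeric vectors (non-finite values are
#'   dropped).
#' @param trim_fraction Fraction in (0, 1] of each group to retain (the
#'   lowest values).
#' @param alternative `"greater"` tests whether the trimmed cancer subset is
#'   stochastically larger than the trimmed normal subset; `"less"` the
#'   converse.
#' @param n_null Monte-Carlo null size (default 2e5; smallest attainable
#'   p-value is `1/(n_null+1)`).
#' @return A list of class `trimmed_group_summary`: `mu_c`, `mu_n` (trimmed
#'   subgroup means), `trim_fraction`, `alternative`, `p_value`, `q_value`
#'   (`NA` until BH-adjusted by the caller), and `degenerate` (TRUE when the
#'   input is unusable or both trimmed subsets are one constant; p pinned
#'   at 1).
#' @examples
#' trimmed_group_test(rlnorm(50, 1), rlnorm(50), 0.3, "greater")
#' @export
trimmed_group_test <- function(cancer_values, normal_values,
                               trim_fraction = 0.3,
                               alternative = c("greater", "less"),
                               n_null = 200000L) {
  alternative <- match.arg(alternative)
  if (!is.numeric(trim_fraction) || trim_fraction <= 0 || trim_fraction > 1) {
    stopf("trim_fraction must lie in (0, 1], got %s", format(trim_fraction))
  }
  cancer_values <- cancer_values[is.finite(cancer_values)]
  normal_values <- normal_values[is.finite(normal_values)]
  need <- ceiling(1 / trim_fraction)
  res <- list(mu_c = NA_real_, mu_n = NA_real_,
              trim_fraction = trim_fraction, alternative = alternative,
              p_value = 1, q_value = NA_real_, degenerate = TRUE)
  class(res) <- "trimmed_group_summary"
  if (length(cancer_values) < need || length(normal_values) < need) {
    return(res)
  }
  k_c <- max(1L, as.integer(floor(trim_fraction * length(cancer_values))))
  k_n <- max(1L, as.integer(floor(trim_fraction * length(normal_values))))
  # stable sort: boundary ties resolved by original order
  sub_c <- cancer_values[order(cancer_values)][seq_len(k_c)]
  sub_n <- normal_values[order(normal_values)][seq_len(k_n)]
  res$mu_c <- mean(sub_c)
  res$mu_n <- mean(sub_n)
  if (length(unique(c(sub_c, sub_n))) == 1L) {
    return(res)  # constant after trim: p = 1, flagged
  }
  r <- rank(c(sub_c, sub_n), ties.method = "average")
  u_obs <- sum(r[seq_len(k_c)]) - k_c * (k_c + 1) / 2
  tab <- trimmed_u_null(length(cancer_values), length(normal_values),
                        k_c, k_n, n_null)
  n_tab <- length(tab)
  if (alternative == "greater") {
    n_ge <- n_tab - findInterval(u_obs - 1e-9, tab)
    p <- (1 + n_ge) / (n_tab + 1)
  } else {
    n_le <- findInterval(u_obs + 1e-9, tab)
    p <- (1 + n_le) / (n_tab + 1)
  }
  res$p_value <- min(1, p)
  res$degenerate <- FALSE
  res
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment, order-preserved relative to the input.
#' `NA`/`NaN` entries propagate without affecting the adjustment of the
#' remaining entries.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Fisher's exact enrichment of a feature in a region set
#'
#' Builds the 2x2 table \[in-set hits, in-set misses; background hits,
#' background misses\] and returns the cross-product odds ratio (Haldane 0.5
#' correction applied iff some cell is zero) with the one-sided Fisher exact
#' p-value for enrichment.
#'
#' @param in_set_hits,in_set_total Hits and total in the set of interest.
#' @param bg_hits,bg_total Hits and total in the background set.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_enrichment <- function(in_set_hits, in_set_total, bg_hits, bg_total) {
  cnt <- c(in_set_hits, in_set_total, bg_hits, bg_total)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stopf("counts must be nonnegative integers")
  }
  if (in_set_total == 0) stopf("zero margin: in_set_total is 0")
  if (bg_total == 0) stopf("zero margin: bg_total is 0")
  if (in_set_hits > in_set_total) stopf("in_set_hits exceeds in_set_total")
  if (bg_hits > bg_total) stopf("bg_hits exceeds bg_total")
  a <- in_set_hits; b <- in_set_total - in_set_hits
  c_ <- bg_hits;    d <- bg_total - bg_hits
  tab <- matrix(c(a, c_, b, d), nrow = 2)
  if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p_value = p)
}

## Plug-in MI (bits) from a joint count table.
mi_from_joint <- function(joint) {
  n <- sum(joint)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  pj <- joint / n
  idx <- which(pj > 0, arr.ind = TRUE)
  pv <- pj[idx]
  sum(pv * log2(pv / (px[idx[, 1]] * py[idx[, 2]])))
}

#' Mutual information with equal-frequency binning
#'
#' Discretizes each vector into `n_bins` equal-frequency bins and computes
#' plug-in mutual information (base 2) over the joint histogram, plus the
#' normalized MI `mi / sqrt(H(X) * H(Y))`. Equal-frequency binning makes the
#' estimate invariant to monotone transforms of either margin, in the spirit
#' of rank-based association measures.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of bins; default `floor(sqrt(n/5))` clamped to
#'   \[2, 10\].
#' @return List with `mi` (bits, >= 0) and `nmi` (in \[0, 1\]; 0 whenever a
#'   marginal entropy is 0, e.g. a constant vector — warned).
#' @export
mutual_information <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3 * n_bins) {
    stopf("need length >= 3 * n_bins (= %d), got %d", 3 * n_bins, length(x))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("constant input vector: MI = 0")
    return(list(mi = 0, nmi = 0))
  }
  xb <- ef_bin(x, n_bins)
  yb <- ef_bin(y, n_bins)
  joint <- joint_counts(xb, yb, n_bins, n_bins)
  mi <- mi_from_joint(joint)
  hx <- entropy_bits(rowSums(joint))
  hy <- entropy_bits(colSums(joint))
  nmi <- if (hx <= 0 || hy <= 0) 0 else mi / sqrt(hx * hy)
  list(mi = max(0, mi), nmi = min(1, max(0, nmi)))
}

## Fast joint contingency table for integer codes in 1..bx, 1..by.
joint_counts <- function(xb, yb, bx, by) {
  matrix(tabulate((yb - 1L) * bx + xb, nbins = bx * by), nrow = bx)
}

#' Permutation Fisher-Z significance of mutual information
#'
#' Computes the observed normalized MI, then permutes `y` `n_perm` times
#' (seeded) recomputing it; every NMI is Fisher-Z transformed,
#' `z = atanh(nmi)` (clamped at 1 - 1e-9), and the p-value is
#' `2 * pnorm(-|Z - z'| / sigma_z)` where `z'`, `sigma_z` are the mean and SD
#' of the permuted transforms.
#'
#' @inheritParams mutual_information
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return Object of class `mi_result`: `mi`, `nmi`, `z_obs`, `z_perm_mean`,
#'   `z_perm_sd`, `p_value`, `n_perm`, `seed`, `degenerate` (TRUE when the
#'   permutation SD collapses to 0 and p is pinned as documented).
#' @export
mi_permutation_p <- function(x, y, n_perm = 1000L, seed = 1L,
                             n_bins = default_bins(length(x))) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  obs <- mutual_information(x, y, n_bins)
  n <- length(x)
  xb <- ef_bin(x, n_bins)
  yb <- ef_bin(y, n_bins)
  hx <- entropy_bits(tabulate(xb, n_bins))
  hy <- entropy_bits(tabulate(yb, n_bins))
  denom <- sqrt(hx * hy)
  clamp <- function(v) pmin(v, 1 - 1e-9)
  z_obs <- atanh(clamp(obs$nmi))
  z_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- yb[sample.int(n)]
      m <- mi_from_joint(joint_counts(xb, yp, n_bins, n_bins))
      nm <- if (denom <= 0) 0 else max(0, m) / denom
      atanh(clamp(min(1, nm)))
    }, numeric(1))
  })
  zm <- mean(z_perm)
  zs <- sd(z_perm)
  degenerate <- FALSE
  if (!is.finite(zs) || zs <= 0) {
    degenerate <- TRUE
    p <- if (z_obs <= zm) 1 else 1 / (n_perm + 1)
  } else {
    p <- 2 * pnorm(-abs(z_obs - zm) / zs)
  }
  structure(list(mi = obs$mi, nmi = obs$nmi, z_obs = z_obs,
                 z_perm_mean = zm, z_perm_sd = zs,
                 p_value = min(1, max(0, p)), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), degenerate = degenerate),
            class = "mi_result")
}

## Spearman rho and its asymptotic t p-value (two-sided), df = n - 2 - k.
spearman_t_p <- function(rho, n, k = 0L) {
  df <- n - 2 - k
  if (df <= 0 || abs(rho) >= 1) return(if (abs(rho) >= 1) 0 else 1)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * pt(-abs(tstat), df)
}

#' Partial Spearman correlation between an SE and a gene given TFs
#'
#' Computes the raw Spearman correlation `rho(SE, G)` with its asymptotic t
#' p-value, and the partial correlation given one or two conditioning
#' variables via the recursive first-order formula
#' `rho_xy.z = (rho_xy - rho_xz * rho_yz) / sqrt((1-rho_xz^2)(1-rho_yz^2))`,
#' applied once per conditioner. The partial p-value uses the same t
#' approximation with the degrees of freedom reduced by the conditioning
#' arity.
#'
#' @param se,g Numeric vectors (equal length >= 8).
#' @param conditioners A numeric vector or a list of 1-2 numeric vectors.
#' @return Object of class `partial_cor_result`: `rho_raw`, `p_raw`,
#'   `rho_partial`, `p_partial`, `conditioning_arity`, `degenerate` (TRUE
#'   when a conditioning correlation is +/-1 and the partial correlation is
#'   undefined — reported as 0).
#' @export
partial_spearman <- function(se, g, conditioners) {
  if (is.numeric(conditioners)) conditioners <- list(conditioners)
  k <- length(conditioners)
  if (k < 1 || k > 2) stopf("conditioners must hold 1 or 2 vectors")
  n <- length(se)
  if (length(g) != n || any(vapply(conditioners, length, 1L) != n)) {
    stopf("all vectors must share the same length")
  }
  if (n < 8) stopf("need at least 8 observations, got %d", n)
  for (z in conditioners) {
    if (length(unique(z)) == 1L) stopf("conditioner is constant")
  }
  vars <- c(list(se, g), conditioners)
  ranks <- lapply(vars, rank, ties.method = "average")
  cm <- cor(do.call(cbind, ranks))  # Pearson on ranks = Spearman
  rho_raw <- cm[1, 2]
  p_raw <- spearman_t_p(rho_raw, n, 0L)

  part1 <- function(rxy, rxz, ryz) {
    den <- sqrt((1 - rxz^2) * (1 - ryz^2))
    if (!is.finite(den) || den < 1e-12) return(NA_real_)
    (rxy - rxz * ryz) / den
  }
  degenerate <- FALSE
  if (k == 1L) {
    rp <- part1(cm[1, 2], cm[1, 3], cm[2, 3])
  } else {
    # second order: condition on z1 first, then on z2 within that
    r12.3 <- part1(cm[1, 2], cm[1, 3], cm[2, 3])
    r14.3 <- part1(cm[1, 4], cm[1, 3], cm[4, 3])
    r24.3 <- part1(cm[2, 4], cm[2, 3], cm[4, 3])
    rp <- if (anyNA(c(r12.3, r14.3, r24.3))) NA_real_ else
      part1(r12.3, r14.3, r24.3)
  }
  if (is.na(rp)) {
    degenerate <- TRUE
    rp <- 0
    pp <- 1
  } else {
    rp <- min(1, max(-1, rp))
    pp <- spearman_t_p(rp, n, k)
  }
  structure(list(rho_raw = rho_raw, p_raw = p_raw,
                 rho_partial = rp, p_partial = pp,
                 conditioning_arity = as.integer(k),
                 degenerate = degenerate),
            class = "partial_cor_result")
}

## Conditional mutual information I(X;Y|Z) in bits from integer codes;
## strata = distinct joint conditioner codes.
cmi_from_codes <- function(xb, yb, zb, bx, by) {
  n <- length(xb)
  cmi <- 0
  for (z in unique(zb)) {
    sel <- zb == z
    nz <- sum(sel)
    if (nz < 2) next
    joint <- joint_counts(xb[sel], yb[sel], bx, by)
    cmi <- cmi + (nz / n) * mi_from_joint(joint)
  }
  cmi
}

#' Permutation conditional-independence test
#'
#' Tests SE independent of G given the conditioners using conditional mutual
#' information on equal-frequency-discretized data. The null is generated by
#' permuting `g` within strata of the discretized conditioners;
#' `p = (1 + #{CMI_perm >= CMI_obs}) / (n_perm + 1)`.
#'
#' @inheritParams partial_spearman
#' @param n_perm Number of within-stratum permutations.
#' @param seed Integer seed.
#' @param n_bins Bins for SE and G. Conditioners are discretized into
#'   `max(2, min(10, floor((n/15)^(1/k))))` bins each (k = conditioning
#'   arity): fine enough that little conditioner signal leaks within a
#'   stratum, coarse enough that strata keep ~15 observations for the
#'   within-stratum permutations.
#' @return The permutation p-value in (0, 1\].
#' @export
conditional_independence_test <- function(se, g, conditioners,
                                          n_perm = 500L, seed = 1L,
                                          n_bins = default_bins(length(se))) {
  if (is.numeric(conditioners)) conditioners <- list(conditioners)
  n <- length(se)
  if (length(g) != n || any(vapply(conditioners, length, 1L) != n)) {
    stopf("all vectors must share the same length")
  }
  k <- length(conditioners)
  zbins <- max(2L, min(10L, as.integer(floor((n / 15)^(1 / k)))))
  xb <- ef_bin(se, n_bins)
  yb <- ef_bin(g, n_bins)
  zcodes <- lapply(conditioners, ef_bin, n_bins = zbins)
  zb <- Reduce(function(a, b) (a - 1L) * zbins + b, zcodes)
  sizes <- table(zb)
  small <- as.integer(names(sizes)[sizes < 2])
  if (length(small) > 0) {
    warnf("%d conditioning stratum/strata of size < 2 excluded", length(small))
  }
  keep <- !(zb %in% small)
  xb <- xb[keep]; yb <- yb[keep]; zb <- zb[keep]
  obs <- cmi_from_codes(xb, yb, zb, n_bins, n_bins)
  strata <- split(seq_along(zb), zb)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      yp <- yb
      for (idx in strata) {
        if (length(idx) > 1) yp[idx] <- yb[idx[sample.int(length(idx))]]
      }
      if (cmi_from_codes(xb, yp, zb, n_bins, n_bins) >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  (1 + exceed) / (n_perm + 1)
}
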