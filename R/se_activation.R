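## Stage 1 — activated super-enhancer calling from eRNA transcription, with
## CNV enrichment and differential methylation characterization.

#' Remove untranscribed eRNAs
#'
#' Drops rows whose RPKM is exactly zero in more than 70% of all samples
#' (strict inequality: a row zero in exactly 70% is retained). Missing values
#' are not counted as zeros.
#'
#' @param mat A [labeled_matrix()] of eRNA RPKM.
#' @param max_zero_frac Zero-fraction threshold (default 0.7).
#' @return The filtered `labeled_matrix`, with attribute `removed` listing
#'   the dropped feature ids.
#' @export
filter_erna <- function(mat, max_zero_frac = 0.7) {
  zero_frac <- rowMeans(mat$values == 0, na.rm = TRUE)
  drop <- zero_frac > max_zero_frac
  out <- labeled_matrix(mat$values[!drop, , drop = FALSE], mat$sample_labels)
  attr(out, "removed") <- rownames(mat$values)[drop]
  out
}

## Map features (by name) to the unique SE containing them; features inside
## zero or multiple SEs are dropped with a warning.
map_into_se <- function(feature_gr, se_regions) {
  hits <- quiet_overlaps(feature_gr, se_regions,
                                      type = "within")
  qh <- S4Vectors::queryHits(hits)
  tab <- tabulate(qh, nbins = length(feature_gr))
  multi <- sum(tab > 1)
  none <- sum(tab == 0)
  if (multi > 0 || none > 0) {
    warnf("%d feature(s) outside any SE and %d in multiple SEs dropped",
          none, multi)
  }
  keep <- which(tab == 1)
  sel <- qh %in% keep
  setNames(S4Vectors::mcols(se_regions)$name[S4Vectors::subjectHits(hits)[sel]],
           S4Vectors::mcols(feature_gr)$name[qh[sel]])
}

#' Call activated super-enhancers from eRNA transcription
#'
#' Per eRNA, tests whether the mean transcription of the 30% lowest cancer
#' samples exceeds that of the 30% lowest normal samples (one-tailed trimmed
#' Mann-Whitney); BH adjustment across all tested eRNAs. An SE is activated
#' iff at least one of its eRNAs is significantly up-regulated.
#'
#' @param erna [labeled_matrix()] of eRNA RPKM (after [filter_erna()]).
#' @param erna_loci `GRanges` of eRNA loci (names matching matrix rows).
#' @param se_regions `GRanges` of SE regions with `name`s.
#' @param trim Trim fraction (default 0.3).
#' @param q_thresh Up-regulation threshold on the BH q-value (default 0.05).
#' @return List with `calls` (data.frame: erna_id, se_id, mu_c, mu_n,
#'   p_value, q_value, up_regulated) and `activated_se_ids`.
#' @export
call_activated_ses <- function(erna, erna_loci, se_regions, trim = 0.3,
                               q_thresh = 0.05) {
  se_of <- map_into_se(erna_loci, se_regions)
  ids <- intersect(rownames(erna$values), names(se_of))
  if (length(ids) == 0) stopf("no eRNA maps into an SE region")
  cv <- class_values(erna, "cancer")
  nv <- class_values(erna, "normal")
  res <- lapply(ids, function(id) {
    trimmed_group_test(cv[id, ], nv[id, ], trim, "greater")
  })
  p <- vapply(res, `[[`, 0, "p_value")
  q <- bh_adjust(p)
  calls <- data.frame(
    erna_id = ids,
    se_id = unname(se_of[ids]),
    mu_c = vapply(res, `[[`, 0, "mu_c"),
    mu_n = vapply(res, `[[`, 0, "mu_n"),
    p_value = p,
    q_value = q,
    up_regulated = q < q_thresh,
    stringsAsFactors = FALSE
  )
  list(calls = calls,
       activated_se_ids = sort(unique(calls$se_id[calls$up_regulated])))
}

#' CNV amplification/deletion enrichment in SE regions
#'
#' Classifies segments by log2 ratio (amplification above `log2_cut`,
#' deletion below `-log2_cut`), counts SE vs length-matched random regions
#' overlapping at least one such segment (>= 1 bp, any sample), and tests
#' enrichment with a one-sided Fisher exact test.
#'
#' @param segments data.frame from [read_seg()].
#' @param se_regions,random_regions `GRanges` sets of equal size and matched
#'   length distribution (see [sample_random_regions()]).
#' @param log2_cut Segment classification cutoff (default 0.8).
#' @return List with `amplification` and `deletion`, each holding
#'   `odds_ratio`, `p_value`, `se_hits`, `bg_hits` and region totals;
#'   `odds_ratio` is NA with `degenerate = TRUE` when no segment falls in
#'   the class.
#' @export
cnv_enrichment <- function(segments, se_regions, random_regions,
                           log2_cut = 0.8) {
  seg_gr <- function(df) {
    if (nrow(df) == 0) return(NULL)
    granges_from_bed0(df$chrom, df$start, df$end)
  }
  one_class <- function(df) {
    n_se <- length(se_regions)
    n_bg <- length(random_regions)
    gr <- seg_gr(df)
    if (is.null(gr)) {
      return(list(odds_ratio = NA_real_, p_value = NA_real_,
                  se_hits = 0L, se_total = n_se, bg_hits = 0L,
                  bg_total = n_bg, degenerate = TRUE))
    }
    se_hits <- sum(quiet_overlaps_any(se_regions, gr))
    bg_hits <- sum(quiet_overlaps_any(random_regions, gr))
    fe <- fisher_enrichment(se_hits, n_se, bg_hits, n_bg)
    list(odds_ratio = fe$odds_ratio, p_value = fe$p_value,
         se_hits = se_hits, se_total = n_se, bg_hits = bg_hits,
         bg_total = n_bg, degenerate = FALSE)
  }
  list(
    amplification = one_class(segments[segments$log2ratio > log2_cut, ]),
    deletion = one_class(segments[segments$log2ratio < -log2_cut, ])
  )
}

#' Differential methylation of CpG sites inside SE regions
#'
#' For each CpG mapped into an SE, runs two one-sided trimmed tests on the
#' beta values (lowest 30% of each class): `less` for hypomethylation and
#' `greater` for hypermethylation, each BH-adjusted separately; direction is
#' assigned where q < `q_thresh`.
#'
#' @param beta [labeled_matrix()] of beta values in \[0, 1\].
#' @param cpg_loci `GRanges` of CpG positions (names matching matrix rows).
#' @param se_regions `GRanges` of SE regions.
#' @param trim Trim fraction (default 0.3).
#' @param q_thresh Direction-call threshold (default 0.05).
#' @return data.frame: cpg_id, se_id, mu_c, mu_n, p_hypo, q_hypo, p_hyper,
#'   q_hyper, direction in \{hypo, hyper, none\}.
#' @export
call_differential_methylation <- function(beta, cpg_loci, se_regions,
                                          trim = 0.3, q_thresh = 0.05) {
  if (any(beta$values < 0 | beta$values > 1, na.rm = TRUE)) {
    stopf("beta values must lie in [0, 1]")
  }
  se_of <- map_into_se(cpg_loci, se_regions)
  ids <- intersect(rownames(beta$values), names(se_of))
  cv <- class_values(beta, "cancer")
  nv <- class_values(beta, "normal")
  hypo <- lapply(ids, function(id)
    trimmed_group_test(cv[id, ], nv[id, ], trim, "less"))
  hyper <- lapply(ids, function(id)
    trimmed_group_test(cv[id, ], nv[id, ], trim, "greater"))
  p_hypo <- vapply(hypo, `[[`, 0, "p_value")
  p_hyper <- vapply(hyper, `[[`, 0, "p_value")
  q_hypo <- bh_adjust(p_hypo)
  q_hyper <- bh_adjust(p_hyper)
  direction <- rep("none", length(ids))
  direction[q_hypo < q_thresh] <- "hypo"
  is_hyper <- q_hyper < q_thresh
  stopifnot(!any(direction == "hypo" & is_hyper))
  direction[is_hyper] <- "hyper"
  data.frame(
    cpg_id = ids,
    se_id = unname(se_of[ids]),
    mu_c = vapply(hypo, `[[`, 0, "mu_c"),
    mu_n = vapply(hypo, `[[`, 0, "mu_n"),
    p_hypo = p_hypo, q_hypo = q_hypo,
    p_hyper = p_hyper, q_hyper = q_hyper,
    direction = direction,
    stringsAsFactors = FALSE
  )
}
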