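## Stage 2 — assign target genes to activated SEs: 3D-contact support,
## mutual information with permutation significance, and the enhanced score.

#' Filter genes by expression prevalence
#'
#' Keeps genes expressed (FPKM > 0) in at least `min_nonzero_frac` of all
#' samples.
#' @param mat A [labeled_matrix()] of FPKM.
#' @param min_nonzero_frac Minimum fraction of samples with FPKM > 0.
#' @return Filtered `labeled_matrix` with attribute `removed`.
#' @export
filter_genes <- function(mat, min_nonzero_frac = 0.7) {
  nz <- rowMeans(mat$values > 0, na.rm = TRUE)
  keep <- nz >= min_nonzero_frac
  out <- labeled_matrix(mat$values[keep, , drop = FALSE], mat$sample_labels)
  attr(out, "removed") <- rownames(mat$values)[!keep]
  out
}

#' Candidate SE-gene pairs supported by 3D contacts
#'
#' A pair (SE, gene) is a candidate iff some contact has one anchor
#' overlapping the SE and the other overlapping the gene's promoter window
#' (TSS +/- `promoter_halfwidth`), in either anchor orientation.
#'
#' @param se_regions `GRanges` of SEs (with `name`).
#' @param tss `GRanges` of gene TSS positions (with `name`, strand).
#' @param contacts List from [read_bedpe()].
#' @param promoter_halfwidth Promoter window half-width (default 3000 bp).
#' @return data.frame with `se_id`, `gene_id` (unique pairs).
#' @export
contact_supported_pairs <- function(se_regions, tss, contacts,
                                    promoter_halfwidth = 3000) {
  promoters <- promoter_windows(tss, promoter_halfwidth)
  pair_hits <- function(a, b) {
    ov_se <- quiet_overlaps(a, se_regions)
    ov_pr <- quiet_overlaps(b, promoters)
    se_by_contact <- split(S4Vectors::subjectHits(ov_se),
                           S4Vectors::queryHits(ov_se))
    pr_by_contact <- split(S4Vectors::subjectHits(ov_pr),
                           S4Vectors::queryHits(ov_pr))
    shared <- intersect(names(se_by_contact), names(pr_by_contact))
    if (length(shared) == 0) {
      return(data.frame(se = integer(), gene = integer()))
    }
    do.call(rbind, lapply(shared, function(k) {
      expand.grid(se = se_by_contact[[k]], gene = pr_by_contact[[k]])
    }))
  }
  hits <- rbind(pair_hits(contacts$anchor1, contacts$anchor2),
                pair_hits(contacts$anchor2, contacts$anchor1))
  if (nrow(hits) == 0) {
    return(data.frame(se_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(
    se_id = S4Vectors::mcols(se_regions)$name[hits$se],
    gene_id = S4Vectors::mcols(tss)$name[hits$gene],
    stringsAsFactors = FALSE
  ))
  out[order(out$se_id, out$gene_id), , drop = FALSE]
}

## eS = (nmi * log2FC) / (pnorm(P) * pnorm(q)); pnorm evaluated at the
## p-values themselves, so each significance factor is ~0.5 for small p.
es_value <- function(nmi, log2_fc, p_mi, q_up) {
  (nmi * log2_fc) / (pnorm(p_mi) * pnorm(q_up))
}

#' Enhanced score for one eRNA-gene pair
#'
#' Combines the permutation significance of the eRNA-gene mutual information
#' (computed over cancer samples), the BH-adjustable one-tailed expression
#' test of the gene (trimmed cancer vs normal, H0: mu_c <= mu_n) and the
#' trimmed-mean fold change into
#' `eS = (nmi * log2FC) / (pnorm(P) * pnorm(q))`.
#'
#' When scoring a single pair, `q_up` defaults to the raw p-value; the
#' table-level wrapper [score_candidate_pairs()] substitutes the BH-adjusted
#' value across the whole candidate family and recomputes eS.
#'
#' @param erna_values,gene_values Numeric vectors aligned on samples.
#' @param labels Character vector of `"cancer"`/`"normal"` per sample.
#' @param trim Trim fraction for the expression test and fold change.
#' @param n_perm,seed Permutation settings for the MI p-value.
#' @return List: `mi` (an `mi_result`), `p_mi`, `p_up`, `q_up`, `mu_c`,
#'   `mu_n`, `fc`, `log2_fc`, `es`, `fc_floored`.
#' @export
enhanced_score <- function(erna_values, gene_values, labels, trim = 0.3,
                           n_perm = 1000L, seed = 1L) {
  stopifnot(length(erna_values) == length(gene_values),
            length(labels) == length(erna_values))
  cancer <- labels == "cancer"
  mi <- mi_permutation_p(erna_values[cancer], gene_values[cancer],
                         n_perm = n_perm, seed = seed)
  tg <- trimmed_group_test(gene_values[cancer], gene_values[!cancer],
                           trim, "greater")
  fc_floored <- FALSE
  mu_n <- tg$mu_n
  if (!is.na(mu_n) && mu_n <= 0) {
    mu_n <- 1e-6
    fc_floored <- TRUE
  }
  fc <- tg$mu_c / mu_n
  log2_fc <- log2(fc)
  es <- es_value(mi$nmi, log2_fc, mi$p_value, tg$p_value)
  list(mi = mi, p_mi = mi$p_value, p_up = tg$p_value, q_up = tg$p_value,
       mu_c = tg$mu_c, mu_n = tg$mu_n, fc = fc, log2_fc = log2_fc,
       es = es, fc_floored = fc_floored)
}

#' Score every contact-supported (SE, eRNA, gene) combination
#'
#' Applies [enhanced_score()] to each eRNA of each candidate SE against the
#' candidate gene; the expression q-value is BH-adjusted across the distinct
#' genes tested and eS recomputed with it. Permutation seeds are derived per
#' (eRNA, gene) pair from `seed` by stable hashing, so results do not depend
#' on iteration order.
#'
#' @param pairs data.frame from [contact_supported_pairs()].
#' @param erna [labeled_matrix()] of eRNA RPKM (filtered).
#' @param genes [labeled_matrix()] of gene FPKM (filtered).
#' @param erna_se Named character vector mapping eRNA id -> SE id.
#' @param trim,n_perm,seed As in [enhanced_score()].
#' @return data.frame: se_id, erna_id, gene_id, mi, nmi, p_mi, p_up, q_up,
#'   mu_c, mu_n, fc, log2_fc, es.
#' @export
score_candidate_pairs <- function(pairs, erna, genes, erna_se, trim = 0.3,
                                  n_perm = 1000L, seed = 1L) {
  empty <- data.frame(se_id = character(), erna_id = character(),
                      gene_id = character(), mi = numeric(), nmi = numeric(),
                      p_mi = numeric(), p_up = numeric(), q_up = numeric(),
                      mu_c = numeric(), mu_n = numeric(), fc = numeric(),
                      log2_fc = numeric(), es = numeric(),
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene_id %in% rownames(genes$values), , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  labels <- unname(genes$sample_labels)
  cancer <- labels == "cancer"
  gene_cv <- class_values(genes, "cancer")
  gene_nv <- class_values(genes, "normal")

  ## one expression test per distinct gene, BH across that family
  genes_tested <- unique(pairs$gene_id)
  up <- lapply(genes_tested, function(g)
    trimmed_group_test(gene_cv[g, ], gene_nv[g, ], trim, "greater"))
  names(up) <- genes_tested
  p_up <- vapply(up, `[[`, 0, "p_value")
  q_up <- setNames(bh_adjust(p_up), genes_tested)

  erna_by_se <- split(names(erna_se), unname(erna_se))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    se <- pairs$se_id[i]
    g <- pairs$gene_id[i]
    ernas <- intersect(erna_by_se[[se]] %||% character(0),
                       rownames(erna$values))
    if (length(ernas) == 0) next
    tg <- up[[g]]
    mu_n <- if (!is.na(tg$mu_n) && tg$mu_n <= 0) 1e-6 else tg$mu_n
    fc <- tg$mu_c / mu_n
    l2fc <- log2(fc)
    gvec <- genes$values[g, cancer]
    for (e in ernas) {
      mi <- mi_permutation_p(erna$values[e, cancer], gvec, n_perm = n_perm,
                             seed = derive_seed(seed, paste(e, g)))
      rows[[length(rows) + 1L]] <- data.frame(
        se_id = se, erna_id = e, gene_id = g,
        mi = mi$mi, nmi = mi$nmi, p_mi = mi$p_value,
        p_up = tg$p_value, q_up = q_up[[g]],
        mu_c = tg$mu_c, mu_n = tg$mu_n, fc = fc, log2_fc = l2fc,
        es = es_value(mi$nmi, l2fc, mi$p_value, q_up[[g]]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Assign genes to SEs from the score table
#'
#' A gene is assigned to an SE iff at least one of its eRNA pairs passes the
#' MI significance gate, the expression significance gate, and the eS
#' threshold.
#'
#' @param scores data.frame from [score_candidate_pairs()].
#' @param threshold eS threshold (default 0.005).
#' @param p_gate MI permutation p gate (default 1e-4).
#' @param q_gate BH-adjusted expression q gate (default 1e-4).
#' @param tf_ids Optional character vector of TF gene ids to flag.
#' @return data.frame: se_id, gene_id, best_es, best_erna,
#'   supporting_ernas (comma-joined), is_tf.
#' @export
assign_genes <- function(scores, threshold = 0.005, p_gate = 1e-4,
                         q_gate = 1e-4, tf_ids = character(0)) {
  pass <- scores[scores$p_mi < p_gate & scores$q_up < q_gate &
                   scores$es > threshold, , drop = FALSE]
  if (nrow(pass) == 0) {
    return(data.frame(se_id = character(), gene_id = character(),
                      best_es = numeric(), best_erna = character(),
                      supporting_ernas = character(), is_tf = logical(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(pass$se_id, pass$gene_id, sep = "\r")
  out <- do.call(rbind, lapply(split(pass, key), function(d) {
    best <- which.max(d$es)
    data.frame(se_id = d$se_id[1], gene_id = d$gene_id[1],
               best_es = d$es[best], best_erna = d$erna_id[best],
               supporting_ernas = paste(sort(unique(d$erna_id)),
                                        collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$is_tf <- out$gene_id %in% tf_ids
  out[order(out$se_id, out$gene_id), , drop = FALSE]
}

#' Data-driven eS threshold
#'
#' `threshold = (mean nmi * mean log2FC) / pnorm(1e-4)^2`, reported alongside
#' the fixed default of 0.005.
#' @param scores data.frame from [score_candidate_pairs()] (>= 10 rows).
#' @return Single numeric threshold.
#' @export
compute_es_threshold <- function(scores) {
  if (nrow(scores) < 10) stopf("need >= 10 scored pairs")
  m_nmi <- mean(scores$nmi)
  if (m_nmi == 0) warnf("all-zero MI: threshold is 0")
  (m_nmi * mean(scores$log2_fc)) / pnorm(1e-4)^2
}
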