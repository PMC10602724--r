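## Stage 4 — partner TFs for CRC TFs and the CRC-TF/partner-TF pairs (CTPs)
## that statistically bridge SE-promoter loops.

expression_ratio_of <- function(expr, id, trim = 0.3) {
  cv <- class_values(expr, "cancer")[id, ]
  nv <- class_values(expr, "normal")[id, ]
  tg <- trimmed_group_test(cv, nv, trim, "greater")
  mean(cv > max(1, tg$mu_c))
}

#' Partner TF candidates for the CRC TFs
#'
#' Applies the four gates in order: (1) a physical interaction with a CRC TF
#' observed in at least two source interactome datasets; (2) expression
#' ratio above `ratio_min` in cancer samples (same rule as the master
#' score); (3) at least `motif_min` valid motif hits in the union of SE and
#' promoter regions of SE-assigned genes; (4) significant MI (permutation
#' p < `mi_p`) with at least one SE-assigned gene.
#'
#' @param crc_tfs CRC TF ids.
#' @param ppi data.frame from [read_ppi()].
#' @param expr [labeled_matrix()] of gene FPKM.
#' @param se_assigned data.frame from [assign_genes()].
#' @param pwms Named list of PWMs.
#' @param genome `DNAStringSet`.
#' @param se_regions `GRanges` of SEs.
#' @param tss `GRanges` of gene TSSs.
#' @param tf_universe TF ids eligible as partners.
#' @param ratio_min Expression ratio gate (default 0.3, strict >).
#' @param motif_min Motif-support gate (default 5).
#' @param motif_p Motif hit p-value gate (default 1e-4).
#' @param mi_p MI association gate (default 0.01).
#' @param promoter_halfwidth Promoter half-width (default 3000).
#' @param trim,n_perm,seed Statistical settings.
#' @return data.frame: crc_tf, partner_tf, ppi_support, expression_ratio,
#'   motif_support, mi_p (one row per retained pair).
#' @export
partner_candidates <- function(crc_tfs, ppi, expr, se_assigned, pwms, genome,
                               se_regions, tss, tf_universe,
                               ratio_min = 0.3, motif_min = 5,
                               motif_p = 1e-4, mi_p = 0.01,
                               promoter_halfwidth = 3000,
                               trim = 0.3, n_perm = 1000L, seed = 1L) {
  empty <- data.frame(crc_tf = character(), partner_tf = character(),
                      ppi_support = integer(), expression_ratio = numeric(),
                      motif_support = integer(), mi_p = numeric(),
                      stringsAsFactors = FALSE)
  if (length(crc_tfs) == 0 || nrow(ppi) == 0) return(empty)
  ## gate 1: PPI with a CRC TF in >= 2 datasets
  a_is_crc <- ppi$tf_a %in% crc_tfs
  b_is_crc <- ppi$tf_b %in% crc_tfs
  cand <- rbind(
    data.frame(crc_tf = ppi$tf_a[a_is_crc], partner_tf = ppi$tf_b[a_is_crc],
               dataset = ppi$dataset[a_is_crc], stringsAsFactors = FALSE),
    data.frame(crc_tf = ppi$tf_b[b_is_crc], partner_tf = ppi$tf_a[b_is_crc],
               dataset = ppi$dataset[b_is_crc], stringsAsFactors = FALSE)
  )
  cand <- cand[cand$partner_tf %in% setdiff(tf_universe, crc_tfs), ,
               drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  key <- paste(cand$crc_tf, cand$partner_tf, sep = "\r")
  support <- vapply(split(cand$dataset, key),
                    function(d) length(unique(d)), 1L)
  pairs <- unique(cand[, c("crc_tf", "partner_tf")])
  pairs$ppi_support <- support[paste(pairs$crc_tf, pairs$partner_tf,
                                     sep = "\r")]
  pairs <- pairs[pairs$ppi_support >= 2, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)

  in_expr <- pairs$partner_tf %in% rownames(expr$values)
  if (any(!in_expr)) {
    warnf("partner TF(s) absent from expression matrix dropped: %s",
          paste(unique(pairs$partner_tf[!in_expr]), collapse = ", "))
    pairs <- pairs[in_expr, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(empty)

  ## gate 2: expression ratio
  partners <- unique(pairs$partner_tf)
  ratio <- vapply(setNames(partners, partners), function(tf)
    expression_ratio_of(expr, tf, trim), 0)
  pairs$expression_ratio <- ratio[pairs$partner_tf]
  pairs <- pairs[pairs$expression_ratio > ratio_min, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)

  ## gate 3: motif support in SE/promoter regions of SE-assigned genes
  partners <- unique(pairs$partner_tf)
  partners <- partners[partners %in% names(pwms)]
  pairs <- pairs[pairs$partner_tf %in% partners, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  se_ids <- unique(se_assigned$se_id)
  regions <- se_regions[S4Vectors::mcols(se_regions)$name %in% se_ids]
  prom <- promoter_windows(
    tss[S4Vectors::mcols(tss)$name %in% unique(se_assigned$gene_id)],
    promoter_halfwidth,
    setNames(Biostrings::width(genome), names(genome)))
  hits <- rbind(scan_regions(genome, regions, pwms[partners], motif_p),
                scan_regions(genome, prom, pwms[partners], motif_p))
  msup <- vapply(setNames(partners, partners), function(tf)
    sum(hits$pwm_id == tf), 1L)
  pairs$motif_support <- msup[pairs$partner_tf]
  pairs <- pairs[pairs$motif_support >= motif_min, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)

  ## gate 4: MI with >= 1 SE-assigned gene (cancer samples)
  cancer <- unname(expr$sample_labels) == "cancer"
  assigned_genes <- sort(intersect(unique(se_assigned$gene_id),
                                   rownames(expr$values)))
  partners <- unique(pairs$partner_tf)
  best_p <- vapply(setNames(partners, partners), function(tf) {
    best <- 1
    for (g in setdiff(assigned_genes, tf)) {
      p <- mi_permutation_p(expr$values[tf, cancer],
                            expr$values[g, cancer], n_perm = n_perm,
                            seed = derive_seed(seed, paste(tf, g)))$p_value
      best <- min(best, p)
      if (best < mi_p) break
    }
    best
  }, 0)
  pairs$mi_p <- best_p[pairs$partner_tf]
  pairs <- pairs[pairs$mi_p < mi_p, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs[order(pairs$crc_tf, pairs$partner_tf),
        c("crc_tf", "partner_tf", "ppi_support", "expression_ratio",
          "motif_support", "mi_p"), drop = FALSE]
}

#' Bridge test for one (eRNA, gene, TF-pair) combination
#'
#' Computes the Spearman correlation between eRNA transcription and gene
#' expression (`rho(SE,G)`, p-value Pr) and the second-order partial
#' correlation conditioning jointly on both TFs (`rho(SE,G|TFa,TFb)`,
#' p-value Pp). The pair is flagged as a CTP bridging the loop iff
#' `Pr < alpha_raw` and `Pp > alpha_partial`. First-order per-TF partial
#' correlations are reported for transparency.
#'
#' @param erna_values,gene_values,tf_a_values,tf_b_values Numeric vectors
#'   aligned on cancer samples.
#' @param alpha_raw,alpha_partial Decision thresholds (default 0.05 each).
#' @return List: `pc` (a `partial_cor_result`), `is_ctp`, `rho_partial_a`,
#'   `rho_partial_b` (first-order values), `degenerate`.
#' @export
bridge_test <- function(erna_values, gene_values, tf_a_values, tf_b_values,
                        alpha_raw = 0.05, alpha_partial = 0.05) {
  pc <- partial_spearman(erna_values, gene_values,
                         list(tf_a_values, tf_b_values))
  pa <- partial_spearman(erna_values, gene_values, list(tf_a_values))
  pb <- partial_spearman(erna_values, gene_values, list(tf_b_values))
  is_ctp <- !pc$degenerate && pc$p_raw < alpha_raw &&
    pc$p_partial > alpha_partial
  list(pc = pc, is_ctp = is_ctp,
       rho_partial_a = pa$rho_partial, rho_partial_b = pb$rho_partial,
       degenerate = pc$degenerate)
}

#' Bridge-test all candidate pairs against assigned SE-gene links
#'
#' A candidate (CRC TF, partner TF) pair is tested against each assigned
#' link whose SE carries at least `motif_min` valid hits of the CRC TF's
#' motif (the TF must be able to bind the SE it is claimed to act on); the
#' link is represented by its best-supporting eRNA.
#'
#' @param cand data.frame from [partner_candidates()].
#' @param se_assigned data.frame from [assign_genes()].
#' @param erna,expr [labeled_matrix()] objects (eRNA RPKM, gene FPKM).
#' @param crc_se_hits data.frame of CRC motif hits per SE (`pwm_id`,
#'   `region` columns, as from [scan_regions()] over the SE set).
#' @param motif_min Minimum CRC-TF hits in the SE (default 5).
#' @param alpha_raw,alpha_partial Decision thresholds.
#' @return data.frame: se_id, erna_id, gene_id, crc_tf, partner_tf, rho_raw,
#'   p_raw, rho_partial, p_partial, rho_partial_a, rho_partial_b, is_ctp,
#'   degenerate.
#' @export
bridge_links <- function(cand, se_assigned, erna, expr, crc_se_hits,
                         motif_min = 5, alpha_raw = 0.05,
                         alpha_partial = 0.05) {
  empty <- data.frame(se_id = character(), erna_id = character(),
                      gene_id = character(), crc_tf = character(),
                      partner_tf = character(), rho_raw = numeric(),
                      p_raw = numeric(), rho_partial = numeric(),
                      p_partial = numeric(), rho_partial_a = numeric(),
                      rho_partial_b = numeric(), is_ctp = logical(),
                      degenerate = logical(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0 || nrow(se_assigned) == 0) return(empty)
  cancer <- unname(expr$sample_labels) == "cancer"
  ecancer <- unname(erna$sample_labels) == "cancer"
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand$crc_tf[i]; b <- cand$partner_tf[i]
    if (!(a %in% rownames(expr$values)) || !(b %in% rownames(expr$values))) {
      next
    }
    bound_ses <- unique(crc_se_hits$region[crc_se_hits$pwm_id == a])
    links <- se_assigned[se_assigned$se_id %in% bound_ses &
                           se_assigned$gene_id != a &
                           se_assigned$gene_id != b, , drop = FALSE]
    if (nrow(links) == 0) next
    ## require enough hits, not just any
    cnt <- table(crc_se_hits$region[crc_se_hits$pwm_id == a])
    links <- links[cnt[links$se_id] >= motif_min, , drop = FALSE]
    for (j in seq_len(nrow(links))) {
      e <- links$best_erna[j]; g <- links$gene_id[j]
      if (!(e %in% rownames(erna$values)) ||
          !(g %in% rownames(expr$values))) next
      bt <- bridge_test(erna$values[e, ecancer], expr$values[g, cancer],
                        expr$values[a, cancer], expr$values[b, cancer],
                        alpha_raw, alpha_partial)
      rows[[length(rows) + 1L]] <- data.frame(
        se_id = links$se_id[j], erna_id = e, gene_id = g,
        crc_tf = a, partner_tf = b,
        rho_raw = bt$pc$rho_raw, p_raw = bt$pc$p_raw,
        rho_partial = bt$pc$rho_partial, p_partial = bt$pc$p_partial,
        rho_partial_a = bt$rho_partial_a, rho_partial_b = bt$rho_partial_b,
        is_ctp = bt$is_ctp, degenerate = bt$degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Conditional-independence validation of flagged CTPs
#'
#' For every bridge result flagged as a CTP, tests SE independent of G given
#' the TF pair with the permutation CMI test; the dependence-on-the-pair
#' relationship is confirmed when conditional independence is not rejected
#' (p >= `alpha`).
#'
#' @param bridges data.frame from [bridge_links()].
#' @param erna,expr [labeled_matrix()] objects.
#' @param n_perm,seed Permutation settings (default 500).
#' @param alpha Rejection level (default 0.05).
#' @return List with `bridges` (columns `ci_p`, `ci_confirmed` added) and
#'   `confirmed_fraction` (NA when no CTP was flagged).
#' @export
ci_validate <- function(bridges, erna, expr, n_perm = 500L, seed = 1L,
                        alpha = 0.05) {
  if (nrow(bridges) == 0) {
    bridges$ci_p <- numeric(0)
    bridges$ci_confirmed <- logical(0)
    return(list(bridges = bridges, confirmed_fraction = NA_real_))
  }
  bridges$ci_p <- NA_real_
  bridges$ci_confirmed <- NA
  idx <- which(bridges$is_ctp)
  cancer <- unname(expr$sample_labels) == "cancer"
  ecancer <- unname(erna$sample_labels) == "cancer"
  for (i in idx) {
    bridges$ci_p[i] <- conditional_independence_test(
      erna$values[bridges$erna_id[i], ecancer],
      expr$values[bridges$gene_id[i], cancer],
      list(expr$values[bridges$crc_tf[i], cancer],
           expr$values[bridges$partner_tf[i], cancer]),
      n_perm = n_perm,
      seed = derive_seed(seed, paste(bridges$erna_id[i],
                                     bridges$gene_id[i],
                                     bridges$crc_tf[i],
                                     bridges$partner_tf[i]))
    )
    bridges$ci_confirmed[i] <- bridges$ci_p[i] >= alpha
  }
  frac <- if (length(idx) == 0) NA_real_
          else mean(bridges$ci_confirmed[idx])
  list(bridges = bridges, confirmed_fraction = frac)
}

#' Summarize CTPs across bridged links
#'
#' @param bridges data.frame from [bridge_links()].
#' @return List: `pairs` (distinct CTPs with their bridged-link counts),
#'   `per_gene` (distinct CTP count per regulated gene), `mean_ctps_per_gene`
#'   (NA when no gene is CTP-regulated).
#' @export
summarize_ctps <- function(bridges) {
  ctp <- bridges[bridges$is_ctp, , drop = FALSE]
  if (nrow(ctp) == 0) {
    return(list(pairs = data.frame(crc_tf = character(),
                                   partner_tf = character(),
                                   n_links = integer()),
                per_gene = data.frame(gene_id = character(),
                                      n_ctps = integer()),
                mean_ctps_per_gene = NA_real_))
  }
  key <- paste(ctp$crc_tf, ctp$partner_tf, sep = "\r")
  pairs <- do.call(rbind, lapply(split(ctp, key), function(d) {
    data.frame(crc_tf = d$crc_tf[1], partner_tf = d$partner_tf[1],
               n_links = nrow(unique(d[, c("se_id", "gene_id")])),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  per_gene <- do.call(rbind, lapply(split(ctp, ctp$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1],
               n_ctps = nrow(unique(d[, c("crc_tf", "partner_tf")])),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(pairs = pairs[order(pairs$crc_tf, pairs$partner_tf), , drop = FALSE],
       per_gene = per_gene,
       mean_ctps_per_gene = mean(per_gene$n_ctps))
}
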