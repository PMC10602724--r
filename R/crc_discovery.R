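## Stage 3 — master TF ranking, autoregulatory circuitry detection by motif
## scanning, and dissection of downstream perturbed genes.

#' Master score ranking of SE-assigned TFs
#'
#' Per TF: trimmed cancer/normal means, `lambda = mu_c * log2FC`, the
#' expression ratio (fraction of cancer samples with expression above
#' `max(1 FPKM, mu_c)`), and `MS = lambda * expression_ratio`. Master TFs
#' are the top `ceiling(top_frac * n)` by MS (ties broken by lambda, then
#' id), so the top-15% rule always selects at least one TF.
#'
#' @param expr [labeled_matrix()] of gene FPKM containing the TF rows.
#' @param tf_ids TF gene ids (drawn from the SE-assigned genes).
#' @param trim Trim fraction (default 0.3).
#' @param top_frac Master cutoff as a fraction of the TF count (default
#'   0.15).
#' @return List with `scores` (data.frame: tf_id, mu_c, mu_n, log2_fc,
#'   lambda, expression_ratio, ms, rank, is_master, fc_floored) and
#'   `master_tf_ids`.
#' @export
master_score <- function(expr, tf_ids, trim = 0.3, top_frac = 0.15) {
  tf_ids <- intersect(tf_ids, rownames(expr$values))
  if (length(tf_ids) == 0) stopf("no TF id resolves in the expression matrix")
  cv <- class_values(expr, "cancer")
  nv <- class_values(expr, "normal")
  rows <- lapply(tf_ids, function(tf) {
    tg <- trimmed_group_test(cv[tf, ], nv[tf, ], trim, "greater")
    fc_floored <- FALSE
    mu_n <- tg$mu_n
    if (!is.na(mu_n) && mu_n <= 0) {
      mu_n <- 1e-6
      fc_floored <- TRUE
    }
    log2_fc <- log2(tg$mu_c / mu_n)
    lambda <- tg$mu_c * log2_fc
    thresh <- max(1, tg$mu_c)
    ratio <- mean(cv[tf, ] > thresh)
    data.frame(tf_id = tf, mu_c = tg$mu_c, mu_n = tg$mu_n,
               log2_fc = log2_fc, lambda = lambda,
               expression_ratio = ratio, ms = lambda * ratio,
               fc_floored = fc_floored, stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  ord <- order(-sc$ms, -sc$lambda, sc$tf_id)
  sc <- sc[ord, , drop = FALSE]
  rownames(sc) <- NULL
  sc$rank <- seq_len(nrow(sc))
  n_master <- min(nrow(sc), as.integer(ceiling(top_frac * nrow(sc))))
  sc$is_master <- sc$rank <= n_master
  list(scores = sc, master_tf_ids = sc$tf_id[sc$is_master])
}

#' Detect the core transcriptional regulatory circuitry
#'
#' A master TF joins the CRC iff its motif has at least `min_occurrences`
#' valid hits (exact p < `p_thresh`) within the union of its own SE
#' sequences; directed cross-edges connect TFs with sufficient hits in
#' another CRC TF's SEs. The returned graph is restricted to self-looped
#' nodes (the autoregulatory requirement).
#'
#' @param master_tfs Character vector of master TF ids.
#' @param se_gene_links data.frame from [assign_genes()] (maps TFs to their
#'   own SEs).
#' @param pwms Named list of `pwm` objects (names = TF ids).
#' @param genome `DNAStringSet`.
#' @param se_regions `GRanges` of SE regions.
#' @param min_occurrences Minimum valid hit count (default 5).
#' @param p_thresh Motif hit p-value gate (default 1e-4).
#' @return List of class `circuitry_graph`: `nodes` (CRC TF ids), `edges`
#'   (data.frame from, to — includes self-loops), `hit_counts` (data.frame
#'   tf_id, se_owner, n_hits), `hits` (full motif hit table).
#' @export
detect_crc <- function(master_tfs, se_gene_links, pwms, genome, se_regions,
                       min_occurrences = 5, p_thresh = 1e-4) {
  have_pwm <- master_tfs %in% names(pwms)
  if (any(!have_pwm)) {
    warnf("master TF(s) without PWM excluded: %s",
          paste(master_tfs[!have_pwm], collapse = ", "))
  }
  tfs <- master_tfs[have_pwm]
  own_ses <- lapply(setNames(tfs, tfs), function(tf) {
    unique(se_gene_links$se_id[se_gene_links$gene_id == tf])
  })
  tfs <- tfs[lengths(own_ses) > 0]
  empty_graph <- structure(list(nodes = character(),
                                edges = data.frame(from = character(),
                                                   to = character()),
                                hit_counts = data.frame(),
                                hits = data.frame()),
                           class = "circuitry_graph")
  if (length(tfs) == 0) return(empty_graph)
  all_ses <- unique(unlist(own_ses[tfs]))
  regions <- se_regions[S4Vectors::mcols(se_regions)$name %in% all_ses]
  hits <- scan_regions(genome, regions, pwms[tfs], p_thresh)
  count_in <- function(tf, ses) {
    if (nrow(hits) == 0) return(0L)
    sum(hits$pwm_id == tf & hits$region %in% ses)
  }
  ## membership: >= min_occurrences hits of a TF's own motif in its own SEs
  in_crc <- vapply(tfs, function(tf)
    count_in(tf, own_ses[[tf]]) >= min_occurrences, TRUE)
  nodes <- sort(tfs[in_crc])
  if (length(nodes) == 0) return(empty_graph)
  edges <- list()
  counts <- list()
  for (a in nodes) {
    for (b in nodes) {
      n_hits <- count_in(a, own_ses[[b]])
      counts[[length(counts) + 1L]] <- data.frame(
        tf_id = a, se_owner = b, n_hits = n_hits, stringsAsFactors = FALSE)
      if (n_hits >= min_occurrences) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = a, to = b, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = do.call(rbind, edges),
                 hit_counts = do.call(rbind, counts),
                 hits = hits),
            class = "circuitry_graph")
}

#' @export
print.circuitry_graph <- function(x, ...) {
  cat(sprintf("circuitry_graph: %d CRC TF(s), %d edge(s) incl. self-loops\n",
              length(x$nodes), if (is.null(x$edges)) 0 else nrow(x$edges)))
  invisible(x)
}

#' Downstream genes perturbed by the CRC
#'
#' Differentially expressed genes (two-sided Mann-Whitney across all
#' samples, BH q < `de_q`) are candidate targets of a CRC TF when the TF's
#' motif has at least `motif_min` valid hits in the gene's linked SE(s)
#' and/or promoter; candidates are confirmed when the BH-adjusted (within
#' TF) MI permutation p-value between TF and gene expression is below
#' `mi_q`. Binding class records where the motif support came from.
#'
#' @param crc_tfs CRC TF ids.
#' @param expr [labeled_matrix()] of gene FPKM (expression-filtered
#'   universe).
#' @param se_gene_links data.frame from [assign_genes()].
#' @param se_regions `GRanges` of SEs.
#' @param tss `GRanges` of gene TSSs.
#' @param genome `DNAStringSet`.
#' @param pwms Named list of PWMs.
#' @param de_q DE gene q-value gate (default 0.01).
#' @param mi_q Confirmation gate on the BH-adjusted MI p (default 0.01).
#' @param motif_min Minimum motif hits (default 5).
#' @param motif_p Motif hit p-value gate (default 1e-4).
#' @param promoter_halfwidth Promoter half-width (default 3000).
#' @param n_perm,seed Permutation settings.
#' @return data.frame: tf_id, gene_id, binding (SE/promoter/both),
#'   de_q_value, mi_p, mi_q_adj, confirmed, direction (up/down in cancer).
#' @export
downstream_genes <- function(crc_tfs, expr, se_gene_links, se_regions, tss,
                             genome, pwms, de_q = 0.01, mi_q = 0.01,
                             motif_min = 5, motif_p = 1e-4,
                             promoter_halfwidth = 3000,
                             n_perm = 1000L, seed = 1L) {
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      binding = character(), de_q_value = numeric(),
                      mi_p = numeric(), mi_q_adj = numeric(),
                      confirmed = logical(), direction = character(),
                      stringsAsFactors = FALSE)
  if (length(crc_tfs) == 0) return(empty)
  cv <- class_values(expr, "cancer")
  nv <- class_values(expr, "normal")
  genes <- rownames(expr$values)
  de_p <- vapply(genes, function(g) {
    x <- cv[g, ]; y <- nv[g, ]
    if (length(unique(c(x, y))) == 1L) return(1)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }, 0)
  de_qv <- setNames(bh_adjust(de_p), genes)
  de_genes <- genes[de_qv < de_q]
  if (length(de_genes) == 0) return(empty)
  direction <- ifelse(rowMeans(cv[de_genes, , drop = FALSE]) >
                        rowMeans(nv[de_genes, , drop = FALSE]), "up", "down")
  names(direction) <- de_genes

  ## motif support in linked SEs of DE genes
  links <- se_gene_links[se_gene_links$gene_id %in% de_genes, , drop = FALSE]
  se_ids <- unique(links$se_id)
  se_hits <- if (length(se_ids) > 0) {
    regions <- se_regions[S4Vectors::mcols(se_regions)$name %in% se_ids]
    scan_regions(genome, regions, pwms[intersect(crc_tfs, names(pwms))],
                 motif_p)
  } else data.frame(pwm_id = character(), region = character())
  ## motif support in promoters of DE genes
  prom <- promoter_windows(tss[S4Vectors::mcols(tss)$name %in% de_genes],
                           promoter_halfwidth,
                           setNames(Biostrings::width(genome), names(genome)))
  pr_hits <- scan_regions(genome, prom, pwms[intersect(crc_tfs, names(pwms))],
                          motif_p)

  cancer <- unname(expr$sample_labels) == "cancer"
  rows <- list()
  for (tf in crc_tfs) {
    th_se <- se_hits[se_hits$pwm_id == tf, , drop = FALSE]
    th_pr <- pr_hits[pr_hits$pwm_id == tf, , drop = FALSE]
    se_cnt <- table(th_se$region)
    pr_cnt <- table(th_pr$region)
    cand <- character(0); bind <- character(0)
    for (g in de_genes) {
      n_se <- sum(se_cnt[links$se_id[links$gene_id == g]], na.rm = TRUE)
      n_pr <- if (g %in% names(pr_cnt)) pr_cnt[[g]] else 0
      via_se <- n_se >= motif_min
      via_pr <- n_pr >= motif_min
      if (via_se || via_pr) {
        cand <- c(cand, g)
        bind <- c(bind, if (via_se && via_pr) "both"
                  else if (via_se) "SE" else "promoter")
      }
    }
    if (length(cand) == 0) next
    mi_p_raw <- vapply(cand, function(g) {
      mi_permutation_p(expr$values[tf, cancer], expr$values[g, cancer],
                       n_perm = n_perm,
                       seed = derive_seed(seed, paste(tf, g)))$p_value
    }, 0)
    mi_adj <- bh_adjust(mi_p_raw)
    rows[[length(rows) + 1L]] <- data.frame(
      tf_id = tf, gene_id = cand, binding = bind,
      de_q_value = unname(de_qv[cand]), mi_p = mi_p_raw, mi_q_adj = mi_adj,
      confirmed = mi_adj < mi_q, direction = unname(direction[cand]),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, c(rows, make.row.names = FALSE))
}
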