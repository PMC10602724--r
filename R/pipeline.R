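## End-to-end orchestration: configuration, the four-stage run, and
## evaluation against planted ground truth.

#' Pipeline configuration
#'
#' Thresholds default to the published analysis values: 30% trimming, q < 0.05
#' activation, |log2| > 0.8 CNV segments, TSS +/- 3 kb promoters, eS > 0.005
#' with MI p < 1e-4 and expression q < 1e-4 gates, top-15% master TFs, >= 5
#' motif occurrences at p < 1e-4, DE q < 0.01, partner expression ratio >
#' 0.3, and Pr < 0.05 / Pp > 0.05 for CTP bridging.
#'
#' @param trim_fraction,q_activation,log2_cnv,promoter_halfwidth Stage-1/2
#'   thresholds.
#' @param es_threshold,mi_gate,expr_q_gate Stage-2 assignment gates.
#' @param de_q,motif_p,motif_min,top_tf_frac Stage-3 thresholds.
#' @param ratio_min,partner_mi_p,alpha_raw,alpha_partial Stage-4 thresholds.
#' @param n_perm,ci_n_perm Permutation counts (MI / CI tests).
#' @param seed Global seed; all stage randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_fraction = 0.3, q_activation = 0.05,
                            log2_cnv = 0.8, promoter_halfwidth = 3000,
                            es_threshold = 0.005, mi_gate = 1e-4,
                            expr_q_gate = 1e-4, de_q = 0.01,
                            motif_p = 1e-4, motif_min = 5,
                            top_tf_frac = 0.15, ratio_min = 0.3,
                            partner_mi_p = 0.01, alpha_raw = 0.05,
                            alpha_partial = 0.05, n_perm = 1000L,
                            ci_n_perm = 500L, seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Generate a synthetic cohort bundle (pipeline front-end)
#'
#' Thin wrapper over [generate_cohort()].
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @return See [generate_cohort()].
#' @export
simulate_cohort <- function(config, out_dir) generate_cohort(config, out_dir)

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  path
}

#' Run the four-stage CRC pipeline
#'
#' Executes SE activation calling, SE-gene assignment, CRC discovery and CTP
#' bridging on a file bundle, writing every intermediate table plus a
#' manifest to `out_dir`. Rerunning with the same inputs and config
#' reproduces all outputs bit-exactly.
#'
#' @param paths Named list of input paths (as produced by
#'   [generate_cohort()]): genome, se_regions, erna_loci, erna_rpkm,
#'   gene_tss, gene_fpkm, sample_labels, beta, cpg_loci, cnv_seg, contacts,
#'   pwms, tf_list, ppi.
#' @param out_dir Run directory (created).
#' @param config A [pipeline_config()].
#' @return List of class `secrc_run` with all stage tables, the activated SE
#'   set, the circuitry graph, CTP results and the manifest.
#' @export
run_pipeline <- function(paths, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("genome", "se_regions", "erna_loci", "erna_rpkm", "gene_tss",
                "gene_fpkm", "sample_labels", "beta", "cpg_loci", "cnv_seg",
                "contacts", "pwms", "tf_list", "ppi")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0) {
    stopf("missing input path(s): %s", paste(missing, collapse = ", "))
  }
  for (f in required) {
    if (!file.exists(paths[[f]])) stopf("input file not found: %s", paths[[f]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  stage <- "load_inputs"
  res <- tryCatch(
    run_pipeline_impl(paths, out_dir, config, logf,
                      function(s) stage <<- s),
    error = function(e) {
      logf("FAILED at stage %s: %s", stage, conditionMessage(e))
      stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
    }
  )
  res
}

run_pipeline_impl <- function(paths, out_dir, config, logf, set_stage) {
  pth <- function(f) file.path(out_dir, f)
  logf("secrc run, seed %d", config$seed)

  genome <- read_fasta(paths$genome)
  seqlens <- setNames(Biostrings::width(genome), names(genome))
  se_regions <- read_bed(paths$se_regions)
  erna_loci <- read_bed(paths$erna_loci)
  tss <- read_bed(paths$gene_tss)
  erna <- read_matrix(paths$erna_rpkm, paths$sample_labels)
  genes <- read_matrix(paths$gene_fpkm, paths$sample_labels)
  beta <- read_matrix(paths$beta, paths$sample_labels)
  cpg_loci <- read_bed(paths$cpg_loci)
  seg <- read_seg(paths$cnv_seg)
  contacts <- read_bedpe(paths$contacts)
  pwms <- read_jaspar(paths$pwms, background = genome_background(genome))
  tf_tab <- data.table::fread(paths$tf_list, sep = "\t", header = TRUE,
                              data.table = FALSE)
  tf_universe <- unique(as.character(tf_tab$gene_id))
  ppi <- read_ppi(paths$ppi)

  ## ---- stage 1: SE activation ---------------------------------------
  set_stage("se_activation")
  erna_f <- filter_erna(erna)
  logf("stage1: %d/%d eRNAs retained after sparsity filter",
       nrow(erna_f$values), nrow(erna$values))
  act <- call_activated_ses(erna_f, erna_loci, se_regions,
                            trim = config$trim_fraction,
                            q_thresh = config$q_activation)
  write_tsv(act$calls, pth("activation_calls.tsv"))
  act_regions <- se_regions[S4Vectors::mcols(se_regions)$name %in%
                              act$activated_se_ids]
  write_bed(act_regions, pth("activated_ses.bed"))
  logf("stage1: %d up-regulated eRNAs, %d activated SEs",
       sum(act$calls$up_regulated), length(act$activated_se_ids))

  cnv <- NULL
  if (length(act_regions) > 0) {
    rand_regions <- sample_random_regions(
      genome, length(act_regions), act_regions, exclude = se_regions,
      seed = derive_seed(config$seed, "random_regions"))
    cnv <- cnv_enrichment(seg, act_regions, rand_regions,
                          log2_cut = config$log2_cnv)
    jsonlite::write_json(cnv, pth("cnv_enrichment.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  meth <- if (length(act_regions) > 0) {
    call_differential_methylation(beta, cpg_loci, act_regions,
                                  trim = config$trim_fraction)
  } else {
    data.frame()
  }
  if (nrow(meth) > 0) write_tsv(meth, pth("methylation_calls.tsv"))

  ## ---- stage 2: SE-gene assignment ----------------------------------
  set_stage("se_gene_assignment")
  genes_f <- filter_genes(genes)
  logf("stage2: %d/%d genes pass expression filter",
       nrow(genes_f$values), nrow(genes$values))
  pairs <- contact_supported_pairs(act_regions, tss, contacts,
                                   config$promoter_halfwidth)
  erna_se <- map_into_se(erna_loci, se_regions)
  erna_se <- erna_se[names(erna_se) %in% rownames(erna_f$values)]
  scores <- score_candidate_pairs(pairs, erna_f, genes_f, erna_se,
                                  trim = config$trim_fraction,
                                  n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, "scores"))
  write_tsv(scores, pth("se_gene_scores.tsv"))
  assigned <- assign_genes(scores, threshold = config$es_threshold,
                           p_gate = config$mi_gate,
                           q_gate = config$expr_q_gate,
                           tf_ids = tf_universe)
  write_tsv(assigned, pth("se_assigned_genes.tsv"))
  es_alt <- if (nrow(scores) >= 10) compute_es_threshold(scores) else NA_real_
  logf("stage2: %d candidate pairs, %d assigned links (alt eS threshold %.4g)",
       nrow(pairs), nrow(assigned), es_alt)
  if (nrow(assigned) > 0) {
    link_se <- se_regions[match(assigned$se_id,
                                S4Vectors::mcols(se_regions)$name)]
    link_pr <- promoter_windows(tss[match(assigned$gene_id,
                                          S4Vectors::mcols(tss)$name)],
                                config$promoter_halfwidth, seqlens)
    write_bedpe(list(anchor1 = link_se, anchor2 = link_pr,
                     name = paste(assigned$se_id, assigned$gene_id,
                                  sep = "|")),
                pth("links.bedpe"))
  }

  ## ---- stage 3: CRC discovery ---------------------------------------
  set_stage("crc_discovery")
  tf_assigned <- sort(unique(assigned$gene_id[assigned$is_tf]))
  ms <- NULL
  crc <- structure(list(nodes = character(),
                        edges = data.frame(from = character(),
                                           to = character()),
                        hit_counts = data.frame(), hits = data.frame()),
                   class = "circuitry_graph")
  downstream <- data.frame()
  crc_hits_all <- data.frame(pwm_id = character(), region = character())
  if (length(tf_assigned) > 0) {
    ms <- master_score(genes_f, tf_assigned, trim = config$trim_fraction,
                       top_frac = config$top_tf_frac)
    write_tsv(ms$scores, pth("master_scores.tsv"))
    logf("stage3: %d SE-assigned TFs, %d master TFs",
         length(tf_assigned), length(ms$master_tf_ids))
    crc <- detect_crc(ms$master_tf_ids, assigned, pwms, genome, se_regions,
                      min_occurrences = config$motif_min,
                      p_thresh = config$motif_p)
    if (nrow(crc$hits) > 0) {
      hit_bed <- granges_from_bed0(crc$hits$chrom, crc$hits$start,
                                   crc$hits$end, crc$hits$pwm_id,
                                   crc$hits$strand)
      S4Vectors::mcols(hit_bed)$score <- -log10(crc$hits$p_value)
      write_bed(hit_bed, pth("motif_hits.bed"))
    }
    jsonlite::write_json(
      list(nodes = crc$nodes,
           edges = if (is.null(crc$edges)) list() else crc$edges,
           self_loops = crc$nodes),
      pth("crc_graph.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logf("stage3: %d CRC TFs", length(crc$nodes))
    if (length(crc$nodes) > 0) {
      downstream <- downstream_genes(
        crc$nodes, genes_f, assigned, se_regions, tss, genome, pwms,
        de_q = config$de_q, mi_q = config$de_q,
        motif_min = config$motif_min, motif_p = config$motif_p,
        promoter_halfwidth = config$promoter_halfwidth,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, "downstream"))
      write_tsv(downstream, pth("downstream_targets.tsv"))
      ## CRC motif hits across all activated SEs (bridging support)
      crc_hits_all <- scan_regions(genome, act_regions, pwms[crc$nodes],
                                   config$motif_p)
    }
  }

  ## ---- stage 4: CTP bridging ----------------------------------------
  set_stage("ctp_bridging")
  cand <- partner_candidates(
    crc$nodes, ppi, genes_f, assigned, pwms, genome, se_regions, tss,
    tf_universe, ratio_min = config$ratio_min,
    motif_min = config$motif_min, motif_p = config$motif_p,
    mi_p = config$partner_mi_p,
    promoter_halfwidth = config$promoter_halfwidth,
    trim = config$trim_fraction, n_perm = config$n_perm,
    seed = derive_seed(config$seed, "partners"))
  write_tsv(cand, pth("partner_candidates.tsv"))
  bridges <- bridge_links(cand, assigned, erna_f, genes_f, crc_hits_all,
                          motif_min = config$motif_min,
                          alpha_raw = config$alpha_raw,
                          alpha_partial = config$alpha_partial)
  civ <- ci_validate(bridges, erna_f, genes_f, n_perm = config$ci_n_perm,
                     seed = derive_seed(config$seed, "ci"))
  bridges <- civ$bridges
  write_tsv(bridges, pth("ctp_bridges.tsv"))
  ctp_sum <- summarize_ctps(bridges)
  jsonlite::write_json(
    list(n_ctps = nrow(ctp_sum$pairs),
         mean_ctps_per_gene = ctp_sum$mean_ctps_per_gene,
         ci_confirmed_fraction = civ$confirmed_fraction,
         pairs = ctp_sum$pairs, per_gene = ctp_sum$per_gene),
    pth("ctp_summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA,
    na = "null")
  logf("stage4: %d partner candidates, %d bridge tests, %d CTP pairs",
       nrow(cand), nrow(bridges), nrow(ctp_sum$pairs))

  set_stage("manifest")
  manifest <- list(
    pipeline = "secrc",
    seed = config$seed,
    config = unclass(config),
    counts = list(
      ernas_tested = nrow(act$calls),
      up_regulated_ernas = sum(act$calls$up_regulated),
      activated_ses = length(act$activated_se_ids),
      candidate_pairs = nrow(pairs),
      scored_rows = nrow(scores),
      assigned_genes = length(unique(assigned$gene_id)),
      assigned_links = nrow(assigned),
      assigned_tfs = length(tf_assigned),
      master_tfs = if (is.null(ms)) 0L else length(ms$master_tf_ids),
      crc_tfs = length(crc$nodes),
      downstream_confirmed = if (nrow(downstream) > 0)
        sum(downstream$confirmed) else 0L,
      partner_candidates = nrow(cand),
      bridge_tests = nrow(bridges),
      ctp_pairs = nrow(summarize_ctps(bridges)$pairs)
    )
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  structure(list(
    out_dir = out_dir, config = config,
    activation = act, cnv = cnv, methylation = meth,
    candidate_pairs = pairs, scores = scores, assigned = assigned,
    master = ms, crc = crc, downstream = downstream,
    partner_candidates = cand, bridges = bridges,
    ctp_summary = ctp_sum, ci_confirmed_fraction = civ$confirmed_fraction,
    manifest = manifest
  ), class = "secrc_run")
}

## Rank-based AUROC (Mann-Whitney statistic).
auroc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate a pipeline run against planted ground truth
#'
#' @param run `secrc_run` object from [run_pipeline()].
#' @param truth Ground-truth list from [generate_cohort()].
#' @param out_path Optional path for a metrics JSON.
#' @return List of metrics: activated-SE sensitivity/FDR, SE-gene link AUROC
#'   (by best eS over contact-supported candidates), CRC TF set equality and
#'   Jaccard, CTP sensitivity and control false-flag rate, CI-confirmed
#'   fraction, hypomethylation sensitivity, CNV amplification odds ratio.
#' @export
evaluate_run <- function(run, truth, out_path = NULL) {
  stopifnot(inherits(run, "secrc_run"))
  if (is.null(truth)) stopf("ground truth required")
  called <- run$activation$activated_se_ids
  t_act <- truth$activated_se_ids
  act_sens <- if (length(t_act) > 0) {
    length(intersect(called, t_act)) / length(t_act)
  } else NA_real_
  act_fdr <- if (length(called) > 0) {
    length(setdiff(called, t_act)) / length(called)
  } else NA_real_

  ## AUROC of best eS per candidate pair against true links
  link_auroc <- NA_real_
  if (nrow(run$scores) > 0) {
    key <- paste(run$scores$se_id, run$scores$gene_id, sep = "\r")
    best <- vapply(split(run$scores$es, key), max, 0)
    tkey <- paste(truth$se_gene_links$se_id, truth$se_gene_links$gene_id,
                  sep = "\r")
    link_auroc <- auroc(best, names(best) %in% tkey)
  }

  crc_equal <- setequal(run$crc$nodes, truth$crc_tf_ids)
  crc_jaccard <- if (length(union(run$crc$nodes, truth$crc_tf_ids)) == 0) {
    NA_real_
  } else {
    length(intersect(run$crc$nodes, truth$crc_tf_ids)) /
      length(union(run$crc$nodes, truth$crc_tf_ids))
  }

  ## CTP recovery: match planted triples on (gene, crc_tf, partner_tf)
  ctp_sens <- NA_real_; ctp_ffr <- NA_real_
  tt <- truth$ctp_triples
  if (nrow(tt) > 0 && nrow(run$bridges) > 0) {
    bkey <- paste(run$bridges$gene_id, run$bridges$crc_tf,
                  run$bridges$partner_tf, sep = "\r")
    flagged <- bkey[run$bridges$is_ctp]
    med <- paste(tt$gene_id[tt$mediated], tt$crc_tf[tt$mediated],
                 tt$partner_tf[tt$mediated], sep = "\r")
    ctl <- paste(tt$gene_id[!tt$mediated], tt$crc_tf[!tt$mediated],
                 tt$partner_tf[!tt$mediated], sep = "\r")
    if (length(med) > 0) ctp_sens <- mean(med %in% flagged)
    if (length(ctl) > 0) ctp_ffr <- mean(ctl %in% flagged)
  }

  hypo_sens <- NA_real_
  if (length(truth$hypo_cpg_ids) > 0 && nrow(run$methylation) > 0) {
    called_hypo <- run$methylation$cpg_id[run$methylation$direction == "hypo"]
    tested_hypo <- intersect(truth$hypo_cpg_ids, run$methylation$cpg_id)
    if (length(tested_hypo) > 0) {
      hypo_sens <- mean(tested_hypo %in% called_hypo)
    }
  }

  metrics <- list(
    activated_se_sensitivity = act_sens,
    activated_se_fdr = act_fdr,
    up_regulated_erna_count = sum(run$activation$calls$up_regulated),
    se_gene_link_auroc = link_auroc,
    crc_tf_set_equal = crc_equal,
    crc_tf_jaccard = crc_jaccard,
    ctp_sensitivity = ctp_sens,
    ctp_false_flag_rate = ctp_ffr,
    ci_confirmed_fraction = run$ci_confirmed_fraction,
    hypo_cpg_sensitivity = hypo_sens,
    cnv_amplification_or = if (is.null(run$cnv)) NA_real_
                           else run$cnv$amplification$odds_ratio,
    cnv_amplification_p = if (is.null(run$cnv)) NA_real_
                          else run$cnv$amplification$p_value
  )
  if (!is.null(out_path)) {
    jsonlite::write_json(metrics, out_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  metrics
}

#' @export
print.secrc_run <- function(x, ...) {
  cat("secrc pipeline run\n")
  cnt <- x$manifest$counts
  cat(sprintf("  activated SEs: %d (%d up-regulated eRNAs)\n",
              cnt$activated_ses, cnt$up_regulated_ernas))
  cat(sprintf("  assigned genes: %d (%d links)\n", cnt$assigned_genes,
              cnt$assigned_links))
  cat(sprintf("  master TFs: %d, CRC TFs: %d\n", cnt$master_tfs,
              cnt$crc_tfs))
  cat(sprintf("  partner candidates: %d, CTP pairs: %d\n",
              cnt$partner_candidates, cnt$ctp_pairs))
  invisible(x)
}
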