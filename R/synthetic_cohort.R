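## Synthetic multi-omics cohort generator with planted ground truth.
##
## Emulates the statistical structure the pipeline assumes: log-scale eRNA
## shifts in a planted activated-SE subset; SE -> gene expression dependence
## routed through per-sample enhancer activity; hypomethylated CpGs and
## amplified CNV segments inside activated SEs; TF consensus motifs embedded
## in SE/promoter sequence creating autoregulatory loops; and TF-pair-
## mediated SE -> gene correlations that vanish upon conditioning.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the reference benchmarking cohort: 50 cancer + 50 normal
#' samples, 200 SEs of which 20% are activated with a +1.5 log2 eRNA shift,
#' 1,000 genes of which 15% are SE-driven at rank-correlation scale 0.7,
#' 30 TFs with 5 planted CRC TFs, and 40 mediated CTP triples (an equal
#' number of unmediated controls is generated alongside).
#'
#' @param n_cancer,n_normal Sample counts per class.
#' @param n_se Number of super-enhancer regions.
#' @param frac_activated Fraction of SEs with planted activation.
#' @param activation_shift Log2-scale mean eRNA shift in cancer for activated
#'   SEs (also the planted expression shift of SE-driven genes).
#' @param n_genes Total genes.
#' @param frac_linked Fraction of genes truly SE-driven.
#' @param link_strength Correlation scale in \[0, 1) between enhancer
#'   activity and linked-gene expression.
#' @param n_tfs Number of TF genes (a subset of the genes).
#' @param n_crc_tfs Planted CRC TFs (must be <= number of activated SEs).
#' @param motif_length Consensus motif length in bp.
#' @param n_ctp_triples Planted mediated (SE, TF-pair, gene) triples.
#' @param noise_sd Log2-scale residual SD of expression.
#' @param seed Integer seed; the same seed reproduces the cohort bit-exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cancer = 50, n_normal = 50,
                          n_se = 200, frac_activated = 0.2,
                          activation_shift = 1.5,
                          n_genes = 1000, frac_linked = 0.15,
                          link_strength = 0.7,
                          n_tfs = 30, n_crc_tfs = 5,
                          motif_length = 10, n_ctp_triples = 40,
                          noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_cancer = n_cancer, n_normal = n_normal, n_se = n_se,
              frac_activated = frac_activated,
              activation_shift = activation_shift,
              n_genes = n_genes, frac_linked = frac_linked,
              link_strength = link_strength, n_tfs = n_tfs,
              n_crc_tfs = n_crc_tfs, motif_length = motif_length,
              n_ctp_triples = n_ctp_triples, noise_sd = noise_sd,
              seed = as.integer(seed))
  counts <- c("n_cancer", "n_normal", "n_se", "n_genes", "n_tfs",
              "motif_length")
  for (f in counts) if (cfg[[f]] <= 0) stopf("%s must be positive", f)
  for (f in c("frac_activated", "frac_linked")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) stopf("%s must lie in [0, 1)", f)
  }
  if (link_strength < 0 || link_strength >= 1) {
    stopf("link_strength must lie in [0, 1)")
  }
  class(cfg) <- "cohort_config"
  cfg
}

SE_SLOT <- 6000L      # chr1 layout: one SE per slot
GENE_SLOT <- 7000L    # chr2 layout: one TSS per slot
ZERO_FPKM <- 0.25     # expression below this is reported as 0

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

mutate_consensus <- function(consensus, n_mut) {
  chars <- strsplit(consensus, "")[[1]]
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

## Embed copies of `word`s at random non-overlapping offsets inside
## chars[at:(at+len-1)] of a chromosome character vector; returns it.
plant_words <- function(chars, region_start1, region_len, words) {
  L <- nchar(words[1])
  if (L > region_len) stopf("motif (%d bp) longer than region (%d bp)",
                            L, region_len)
  n_slots <- floor(region_len / (L + 2))
  if (length(words) > n_slots) {
    stopf("cannot place %d motif copies in a %d bp region",
          length(words), region_len)
  }
  slots <- sample.int(n_slots, length(words))
  for (k in seq_along(words)) {
    at <- region_start1 + (slots[k] - 1L) * (L + 2L)
    chars[at:(at + L - 1L)] <- strsplit(words[k], "")[[1]]
  }
  chars
}

consensus_pwm <- function(id, consensus, strength = 85) {
  L <- nchar(consensus)
  counts <- matrix((100 - strength) / 3, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- strsplit(consensus, "")[[1]]
  for (j in seq_len(L)) counts[chars[j], j] <- strength
  new_pwm(id, counts)
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Writes the complete file bundle the pipeline consumes (genome FASTA, SE /
#' eRNA / TSS / CpG BEDs, RPKM / FPKM / beta TSV matrices, sample labels, SEG
#' CNV table, BEDPE contacts, JASPAR PWMs, TF list, PPI edges) plus
#' ground-truth tables and a manifest JSON.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `truth` (ground-truth
#'   tables) and `config`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  n_act <- round(config$frac_activated * config$n_se)
  if (config$n_crc_tfs > 0 && n_act > 0 && config$n_crc_tfs > n_act) {
    stopf("need at least as many activated SEs as planted CRC TFs")
  }
  if (config$motif_length > 700) {  # SEs are 800-1600 bp; leave headroom
    stopf("motif_length %d incompatible with SE geometry", config$motif_length)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, generate_cohort_impl(config, out_dir, n_act))
}

generate_cohort_impl <- function(config, out_dir, n_act) {
  n_c <- config$n_cancer; n_n <- config$n_normal
  n_samp <- n_c + n_n
  samples <- c(sprintf("TCGA-C%03d", seq_len(n_c)),
               sprintf("NORM-%03d", seq_len(n_n)))
  labels <- setNames(rep(c("cancer", "normal"), c(n_c, n_n)), samples)
  is_cancer <- labels == "cancer"
  sd0 <- config$noise_sd
  ls <- config$link_strength
  shift <- config$activation_shift

  ## ---- genome layout -------------------------------------------------
  chr1_len <- config$n_se * SE_SLOT
  chr2_len <- config$n_genes * GENE_SLOT
  chr1 <- rand_dna(chr1_len)
  chr2 <- rand_dna(chr2_len)

  se_ids <- sprintf("SE%03d", seq_len(config$n_se))
  se_len <- as.integer(round(runif(config$n_se, 800, 1600)))
  se_start0 <- (seq_len(config$n_se) - 1L) * SE_SLOT + 2000L
  se_gr <- granges_from_bed0(rep("chr1", config$n_se), se_start0,
                             se_start0 + se_len, se_ids)
  activated <- sort(sample.int(config$n_se, n_act))
  activated_ids <- se_ids[activated]

  ## eRNAs: 3-8 per SE, contained in the SE
  erna_per_se <- sample(3:8, config$n_se, replace = TRUE)
  erna_se <- rep(seq_len(config$n_se), erna_per_se)
  n_erna <- length(erna_se)
  erna_ids <- sprintf("eRNA%05d", seq_len(n_erna))
  erna_len <- as.integer(round(runif(n_erna, 200, 400)))
  erna_off <- vapply(seq_len(n_erna), function(i) {
    room <- se_len[erna_se[i]] - erna_len[i]
    as.integer(floor(runif(1, 0, max(1, room))))
  }, 1L)
  erna_start0 <- se_start0[erna_se] + erna_off
  erna_gr <- granges_from_bed0(rep("chr1", n_erna), erna_start0,
                               erna_start0 + erna_len, erna_ids)

  ## genes: TSS on chr2
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  tss_pos0 <- (seq_len(config$n_genes) - 1L) * GENE_SLOT + 3500L
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  tss_gr <- granges_from_bed0(rep("chr2", config$n_genes), tss_pos0,
                              tss_pos0 + 1L, gene_ids, gene_strand)

  ## ---- role assignment -----------------------------------------------
  n_linked <- round(config$frac_linked * config$n_genes)
  n_crc <- if (n_act > 0) config$n_crc_tfs else 0L
  partners_per_crc <- 2L
  n_partner <- n_crc * partners_per_crc
  if (config$n_tfs < n_crc + n_partner) {
    stopf("n_tfs too small for %d CRC TFs with %d partners each",
          n_crc, partners_per_crc)
  }
  n_med <- if (n_crc > 0) config$n_ctp_triples else 0L
  n_ctrl <- n_med
  if (n_act > 0 && n_linked < config$n_tfs + n_med + n_ctrl) {
    stopf("frac_linked too small: need >= %d linked genes",
          config$n_tfs + n_med + n_ctrl)
  }

  linked_idx <- if (n_act > 0) sort(sample.int(config$n_genes, n_linked))
                else integer(0)
  # roles drawn from the linked set: TFs first, then mediated, then controls
  role_pool <- sample(linked_idx)
  tf_idx <- sort(head(role_pool, config$n_tfs))
  rest <- setdiff(role_pool, tf_idx)
  med_idx <- sort(head(rest, n_med))
  ctrl_idx <- sort(head(setdiff(rest, med_idx), n_ctrl))
  plain_idx <- setdiff(linked_idx, c(tf_idx, med_idx, ctrl_idx))
  if (n_act == 0) tf_idx <- sort(sample.int(config$n_genes, config$n_tfs))

  tf_ids <- gene_ids[tf_idx]
  crc_tf_ids <- if (n_crc > 0) tf_ids[seq_len(n_crc)] else character(0)
  partner_tf_ids <- if (n_partner > 0)
    tf_ids[n_crc + seq_len(n_partner)] else character(0)
  decoy_tf_ids <- setdiff(tf_ids, c(crc_tf_ids, partner_tf_ids))

  ## CTP pairs: each CRC TF gets `partners_per_crc` partners
  ctp_pairs <- if (n_crc > 0) data.frame(
    crc_tf = rep(crc_tf_ids, each = partners_per_crc),
    partner_tf = partner_tf_ids,
    stringsAsFactors = FALSE
  ) else data.frame(crc_tf = character(), partner_tf = character())

  ## SE assignment for linked genes: CRC TFs own one activated SE each;
  ## partners and CTP genes live on their CRC TF's SE; the rest round-robin.
  gene_se <- rep(NA_integer_, config$n_genes)   # index into SEs
  if (n_act > 0) {
    crc_se <- activated[seq_len(n_crc)]
    names(crc_se) <- crc_tf_ids
    gene_se[tf_idx[seq_len(n_crc)]] <- crc_se
    if (n_partner > 0) {
      gene_se[tf_idx[n_crc + seq_len(n_partner)]] <-
        crc_se[ctp_pairs$crc_tf]
    }
    other_se <- if (length(activated) > n_crc) activated[-seq_len(n_crc)]
                else activated
    if (length(decoy_tf_ids) > 0) {
      gene_se[match(decoy_tf_ids, gene_ids)] <-
        rep_len(other_se, length(decoy_tf_ids))
    }
    pair_of_med <- rep_len(seq_len(nrow(ctp_pairs)), n_med)
    if (n_med > 0) gene_se[med_idx] <- crc_se[ctp_pairs$crc_tf[pair_of_med]]
    pair_of_ctrl <- rep_len(seq_len(nrow(ctp_pairs)), n_ctrl)
    if (n_ctrl > 0) gene_se[ctrl_idx] <- crc_se[ctp_pairs$crc_tf[pair_of_ctrl]]
    if (length(plain_idx) > 0) {
      gene_se[plain_idx] <- rep_len(activated, length(plain_idx))
    }
  }

  ## ---- expression ----------------------------------------------------
  ## Per-SE latent activity and a designated "lead" eRNA trace per SE; all
  ## enhancer-driven signals are standardized (unit variance) before scaling
  ## by noise_sd so link_strength is a correlation.
  latent <- matrix(rnorm(config$n_se * n_samp), nrow = config$n_se,
                   dimnames = list(se_ids, samples))
  w <- sqrt(ls)
  erna_base <- runif(n_erna, 1, 4)
  silent_erna <- runif(n_erna) < 0.10
  erna_base[silent_erna] <- -3
  erna_trace <- matrix(rnorm(n_erna * n_samp), nrow = n_erna)
  for (i in seq_len(n_erna)) {
    erna_trace[i, ] <- w * latent[erna_se[i], ] +
      sqrt(max(0, 1 - ls)) * erna_trace[i, ]
  }
  erna_log2 <- erna_base + sd0 * erna_trace
  act_erna <- erna_se %in% activated
  erna_log2[act_erna, is_cancer] <- erna_log2[act_erna, is_cancer] + shift
  erna_rpkm <- round(2^erna_log2, 4)
  erna_rpkm[erna_rpkm < ZERO_FPKM] <- 0
  dimnames(erna_rpkm) <- list(erna_ids, samples)

  ## lead eRNA per SE: first eRNA of the SE (its standardized trace drives
  ## TFs and control genes, so conditioning behaves like real mediation)
  lead_erna <- match(seq_len(config$n_se), erna_se)
  lead_trace <- erna_trace[lead_erna, , drop = FALSE]  # unit-variance rows

  gene_log2 <- matrix(rnorm(config$n_genes * n_samp), nrow = config$n_genes,
                      dimnames = list(gene_ids, samples))
  gene_base <- runif(config$n_genes, 0.5, 3.5)
  low_expr <- runif(config$n_genes) < 0.15
  gene_base[low_expr] <- -2

  ## plain linked genes: latent-routed SE dependence + cancer shift
  for (i in plain_idx) {
    s <- gene_se[i]
    gene_log2[i, ] <- w * latent[s, ] + sqrt(max(0, 1 - ls)) * gene_log2[i, ]
    gene_log2[i, is_cancer] <- gene_log2[i, is_cancer] + shift / sd0
    gene_base[i] <- runif(1, 1.5, 3)
  }
  ## TFs: driven by the lead eRNA trace of their SE
  tf_base <- setNames(numeric(length(tf_ids)), tf_ids)
  tf_shift <- setNames(numeric(length(tf_ids)), tf_ids)
  for (tfi in seq_along(tf_ids)) {
    id <- tf_ids[tfi]
    i <- tf_idx[tfi]
    role <- if (id %in% crc_tf_ids) "crc"
            else if (id %in% partner_tf_ids) "partner" else "decoy"
    tf_base[id] <- switch(role, crc = 3.5, partner = runif(1, 2.5, 3),
                          decoy = runif(1, 1.5, 3))
    tf_shift[id] <- switch(role, crc = shift * 2, partner = shift,
                           decoy = shift)
    gene_base[i] <- tf_base[id]
    if (n_act > 0) {
      s <- gene_se[i]
      gene_log2[i, ] <- w * lead_trace[s, ] +
        sqrt(max(0, 1 - ls)) * gene_log2[i, ]
      gene_log2[i, is_cancer] <- gene_log2[i, is_cancer] + tf_shift[id] / sd0
    }
  }
  ## mediated CTP genes: expression is a function of the two TF signals only
  truth_triples <- NULL
  if (n_med > 0) {
    tf_signal <- gene_log2[tf_idx, , drop = FALSE]  # standardized TF traces
    rownames(tf_signal) <- tf_ids
    med_pairs <- ctp_pairs[rep_len(seq_len(nrow(ctp_pairs)), n_med), ]
    for (k in seq_len(n_med)) {
      i <- med_idx[k]
      a <- tf_signal[med_pairs$crc_tf[k], ]
      b <- tf_signal[med_pairs$partner_tf[k], ]
      avg <- (a + b) / 2
      # standardize by the within-group SD so the cancer shift carried by the
      # TFs is preserved and the SE->gene correlation stays on the
      # link_strength scale
      sd_w <- sd(avg - stats::ave(avg, is_cancer))
      avg <- avg / sd_w
      gene_log2[i, ] <- sqrt(0.9) * avg + sqrt(0.1) * rnorm(n_samp)
      gene_base[i] <- runif(1, 1.5, 3)
    }
    ## control genes: driven directly by the lead eRNA trace (not via TFs),
    ## with the same explicit cancer shift as other linked genes
    ctrl_pairs <- ctp_pairs[rep_len(seq_len(nrow(ctp_pairs)), n_ctrl), ]
    for (k in seq_len(n_ctrl)) {
      i <- ctrl_idx[k]
      s <- gene_se[i]
      gene_log2[i, ] <- w * lead_trace[s, ] +
        sqrt(max(0, 1 - ls)) * rnorm(n_samp)
      gene_log2[i, is_cancer] <- gene_log2[i, is_cancer] + shift / sd0
      gene_base[i] <- runif(1, 1.5, 3)
    }
    truth_triples <- rbind(
      data.frame(se_id = se_ids[gene_se[med_idx]],
                 erna_id = erna_ids[lead_erna[gene_se[med_idx]]],
                 gene_id = gene_ids[med_idx],
                 crc_tf = med_pairs$crc_tf, partner_tf = med_pairs$partner_tf,
                 mediated = TRUE, stringsAsFactors = FALSE),
      data.frame(se_id = se_ids[gene_se[ctrl_idx]],
                 erna_id = erna_ids[lead_erna[gene_se[ctrl_idx]]],
                 gene_id = gene_ids[ctrl_idx],
                 crc_tf = ctrl_pairs$crc_tf, partner_tf = ctrl_pairs$partner_tf,
                 mediated = FALSE, stringsAsFactors = FALSE)
    )
  }
  gene_log2 <- gene_base + sd0 * gene_log2
  gene_fpkm <- round(2^gene_log2, 4)
  gene_fpkm[gene_fpkm < ZERO_FPKM] <- 0
  dimnames(gene_fpkm) <- list(gene_ids, samples)

  ## ---- methylation ---------------------------------------------------
  cpg_per_se <- 2L
  n_cpg <- config$n_se * cpg_per_se
  cpg_se <- rep(seq_len(config$n_se), each = cpg_per_se)
  cpg_ids <- sprintf("cg%05d", seq_len(n_cpg))
  cpg_pos0 <- se_start0[cpg_se] +
    as.integer(floor(runif(n_cpg, 0, se_len[cpg_se] - 1)))
  cpg_gr <- granges_from_bed0(rep("chr1", n_cpg), cpg_pos0, cpg_pos0 + 1L,
                              cpg_ids)
  hypo <- cpg_se %in% activated & seq_len(n_cpg) %% cpg_per_se == 1L
  rbeta_mean <- function(n, mu, conc = 20) {
    rbeta(n, mu * conc, (1 - mu) * conc)
  }
  beta <- matrix(0, n_cpg, n_samp, dimnames = list(cpg_ids, samples))
  for (i in seq_len(n_cpg)) {
    mu_norm <- runif(1, 0.5, 0.7)
    mu_can <- if (hypo[i]) mu_norm - 0.3 else mu_norm
    beta[i, is_cancer] <- round(rbeta_mean(n_c, mu_can), 4)
    beta[i, !is_cancer] <- round(rbeta_mean(n_n, mu_norm), 4)
  }

  ## ---- CNV segments --------------------------------------------------
  seg <- list()
  chunk <- 50000L
  for (s in samples[is_cancer]) {
    # neutral background tiling of chr1
    starts <- seq(0L, chr1_len - 1L, by = chunk)
    seg[[length(seg) + 1L]] <- data.frame(
      sample = s, chrom = "chr1", start = starts,
      end = pmin(starts + chunk, chr1_len),
      log2ratio = round(rnorm(length(starts), 0, 0.15), 3),
      stringsAsFactors = FALSE
    )
    # amplifications preferentially overlapping activated SEs
    hit <- activated[runif(length(activated)) < 0.6]
    if (length(hit) > 0) {
      seg[[length(seg) + 1L]] <- data.frame(
        sample = s, chrom = "chr1",
        start = se_start0[hit] - 200L,
        end = se_start0[hit] + se_len[hit] + 200L,
        log2ratio = round(rnorm(length(hit), 1.2, 0.2), 3),
        stringsAsFactors = FALSE
      )
    }
  }
  seg <- do.call(rbind, seg)
  amp_truth <- which(seg$log2ratio > 0.8)
  seg$segment_id <- sprintf("seg%06d", seq_len(nrow(seg)))

  ## ---- contacts ------------------------------------------------------
  link_gene_idx <- which(!is.na(gene_se))
  mk_contact <- function(se_i, gene_i) {
    a_s <- se_start0[se_i]; a_e <- a_s + se_len[se_i]
    p0 <- tss_pos0[gene_i]
    b_s <- p0 - as.integer(floor(runif(length(gene_i), 0, 2000)))
    b_e <- p0 + as.integer(floor(runif(length(gene_i), 200, 2000)))
    data.frame(c1 = "chr1", s1 = a_s, e1 = a_e,
               c2 = "chr2", s2 = pmax(0L, b_s), e2 = b_e,
               stringsAsFactors = FALSE)
  }
  true_ct <- if (length(link_gene_idx) > 0)
    mk_contact(gene_se[link_gene_idx], link_gene_idx) else NULL
  n_decoy <- max(20L, 2L * length(link_gene_idx))
  decoy_se <- sample.int(config$n_se, n_decoy, replace = TRUE)
  decoy_gene <- sample(setdiff(seq_len(config$n_genes), link_gene_idx),
                       n_decoy, replace = TRUE)
  decoy_ct <- mk_contact(decoy_se, decoy_gene)
  ct <- rbind(true_ct, decoy_ct)
  # orientation-agnostic: write half of the contacts with anchors swapped
  swap <- seq_len(nrow(ct)) %% 2 == 0
  ct_out <- ct
  ct_out[swap, ] <- ct[swap, c(4:6, 1:3)]
  contacts <- list(
    anchor1 = granges_from_bed0(ct_out$c1, ct_out$s1, ct_out$e1),
    anchor2 = granges_from_bed0(ct_out$c2, ct_out$s2, ct_out$e2),
    name = sprintf("loop%05d", seq_len(nrow(ct_out)))
  )

  ## ---- motifs and sequence planting ----------------------------------
  consensus <- setNames(vapply(seq_along(tf_ids), function(i)
    paste(rand_dna(config$motif_length), collapse = ""), ""), tf_ids)
  pwms <- list()
  for (id in tf_ids) {
    strength <- if (id %in% c(crc_tf_ids, partner_tf_ids)) 85 else 60
    pwms[[id]] <- consensus_pwm(id, consensus[[id]], strength)
  }
  ## words destined for each SE are pooled and planted in one call so copies
  ## from different TFs never overwrite each other
  se_words <- vector("list", config$n_se)
  add_se_words <- function(se_i, words) {
    se_words[[se_i]] <<- c(se_words[[se_i]], words)
  }
  crc_edges <- NULL
  if (n_crc > 0) {
    crc_se_idx <- gene_se[match(crc_tf_ids, gene_ids)]
    for (k in seq_len(n_crc)) {
      id <- crc_tf_ids[k]
      words <- c(rep(consensus[[id]], 5),
                 mutate_consensus(consensus[[id]],
                                  max(1L, round(0.1 * config$motif_length))))
      add_se_words(crc_se_idx[k], words)
      # cross-regulation: plant in the next CRC TF's SE (ring)
      nxt <- if (k == n_crc) 1L else k + 1L
      if (n_crc > 1) {
        add_se_words(crc_se_idx[nxt], rep(consensus[[id]], 5))
      }
    }
    ring_to <- if (n_crc > 1) crc_tf_ids[c(2:n_crc, 1)] else character(0)
    crc_edges <- rbind(
      data.frame(from = crc_tf_ids, to = crc_tf_ids,
                 stringsAsFactors = FALSE),
      if (n_crc > 1) data.frame(from = crc_tf_ids, to = ring_to,
                                stringsAsFactors = FALSE)
    )
    ## partner + CRC motifs in promoters of mediated genes
    if (n_med > 0) {
      med_pairs <- truth_triples[truth_triples$mediated, ]
      for (k in seq_len(nrow(med_pairs))) {
        gi <- match(med_pairs$gene_id[k], gene_ids)
        prom_start1 <- tss_pos0[gi] - 3000L + 1L
        chr2 <- plant_words(chr2, prom_start1 + 10L, 2900L,
                            rep(consensus[[med_pairs$partner_tf[k]]], 3))
        chr2 <- plant_words(chr2, prom_start1 + 3100L, 2900L,
                            rep(consensus[[med_pairs$crc_tf[k]]], 5))
      }
    }
    ## light decoy planting: 2 copies of each decoy TF consensus somewhere
    for (id in decoy_tf_ids) {
      se_i <- sample.int(config$n_se, 1)
      add_se_words(se_i, rep(consensus[[id]], 2))
    }
    for (se_i in which(lengths(se_words) > 0)) {
      chr1 <- plant_words(chr1, se_start0[se_i] + 1L, se_len[se_i],
                          se_words[[se_i]])
    }
  }

  ## ---- PPIs ----------------------------------------------------------
  datasets <- c("huri", "biogrid", "apid")
  ppi <- list()
  if (nrow(ctp_pairs) > 0) {
    for (k in seq_len(nrow(ctp_pairs))) {
      nsrc <- sample(2:3, 1)
      ppi[[length(ppi) + 1L]] <- data.frame(
        tf_a = ctp_pairs$crc_tf[k], tf_b = ctp_pairs$partner_tf[k],
        dataset = sample(datasets, nsrc), stringsAsFactors = FALSE
      )
    }
  }
  ## decoys: single-dataset edges, plus a couple of 2-dataset edges between
  ## CRC TFs and decoy TFs (these fail the motif-support gate downstream)
  n_ppi_decoy <- max(10L, config$n_tfs)
  for (k in seq_len(n_ppi_decoy)) {
    pair <- sample(tf_ids, 2)
    ppi[[length(ppi) + 1L]] <- data.frame(
      tf_a = pair[1], tf_b = pair[2], dataset = sample(datasets, 1),
      stringsAsFactors = FALSE
    )
  }
  if (n_crc > 0 && length(decoy_tf_ids) >= 2) {
    for (k in 1:2) {
      ppi[[length(ppi) + 1L]] <- data.frame(
        tf_a = crc_tf_ids[1 + (k - 1) %% n_crc], tf_b = decoy_tf_ids[k],
        dataset = datasets[1:2], stringsAsFactors = FALSE
      )
    }
  }
  ppi <- unique(do.call(rbind, ppi))

  ## ---- write bundle --------------------------------------------------
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(chr1, collapse = ""),
                                       chr2 = paste(chr2, collapse = "")))
  pth <- function(f) file.path(out_dir, f)
  paths <- list(
    genome = pth("genome.fa"),
    se_regions = pth("se_regions.bed"),
    erna_loci = pth("erna_loci.bed"),
    erna_rpkm = pth("erna_rpkm.tsv"),
    gene_tss = pth("gene_tss.bed"),
    gene_fpkm = pth("gene_fpkm.tsv"),
    sample_labels = pth("sample_labels.tsv"),
    beta = pth("methylation_beta.tsv"),
    cpg_loci = pth("cpg_loci.bed"),
    cnv_seg = pth("cnv_segments.tsv"),
    contacts = pth("contacts.bedpe"),
    pwms = pth("pwms_jaspar.txt"),
    tf_list = pth("tf_list.tsv"),
    ppi = pth("ppi_edges.tsv"),
    manifest = pth("manifest.json")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  write_bed(se_gr, paths$se_regions)
  write_bed(erna_gr, paths$erna_loci)
  write_bed(tss_gr, paths$gene_tss)
  write_bed(cpg_gr, paths$cpg_loci)
  erna_lm <- labeled_matrix(erna_rpkm, labels)
  write_matrix(erna_lm, paths$erna_rpkm, paths$sample_labels)
  write_matrix(labeled_matrix(gene_fpkm, labels), paths$gene_fpkm)
  write_matrix(labeled_matrix(beta, labels), paths$beta)
  data.table::fwrite(seg[, c("sample", "chrom", "start", "end", "log2ratio",
                             "segment_id")],
                     paths$cnv_seg, sep = "\t", quote = FALSE)
  write_bedpe(contacts, paths$contacts)
  write_jaspar(pwms, paths$pwms)
  data.table::fwrite(data.frame(tf_id = tf_ids, gene_id = tf_ids,
                                pwm_id = tf_ids),
                     paths$tf_list, sep = "\t", quote = FALSE)
  data.table::fwrite(ppi, paths$ppi, sep = "\t", quote = FALSE)

  ## ---- ground truth --------------------------------------------------
  se_gene_links <- if (length(link_gene_idx) > 0) data.frame(
    se_id = se_ids[gene_se[link_gene_idx]],
    gene_id = gene_ids[link_gene_idx],
    stringsAsFactors = FALSE
  ) else data.frame(se_id = character(), gene_id = character())
  truth <- list(
    activated_se_ids = activated_ids,
    se_gene_links = se_gene_links,
    master_tf_ids = crc_tf_ids,
    crc_tf_ids = crc_tf_ids,
    crc_edges = crc_edges %||% data.frame(from = character(),
                                          to = character()),
    ctp_triples = truth_triples %||% data.frame(
      se_id = character(), erna_id = character(), gene_id = character(),
      crc_tf = character(), partner_tf = character(), mediated = logical()),
    hypo_cpg_ids = cpg_ids[hypo],
    amplified_segment_ids = seg$segment_id[amp_truth]
  )
  truth_paths <- list()
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  save_tsv <- function(x, name) {
    p <- file.path(tdir, paste0(name, ".tsv"))
    data.table::fwrite(x, p, sep = "\t", quote = FALSE)
    p
  }
  truth_paths$activated_se_ids <-
    save_tsv(data.frame(se_id = truth$activated_se_ids), "activated_se_ids")
  truth_paths$se_gene_links <- save_tsv(truth$se_gene_links, "se_gene_links")
  truth_paths$crc_tf_ids <-
    save_tsv(data.frame(tf_id = truth$crc_tf_ids), "crc_tf_ids")
  truth_paths$crc_edges <- save_tsv(truth$crc_edges, "crc_edges")
  truth_paths$ctp_triples <- save_tsv(truth$ctp_triples, "ctp_triples")
  truth_paths$hypo_cpg_ids <-
    save_tsv(data.frame(cpg_id = truth$hypo_cpg_ids), "hypo_cpg_ids")
  truth_paths$amplified_segment_ids <-
    save_tsv(data.frame(segment_id = truth$amplified_segment_ids),
             "amplified_segment_ids")

  manifest <- list(
    generator = "secrc::generate_cohort",
    seed = config$seed,
    config = unclass(config),
    files = lapply(paths[names(paths) != "manifest"], basename),
    truth_files = lapply(truth_paths, function(p)
      file.path("truth", basename(p))),
    counts = list(samples = n_samp, ses = config$n_se,
                  activated_ses = length(activated_ids), ernas = n_erna,
                  genes = config$n_genes, linked_genes = nrow(se_gene_links),
                  tfs = length(tf_ids), crc_tfs = length(crc_tf_ids),
                  ctp_triples = nrow(truth$ctp_triples))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(paths = paths, truth = truth, truth_paths = truth_paths,
       config = config)
}

#' Sample random genome regions matched on length
#'
#' Draws `n` regions whose lengths are resampled from `length_source`,
#' placed uniformly over the genome and rejected if they overlap `exclude`;
#' used as the background set for CNV enrichment.
#'
#' @param genome `DNAStringSet` (for chromosome lengths).
#' @param n Number of regions.
#' @param length_source `GRanges` supplying the length distribution.
#' @param exclude `GRanges` that placements must not overlap (may be empty).
#' @param seed Integer seed.
#' @param max_tries Bounded retries per region.
#' @return `GRanges` of `n` placed regions.
#' @export
sample_random_regions <- function(genome, n, length_source,
                                  exclude = NULL, seed = 1L,
                                  max_tries = 200L) {
  lens <- Biostrings::width(length_source)
  chroms <- names(genome)
  chrom_len <- setNames(Biostrings::width(genome), chroms)
  with_seed(seed, {
    pick_len <- sample(lens, n, replace = TRUE)
    out_chrom <- character(n); out_start <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        # chromosome chosen proportional to available positions
        avail <- pmax(chrom_len - pick_len[i] + 1, 0)  # keep names
        if (sum(avail) == 0) break
        ch <- sample(chroms, 1, prob = avail)
        st <- floor(runif(1, 0, avail[ch]))  # 0-based start
        cand <- granges_from_bed0(ch, st, st + pick_len[i])
        if (is.null(exclude) || length(exclude) == 0 ||
            !any(quiet_overlaps_any(cand, exclude))) {
          out_chrom[i] <- ch; out_start[i] <- st
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stopf("random region placement failed after %d tries (placed %d of %d)",
              max_tries, i - 1, n)
      }
    }
    granges_from_bed0(out_chrom, out_start, out_start + pick_len,
                      sprintf("rand%05d", seq_len(n)))
  })
}
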