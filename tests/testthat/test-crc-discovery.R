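mk_expr <- function(values, n_c, n_n, ids) {
  samples <- c(sprintf("c%02d", seq_len(n_c)), sprintf("n%02d", seq_len(n_n)))
  dimnames(values) <- list(ids, samples)
  labeled_matrix(values, setNames(rep(c("cancer", "normal"), c(n_c, n_n)),
                                  samples))
}

test_that("master score arithmetic and threshold rule", {
  # mu_c = 2, FC = 4 => lambda = 2 * log2(4) = 4; ratio 0.5 => MS = 2
  n_c <- 10
  cv <- c(rep(2, 3), rep(10, 5), rep(1.5, 2))   # trimmed mean of lowest 3 = 2
  nv <- rep(0.5, 10)                            # trimmed mean 0.5 -> FC 4
  v <- matrix(c(cv, nv), 1)
  lm <- mk_expr(v, 10, 10, "TF1")
  ms <- master_score(lm, "TF1", trim = 0.3, top_frac = 0.5)
  row <- ms$scores[1, ]
  expect_equal(row$mu_c, mean(c(1.5, 1.5, 2)))
  # threshold rule example: mu_c(trim) = 0 => threshold max(1, 0) = 1
  v2 <- matrix(c(0, 2, 3, 5, rep(1, 4)), 1)
  lm2 <- mk_expr(v2, 4, 4, "TF2")
  ms2 <- master_score(lm2, "TF2", trim = 0.3)
  expect_equal(ms2$scores$expression_ratio, 3 / 4)
})

test_that("master ordering matches brute-force recomputation; top by ceiling", {
  set.seed(61)
  n_tf <- 50
  v <- matrix(2^rnorm(n_tf * 100, 2), n_tf, 100)
  ids <- sprintf("TF%02d", seq_len(n_tf))
  lm <- mk_expr(v, 50, 50, ids)
  ms <- master_score(lm, ids, trim = 0.3, top_frac = 0.15)
  # brute force per TF
  brute <- vapply(ids, function(tf) {
    cv <- sort(v[match(tf, ids), 1:50])[1:15]
    nv <- sort(v[match(tf, ids), 51:100])[1:15]
    lam <- mean(cv) * log2(mean(cv) / mean(nv))
    lam * mean(v[match(tf, ids), 1:50] > max(1, mean(cv)))
  }, 0)
  expect_equal(setNames(ms$scores$ms, ms$scores$tf_id)[ids], brute,
               tolerance = 1e-12)
  expect_equal(ms$scores$tf_id[order(ms$scores$rank)][1:8],
               names(sort(brute, decreasing = TRUE))[1:8])
  expect_length(ms$master_tf_ids, ceiling(0.15 * n_tf))
})

test_that("CRC membership requires >= 5 valid self-hits; cross-edges form", {
  set.seed(62)
  # consensi without palindromes or shifted self-similarity, so neither
  # strand of one planted copy can match another by accident
  consA <- "ATTGCCGTAA"; consB <- "GACTGTCAAG"
  mk_se_seq <- function(words, len = 600) {
    chars <- sample(c("A", "C", "G", "T"), len, TRUE)
    at <- seq(1, by = 30, length.out = length(words))
    for (k in seq_along(words)) {
      chars[at[k]:(at[k] + 9)] <- strsplit(words[k], "")[[1]]
    }
    paste(chars, collapse = "")
  }
  # SE_A: 5 copies of A's motif + 5 of B's; SE_B: only 4 copies of B's
  seqA <- mk_se_seq(c(rep(consA, 5), rep(consB, 5)))
  seqB <- mk_se_seq(rep(consB, 4))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", paste0(seqA, seqB)), fa)
  genome <- read_fasta(fa)
  se <- granges_from_bed0(c("chr1", "chr1"), c(0, 600), c(600, 1200),
                          c("SEA", "SEB"))
  links <- data.frame(se_id = c("SEA", "SEB"), gene_id = c("TFA", "TFB"),
                      stringsAsFactors = FALSE)
  pwms <- list(TFA = test_pwm("TFA", consA), TFB = test_pwm("TFB", consB))
  crc <- detect_crc(c("TFA", "TFB"), links, pwms, genome, se)
  # TFA self-loops (5 copies); TFB has only 4 -> excluded despite hits
  expect_equal(crc$nodes, "TFA")
  expect_true(any(crc$edges$from == "TFA" & crc$edges$to == "TFA"))
  # graph restricted to self-looped nodes: no edges to TFB
  expect_false("TFB" %in% c(crc$edges$from, crc$edges$to))
  # order invariance
  crc2 <- detect_crc(c("TFB", "TFA"), links, pwms, genome, se)
  expect_equal(crc2$nodes, crc$nodes)
  # master TF without a PWM is excluded with a warning
  expect_warning(detect_crc(c("TFA", "TFZ"), links, pwms, genome, se),
                 "TFZ")
})

test_that("CRC graph equals brute-force construction from the hit table", {
  b <- small_bundle()
  genome <- read_fasta(b$paths$genome)
  se <- read_bed(b$paths$se_regions)
  pwms <- read_jaspar(b$paths$pwms)
  tfs <- b$truth$crc_tf_ids
  links <- b$truth$se_gene_links
  crc <- detect_crc(tfs, links, pwms, genome, se)
  expect_setequal(crc$nodes, tfs)  # planted circuitry recovered exactly
  # brute force from the full hit table
  own <- lapply(setNames(tfs, tfs), function(tf)
    unique(links$se_id[links$gene_id == tf]))
  all_se <- se[S4Vectors::mcols(se)$name %in% unique(unlist(own))]
  hits <- scan_regions(genome, all_se, pwms[tfs], 1e-4)
  for (a in tfs) {
    for (b_ in tfs) {
      n_hits <- sum(hits$pwm_id == a & hits$region %in% own[[b_]])
      has_edge <- any(crc$edges$from == a & crc$edges$to == b_)
      expect_equal(has_edge, n_hits >= 5,
                   label = sprintf("edge %s->%s", a, b_))
    }
  }
  # planted ring: every node self-loops and edge count >= node count
  expect_true(all(crc$nodes %in% crc$edges$from[crc$edges$from ==
                                                  crc$edges$to]))
  expect_gte(nrow(crc$edges), length(crc$nodes))
})

test_that("downstream genes: promoter binding plus MI gate", {
  b <- small_bundle()
  genome <- read_fasta(b$paths$genome)
  se <- read_bed(b$paths$se_regions)
  tss <- read_bed(b$paths$gene_tss)
  pwms <- read_jaspar(b$paths$pwms)
  genes <- filter_genes(read_matrix(b$paths$gene_fpkm,
                                    b$paths$sample_labels))
  links <- b$truth$se_gene_links
  tfs <- b$truth$crc_tf_ids
  ds <- downstream_genes(tfs, genes, links, se, tss, genome, pwms,
                         n_perm = 300, seed = 9)
  med <- b$truth$ctp_triples[b$truth$ctp_triples$mediated, ]
  # planted promoter motifs of CRC TFs in mediated-gene promoters:
  # those genes are recovered as confirmed promoter-class targets
  planted <- paste(med$crc_tf, med$gene_id)
  got <- paste(ds$tf_id, ds$gene_id)[ds$confirmed &
                                       ds$binding %in% c("promoter", "both")]
  expect_gte(mean(planted %in% got), 0.7)
  # binding class "both" appears iff SE and promoter support coexist
  if (any(ds$binding == "both")) {
    expect_true(all(ds$binding %in% c("SE", "promoter", "both")))
  }
})
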