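test_that("bridge decision rule is exactly Pr < 0.05 and Pp > 0.05", {
  set.seed(71)
  n <- 60
  e <- rnorm(n)
  tfa <- 0.9 * e + sqrt(1 - 0.81) * rnorm(n)
  tfb <- 0.9 * e + sqrt(1 - 0.81) * rnorm(n)
  g_med <- 0.7 * (tfa + tfb) + 0.3 * rnorm(n)   # mediated
  bt <- bridge_test(e, g_med, tfa, tfb)
  expect_lt(bt$pc$p_raw, 0.05)
  expect_identical(bt$is_ctp,
                   bt$pc$p_raw < 0.05 && bt$pc$p_partial > 0.05)
  # Pr >= 0.05 forces is_ctp FALSE regardless of Pp
  g_null <- rnorm(n)
  bt0 <- bridge_test(e, g_null, tfa, tfb)
  expect_gte(bt0$pc$p_raw, 0.05)
  expect_false(bt0$is_ctp)
  # swapping the TFs leaves the joint partial correlation unchanged
  bt_sw <- bridge_test(e, g_med, tfb, tfa)
  expect_equal(bt$pc$rho_partial, bt_sw$pc$rho_partial, tolerance = 1e-12)
})

test_that("mediated vs direct triples are separated by the bridge test", {
  set.seed(72)
  n <- 100
  flags_med <- logical(40); flags_dir <- logical(40)
  for (i in 1:40) {
    e <- rnorm(n)
    tfa <- 0.85 * e + sqrt(1 - 0.85^2) * rnorm(n)
    tfb <- 0.85 * e + sqrt(1 - 0.85^2) * rnorm(n)
    g_med <- sqrt(0.9) * (tfa + tfb) / sqrt(2 + 2 * 0.85^2) +
      sqrt(0.1) * rnorm(n)
    g_dir <- 0.85 * e + sqrt(1 - 0.85^2) * rnorm(n)
    flags_med[i] <- bridge_test(e, g_med, tfa, tfb)$is_ctp
    flags_dir[i] <- bridge_test(e, g_dir, tfa, tfb)$is_ctp
  }
  expect_gte(mean(flags_med), 0.8)
  expect_lte(mean(flags_dir), 0.1)
})

test_that("partner gates: PPI multiplicity, ratio, motif, MI — in order", {
  b <- small_bundle()
  genome <- read_fasta(b$paths$genome)
  se <- read_bed(b$paths$se_regions)
  tss <- read_bed(b$paths$gene_tss)
  pwms <- read_jaspar(b$paths$pwms)
  genes <- filter_genes(read_matrix(b$paths$gene_fpkm,
                                    b$paths$sample_labels))
  ppi <- read_ppi(b$paths$ppi)
  tf_tab <- data.table::fread(b$paths$tf_list, data.table = FALSE)
  links <- b$truth$se_gene_links
  links$best_es <- 1
  cand <- partner_candidates(
    b$truth$crc_tf_ids, ppi, genes, links, pwms, genome, se, tss,
    tf_universe = tf_tab$gene_id, n_perm = 300, seed = 2)
  truth_pairs <- unique(b$truth$ctp_triples[, c("crc_tf", "partner_tf")])
  got <- paste(cand$crc_tf, cand$partner_tf)
  # planted partners retained
  expect_gte(mean(paste(truth_pairs$crc_tf, truth_pairs$partner_tf) %in%
                    got), 0.8)
  # gate invariants hold row-wise
  expect_true(all(cand$ppi_support >= 2))
  expect_true(all(cand$expression_ratio > 0.3))
  expect_true(all(cand$motif_support >= 5))
  expect_true(all(cand$mi_p < 0.01))
  # single-dataset PPI edges alone are never enough
  single <- ppi[!duplicated(paste(pmin(ppi$tf_a, ppi$tf_b),
                                  pmax(ppi$tf_a, ppi$tf_b))), ]
  edges_once <- table(paste(pmin(ppi$tf_a, ppi$tf_b),
                            pmax(ppi$tf_a, ppi$tf_b)))
  once_only <- names(edges_once)[edges_once == 1]
  bad <- got %in% gsub(" ", " ", once_only)
  expect_false(any(bad))
})

test_that("ci_validate separates mediated from direct triples; deterministic", {
  set.seed(73)
  n <- 50
  n_tri <- 16                       # alternating mediated / direct control
  samples <- sprintf("s%02d", 1:n)
  labs <- setNames(rep("cancer", n), samples)
  ev <- matrix(0, n_tri, n,
               dimnames = list(sprintf("e%02d", seq_len(n_tri)), samples))
  gv <- matrix(0, 3 * n_tri, n,
               dimnames = list(c(sprintf("g%02d", seq_len(n_tri)),
                                 sprintf("TFa%02d", seq_len(n_tri)),
                                 sprintf("TFb%02d", seq_len(n_tri))),
                               samples))
  rows <- list()
  for (i in seq_len(n_tri)) {
    mediated <- i %% 2 == 1
    e <- rnorm(n)
    tfa <- 0.85 * e + 0.53 * rnorm(n)
    tfb <- 0.85 * e + 0.53 * rnorm(n)
    g <- if (mediated) 0.65 * (tfa + tfb) + 0.45 * rnorm(n)
         else 0.85 * e + 0.53 * rnorm(n)
    ev[i, ] <- 2^e
    gv[i, ] <- 2^g
    gv[n_tri + i, ] <- 2^tfa
    gv[2 * n_tri + i, ] <- 2^tfb
    rows[[i]] <- data.frame(
      se_id = sprintf("SE%02d", i), erna_id = rownames(ev)[i],
      gene_id = rownames(gv)[i], crc_tf = rownames(gv)[n_tri + i],
      partner_tf = rownames(gv)[2 * n_tri + i], stringsAsFactors = FALSE)
  }
  bridges <- do.call(rbind, rows)
  bridges$is_ctp <- TRUE
  erna <- structure(list(values = ev, sample_labels = labs),
                    class = "labeled_matrix")
  expr <- structure(list(values = gv, sample_labels = labs),
                    class = "labeled_matrix")
  v1 <- ci_validate(bridges, erna, expr, n_perm = 300, seed = 4)
  v2 <- ci_validate(bridges, erna, expr, n_perm = 300, seed = 4)
  expect_identical(v1$bridges$ci_p, v2$bridges$ci_p)
  expect_equal(v1$confirmed_fraction, mean(v1$bridges$ci_confirmed))
  med <- seq(1, n_tri, by = 2)
  dir_ <- seq(2, n_tri, by = 2)
  # mediated triples are confirmed (CI not rejected) more often than direct
  expect_gt(mean(v1$bridges$ci_p[med]), mean(v1$bridges$ci_p[dir_]))
  expect_gte(mean(v1$bridges$ci_confirmed[med]),
             mean(v1$bridges$ci_confirmed[dir_]))
})

test_that("CTP summary counts equal brute-force aggregation", {
  bridges <- data.frame(
    se_id = c("SE1", "SE1", "SE2", "SE2"),
    erna_id = paste0("e", 1:4),
    gene_id = c("g1", "g2", "g3", "g1"),
    crc_tf = c("A", "A", "A", "B"),
    partner_tf = c("P", "P", "P", "Q"),
    is_ctp = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  s <- summarize_ctps(bridges)
  # one CTP (A,P) bridging 3 genes -> per-gene count 1, mean 1.0
  expect_equal(nrow(s$pairs), 1)
  expect_equal(s$pairs$n_links, 3)
  expect_true(all(s$per_gene$n_ctps == 1))
  expect_equal(s$mean_ctps_per_gene, 1)
  # no CTPs -> empty with NA mean
  s0 <- summarize_ctps(transform(bridges, is_ctp = FALSE))
  expect_equal(nrow(s0$pairs), 0)
  expect_true(is.na(s0$mean_ctps_per_gene))
})
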