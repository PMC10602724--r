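test_that("contact support requires SE-anchor plus promoter-anchor overlap", {
  se <- granges_from_bed0("chr1", c(1000, 50000), c(3000, 52000),
                          c("SE1", "SE2"))
  tss <- granges_from_bed0("chr2", c(10000, 90000), c(10001, 90001),
                          c("g1", "g2"), c("+", "-"))
  # contact exactly spanning SE1 <-> promoter(g1)
  ct <- list(anchor1 = granges_from_bed0("chr1", 1000, 3000),
             anchor2 = granges_from_bed0("chr2", 9000, 11000),
             name = "c1")
  got <- contact_supported_pairs(se, tss, ct)
  expect_equal(got, data.frame(se_id = "SE1", gene_id = "g1",
                               stringsAsFactors = FALSE))
  # orientation-agnostic: swapped anchors give the same pair
  ct_sw <- list(anchor1 = ct$anchor2, anchor2 = ct$anchor1, name = "c1")
  expect_equal(contact_supported_pairs(se, tss, ct_sw), got)
  # anchor beyond TSS + 3000 on both sides is not a candidate
  ct_far <- list(anchor1 = granges_from_bed0("chr1", 1000, 3000),
                 anchor2 = granges_from_bed0("chr2", 13001, 14000),
                 name = "c2")
  expect_equal(nrow(contact_supported_pairs(se, tss, ct_far)), 0)
})

test_that("candidate set equals brute-force all-pairs anchor check", {
  set.seed(51)
  se <- granges_from_bed0(rep("chr1", 10), seq(0, by = 5000, length.out = 10),
                          seq(0, by = 5000, length.out = 10) + 2000,
                          sprintf("SE%02d", 1:10))
  tpos <- seq(5000, by = 10000, length.out = 15)
  tss <- granges_from_bed0(rep("chr2", 15), tpos, tpos + 1,
                          sprintf("g%02d", 1:15),
                          sample(c("+", "-"), 15, TRUE))
  n <- 40
  a_chr <- sample(c("chr1", "chr2"), n, TRUE)
  b_chr <- sample(c("chr1", "chr2"), n, TRUE)
  a_st <- sample.int(150000, n); b_st <- sample.int(150000, n)
  ct <- list(anchor1 = granges_from_bed0(a_chr, a_st, a_st + 1500),
             anchor2 = granges_from_bed0(b_chr, b_st, b_st + 1500),
             name = sprintf("c%02d", 1:n))
  got <- contact_supported_pairs(se, tss, ct)
  prom <- promoter_windows(tss, 3000)
  want <- list()
  for (i in seq_len(n)) {
    for (si in seq_along(se)) {
      for (gi in seq_along(tss)) {
        hit <- function(anc) {
          IRanges::overlapsAny(anc[i], se[si]) &&
            IRanges::overlapsAny(if (identical(anc, ct$anchor1))
              ct$anchor2[i] else ct$anchor1[i], prom[gi])
        }
        if (hit(ct$anchor1) || hit(ct$anchor2)) {
          want[[length(want) + 1L]] <- c(sprintf("SE%02d", si),
                                         sprintf("g%02d", gi))
        }
      }
    }
  }
  want <- unique(do.call(rbind, want))
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$se_id, got$gene_id),
                  paste(want[, 1], want[, 2]))
})

test_that("enhanced score follows the stated arithmetic", {
  # eS = (nmi * log2FC) / (pnorm(P) * pnorm(q))
  expect_equal(secrc:::es_value(0.2, 1, 1e-5, 1e-5),
               0.2 / pnorm(1e-5)^2, tolerance = 1e-9)
  expect_equal(secrc:::es_value(0.2, 1, 1e-5, 1e-5), 0.8, tolerance = 1e-4)
  expect_equal(secrc:::es_value(0, 3, 1e-5, 1e-5), 0)
})

test_that("enhanced_score computes MI on cancer samples and trimmed FC", {
  set.seed(52)
  n <- 120
  labels <- rep(c("cancer", "normal"), each = 60)
  lat <- rnorm(n)
  erna <- 2^(2 + lat + rnorm(n, sd = 0.3) + (labels == "cancer") * 2)
  gene <- 2^(1 + lat + rnorm(n, sd = 0.3) + (labels == "cancer") * 2)
  es <- enhanced_score(erna, gene, labels, n_perm = 300, seed = 4)
  expect_lt(es$p_mi, 1e-3)
  expect_gt(es$fc, 1)
  expect_gt(es$es, 0.005)
  # the MI part must ignore normal samples entirely
  gene2 <- gene
  gene2[labels == "normal"] <- rev(gene2[labels == "normal"])
  es2 <- enhanced_score(erna, gene2, labels, n_perm = 300, seed = 4)
  expect_identical(es$p_mi, es2$p_mi)
  # mu_n = 0 floors the fold change and flags it
  gene3 <- gene; gene3[labels == "normal"] <- 0
  es3 <- enhanced_score(erna, gene3, labels, n_perm = 300, seed = 4)
  expect_true(es3$fc_floored)
  expect_true(is.finite(es3$es))
})

test_that("gene assignment applies all three gates and the filter oracle", {
  sc <- data.frame(
    se_id = c("SE1", "SE1", "SE2", "SE2", "SE3"),
    erna_id = c("e1", "e2", "e3", "e4", "e5"),
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    nmi = 0.3, mi = 0.3,
    p_mi = c(1e-5, 1e-5, 1e-3, 1e-5, 1e-5),
    p_up = 1e-6, q_up = c(1e-5, 1e-5, 1e-5, 1e-5, 2e-4),
    mu_c = 4, mu_n = 1, fc = 4, log2_fc = 2,
    es = c(0.0051, 0.5, 0.02, 0.004, 0.3),
    stringsAsFactors = FALSE
  )
  got <- assign_genes(sc, tf_ids = "g1")
  # g1 assigned (both eRNAs pass; boundary eS 0.0051 > 0.005 counts),
  # g2 fails the P gate, g3 fails eS, g4 fails q
  expect_equal(got$gene_id, "g1")
  expect_equal(got$best_es, 0.5)
  expect_equal(got$best_erna, "e2")
  expect_equal(got$supporting_ernas, "e1,e2")
  expect_true(got$is_tf)
  # brute-force filter oracle on random score tables
  set.seed(53)
  sc2 <- data.frame(
    se_id = sample(sprintf("SE%d", 1:6), 300, TRUE),
    erna_id = sprintf("e%03d", 1:300),
    gene_id = sample(sprintf("g%d", 1:40), 300, TRUE),
    nmi = runif(300), mi = runif(300),
    p_mi = 10^runif(300, -6, 0), p_up = 10^runif(300, -6, 0),
    q_up = 10^runif(300, -6, 0), mu_c = 2, mu_n = 1, fc = 2, log2_fc = 1,
    es = runif(300, 0, 0.02), stringsAsFactors = FALSE
  )
  got2 <- assign_genes(sc2)
  pass <- sc2[sc2$p_mi < 1e-4 & sc2$q_up < 1e-4 & sc2$es > 0.005, ]
  expect_setequal(paste(got2$se_id, got2$gene_id),
                  unique(paste(pass$se_id, pass$gene_id)))
})

test_that("data-driven eS threshold follows the formula and its properties", {
  sc <- data.frame(nmi = rep(0.1, 10), log2_fc = rep(0.0125, 10))
  expect_equal(compute_es_threshold(sc),
               (0.1 * 0.0125) / pnorm(1e-4)^2, tolerance = 1e-9)
  expect_equal(compute_es_threshold(sc), 0.005, tolerance = 1e-3)
  # linear in mean nmi
  sc2 <- transform(sc, nmi = nmi * 3)
  expect_equal(compute_es_threshold(sc2), 3 * compute_es_threshold(sc),
               tolerance = 1e-12)
  expect_warning(compute_es_threshold(transform(sc, nmi = 0)), "threshold")
  expect_error(compute_es_threshold(sc[1:3, ]), ">= 10")
})

test_that("eS is monotone in nmi and log2FC with other factors fixed", {
  base <- secrc:::es_value(0.2, 1, 1e-5, 1e-5)
  expect_gt(secrc:::es_value(0.3, 1, 1e-5, 1e-5), base)
  expect_gt(secrc:::es_value(0.2, 1.5, 1e-5, 1e-5), base)
})
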