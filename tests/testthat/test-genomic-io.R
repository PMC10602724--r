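test_that("BED round-trips and validates records", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200\tSE1"), p)
  gr <- read_bed(p)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr1")
  expect_equal(GenomicRanges::start(gr), 101)  # 1-based in memory
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(S4Vectors::mcols(gr)$name, "SE1")
  expect_equal(as.character(GenomicRanges::strand(gr)), "*")

  # empty file -> empty GRanges
  writeLines(character(0), p)
  expect_length(read_bed(p), 0)

  # malformed records name the offending line
  writeLines(c("chr1\t10\t20\tok", "chr1\t30\t25\tbad"), p)
  expect_error(read_bed(p), "line 2")
  writeLines("chr1\t100", p)
  expect_error(read_bed(p), "field")

  # write-then-read of random intervals preserves every record
  set.seed(14)
  n <- 500
  start <- sample.int(1e6, n)
  gr2 <- granges_from_bed0(sample(c("chr1", "chr2"), n, TRUE),
                           start, start + sample.int(5000, n),
                           sprintf("iv%03d", seq_len(n)),
                           sample(c("+", "-", "."), n, TRUE))
  write_bed(gr2, p)
  back <- read_bed(p)
  expect_equal(as.character(GenomicRanges::seqnames(back)),
               as.character(GenomicRanges::seqnames(gr2)))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr2))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr2))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr2)$name)
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr2)))
})

test_that("coordinate conversion is 0-based half-open at the file boundary", {
  gr <- granges_from_bed0("chr1", 0, 10, "a")
  expect_equal(GenomicRanges::start(gr), 1)
  df <- bed0_from_granges(gr)
  expect_equal(df$start, 0)
  expect_equal(df$end, 10)
  expect_error(granges_from_bed0("chr1", 5, 5), "start < end")
  expect_error(granges_from_bed0("chr1", -1, 5), "start < end")
})

test_that("labeled matrices round-trip and validate labels", {
  m <- matrix(rnorm(4000), 100, 40,
              dimnames = list(sprintf("f%03d", 1:100),
                              sprintf("s%02d", 1:40)))
  lab <- setNames(rep(c("cancer", "normal"), each = 20), colnames(m))
  lm <- labeled_matrix(m, lab)
  p <- tempfile(); pl <- tempfile()
  write_matrix(lm, p, pl)
  back <- read_matrix(p, pl)
  expect_equal(back$values, lm$values, tolerance = 1e-12)
  expect_equal(back$sample_labels, lm$sample_labels)
  expect_equal(ncol(class_values(back, "cancer")), 20)

  expect_error(labeled_matrix(m, lab[1:10]), "missing from labels")
  expect_error(labeled_matrix(m, setNames(rep("x", 40), colnames(m))),
               "cancer")
  m2 <- m; rownames(m2)[2] <- rownames(m2)[1]
  expect_error(labeled_matrix(m2, lab), "duplicated")
})

test_that("JASPAR PWMs parse, validate and round-trip", {
  p <- tempfile()
  writeLines(c(
    ">MA0001.1 TFX",
    "A [ 4 19  0  0 ]",
    "C [16  0 20  0 ]",
    "G [ 0  1  0 20 ]",
    "T [ 0  0  0  0 ]"
  ), p)
  pwms <- read_jaspar(p)
  expect_named(pwms, "MA0001.1")
  expect_equal(ncol(pwms[[1]]$counts), 4)
  expect_equal(unname(pwms[[1]]$counts["C", 1]), 16)
  probs <- pwm_probs(pwms[[1]])
  expect_true(all(abs(colSums(probs) - 1) < 1e-6))

  # round trip
  p2 <- tempfile()
  write_jaspar(pwms, p2)
  again <- read_jaspar(p2)
  expect_equal(again[[1]]$counts, pwms[[1]]$counts)

  writeLines(c(">M1", "A [1 2]", "C [1 2]", "G [1 2]", "T [1]"), p)
  expect_error(read_jaspar(p), "ragged")
  expect_error(new_pwm("x", matrix(1, 4, 3)), "length")
  expect_error(new_pwm("x", matrix(-1, 4, 6)), "nonnegative")
})

test_that("FASTA extraction follows the half-open convention", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">s", "ACGT"), p)
  g <- read_fasta(p)
  expect_equal(extract_sequences(g, granges_from_bed0("s", 1, 3)), "CG")
  expect_equal(extract_sequences(g, granges_from_bed0("s", 0, 4)), "ACGT")
  expect_error(extract_sequences(g, granges_from_bed0("s", 2, 9)), "bounds")
  expect_error(extract_sequences(g, granges_from_bed0("zz", 0, 2)), "absent")
})

test_that("BEDPE round-trips and validates", {
  set.seed(15)
  n <- 200
  s1 <- sample.int(1e5, n); s2 <- sample.int(1e5, n)
  ct <- list(anchor1 = granges_from_bed0(rep("chr1", n), s1, s1 + 500),
             anchor2 = granges_from_bed0(rep("chr2", n), s2, s2 + 500),
             name = sprintf("c%03d", 1:n))
  p <- tempfile(fileext = ".bedpe")
  write_bedpe(ct, p)
  back <- read_bedpe(p)
  expect_equal(GenomicRanges::start(back$anchor1),
               GenomicRanges::start(ct$anchor1))
  expect_equal(GenomicRanges::end(back$anchor2),
               GenomicRanges::end(ct$anchor2))
  expect_equal(back$name, ct$name)
  writeLines("chr1\t1\t2\tchr2\t5\t4\tx", p)
  expect_error(read_bedpe(p), "line 1")
})

test_that("SEG and PPI tables parse with required columns", {
  p <- tempfile()
  data.table::fwrite(data.frame(sample = "s1", chrom = "chr1", start = 0,
                                end = 100, log2ratio = 1.2), p, sep = "\t")
  seg <- read_seg(p)
  expect_equal(seg$log2ratio, 1.2)
  data.table::fwrite(data.frame(a = 1), p, sep = "\t")
  expect_error(read_seg(p), "columns")

  data.table::fwrite(data.frame(tf_a = "T1", tf_b = "T2", dataset = "huri"),
                     p, sep = "\t")
  expect_equal(nrow(read_ppi(p)), 1)
})

test_that("promoter windows are TSS +/- halfwidth, strand-aware, clipped", {
  tss <- granges_from_bed0(c("chr1", "chr1"), c(5000, 100), c(5001, 101),
                           c("g1", "g2"), c("+", "-"))
  pr <- promoter_windows(tss, 3000, c(chr1 = 7000))
  # plus strand: [tss-3000, tss+3000] around the 1-based TSS
  expect_equal(GenomicRanges::start(pr)[1], 2001)
  expect_equal(GenomicRanges::end(pr)[1], 7000)   # clipped at chrom end
  expect_equal(GenomicRanges::start(pr)[2], 1)    # clipped at chrom start
})
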