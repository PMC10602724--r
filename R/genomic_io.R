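## Readers/writers for the standard formats the pipeline touches.
## Convention: every file-facing coordinate is 0-based half-open (BED-style);
## in memory intervals live in GenomicRanges (1-based closed), and the two
## functions granges_from_bed0 / bed0_from_granges are the single conversion
## point. Readers validate and reject malformed records; they never repair.

read_text_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Convert 0-based half-open coordinates to a GRanges
#'
#' The single conversion utility between file coordinates (BED-style, 0-based
#' half-open) and in-memory `GRanges` (1-based closed).
#' @param chrom,start,end,name,strand Parallel vectors; `start`/`end` 0-based
#'   half-open.
#' @return A `GRanges` with a `name` metadata column.
#' @export
granges_from_bed0 <- function(chrom, start, end, name = NULL, strand = NULL) {
  bad <- which(!(start >= 0 & end > start))
  if (length(bad) > 0) {
    stopf("invalid interval (need 0 <= start < end) at record %d: %s:%s-%s",
          bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]])
  }
  strand <- strand %||% rep("*", length(chrom))
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$name <- name %||%
    (if (length(gr) == 0) character(0) else paste0("iv", seq_along(gr)))
  gr
}

#' @rdname granges_from_bed0
#' @param gr A `GRanges`.
#' @return For `bed0_from_granges`, a data.frame with 0-based half-open
#'   `start`/`end`.
#' @export
bed0_from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name
           else paste0("iv", seq_along(gr)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

#' Read/write BED intervals
#'
#' BED3-BED6 dialect; `track`/`browser` lines are skipped. Malformed records
#' (start >= end, negative coordinates, too few columns) raise an error
#' naming the line.
#'
#' @param path File path (gzip transparently supported for reading).
#' @return `read_bed`: a `GRanges` with `name` (and `score` when present)
#'   metadata columns.
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(granges_from_bed0(character(), numeric(), numeric())[0])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stopf("BED line %d has %d field(s); need >= 3", lineno[which(nf < 3)[1]],
          min(nf))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stopf("BED line %d: invalid coordinates '%s'", lineno[bad[1]],
          lines[bad[1]])
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4] %||% NA, ""), NA)
  if (all(is.na(name))) name <- NULL
  strand <- ifelse(nf >= 6, vapply(fields, function(f)
    if (length(f) >= 6) f[6] else ".", ""), ".")
  if (!all(strand %in% c("+", "-", ".", "*"))) {
    stopf("BED line %d: invalid strand", lineno[which(!strand %in%
          c("+", "-", ".", "*"))[1]])
  }
  gr <- granges_from_bed0(chrom, start, end, name, strand)
  if (any(nf >= 5)) {
    S4Vectors::mcols(gr)$score <-
      suppressWarnings(as.numeric(vapply(fields, function(f)
        if (length(f) >= 5) f[5] else NA_character_, "")))
  }
  gr
}

#' @rdname read_bed
#' @param intervals A `GRanges` (as from [read_bed()]).
#' @export
write_bed <- function(intervals, path) {
  df <- bed0_from_granges(intervals)
  score <- S4Vectors::mcols(intervals)$score
  df$score <- if (is.null(score)) 0 else score
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A sample-labeled expression/methylation matrix
#'
#' @param values Numeric matrix, rows = features, columns = samples (both
#'   dimnames required, no duplicates).
#' @param sample_labels Named character vector mapping every column to
#'   `"cancer"` or `"normal"`.
#' @return An object of class `labeled_matrix` (list with `values`,
#'   `sample_labels`).
#' @export
labeled_matrix <- function(values, sample_labels) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("matrix needs row and column names")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicated row id: %s",
          rownames(values)[anyDuplicated(rownames(values))])
  }
  if (anyDuplicated(colnames(values))) stopf("duplicated sample id")
  missing_lab <- setdiff(colnames(values), names(sample_labels))
  if (length(missing_lab) > 0) {
    stopf("samples missing from labels: %s",
          paste(missing_lab, collapse = ", "))
  }
  sample_labels <- sample_labels[colnames(values)]
  if (!all(sample_labels %in% c("cancer", "normal"))) {
    stopf("labels must be 'cancer' or 'normal'")
  }
  structure(list(values = values, sample_labels = sample_labels),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d features x %d samples (%d cancer, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_labels == "cancer"),
              sum(x$sample_labels == "normal")))
  invisible(x)
}

#' Columns of a labeled matrix belonging to one class
#' @param lm A `labeled_matrix`.
#' @param label `"cancer"` or `"normal"`.
#' @return Numeric matrix restricted to that class.
#' @export
class_values <- function(lm, label) {
  lm$values[, lm$sample_labels == label, drop = FALSE]
}

#' Read a feature x sample TSV matrix with sample labels
#'
#' @param path TSV with a header of sample ids; column 1 holds feature ids.
#' @param label_path TSV with columns `sample`, `label` (cancer/normal).
#' @return A [labeled_matrix()].
#' @export
read_matrix <- function(path, label_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stopf("duplicated row id in %s: %s", path, ids[anyDuplicated(ids)])
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  lab <- data.table::fread(label_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  labels <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  labeled_matrix(m, labels)
}

#' @rdname read_matrix
#' @param lm A `labeled_matrix` to write.
#' @export
write_matrix <- function(lm, path, label_path = NULL) {
  df <- data.frame(feature_id = rownames(lm$values), lm$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  if (!is.null(label_path)) {
    data.table::fwrite(data.frame(sample = names(lm$sample_labels),
                                  label = unname(lm$sample_labels)),
                       label_path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Position weight matrix
#'
#' @param motif_id Identifier.
#' @param counts 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities; L >= 4.
#' @param background Length-4 background probabilities (sum 1).
#' @param pseudocount Positive scalar added (scaled by background) before
#'   normalization.
#' @return Object of class `pwm`.
#' @export
new_pwm <- function(motif_id, counts, background = rep(0.25, 4),
                    pseudocount = 0.1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("PWM %s: need 4 rows (A,C,G,T)", motif_id)
  if (ncol(counts) < 4) stopf("PWM %s: length %d < 4", motif_id, ncol(counts))
  if (any(counts < 0) || any(!is.finite(counts))) {
    stopf("PWM %s: counts must be finite and nonnegative", motif_id)
  }
  if (abs(sum(background) - 1) > 1e-6 || any(background < 0)) {
    stopf("PWM %s: background must be a probability 4-vector", motif_id)
  }
  if (pseudocount <= 0) stopf("PWM %s: pseudocount must be positive", motif_id)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, counts = counts,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' Column probabilities of a PWM (pseudocount-regularized)
#' @param pwm A [new_pwm()] object.
#' @return 4 x L matrix whose columns sum to 1.
#' @export
pwm_probs <- function(pwm) {
  cs <- colSums(pwm$counts)
  probs <- sweep(pwm$counts + pwm$pseudocount * pwm$background, 2,
                 cs + pwm$pseudocount, "/")
  stopifnot(all(abs(colSums(probs) - 1) < 1e-6))
  probs
}

#' Read JASPAR-format PWMs
#'
#' Parses JASPAR 2016+ text: a `>ID name` header followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @param path JASPAR text file.
#' @inheritParams new_pwm
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stopf("no JASPAR records in %s", path)
  pwms <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    body <- lines[from:to]
    if (length(body) != 4) {
      stopf("JASPAR record %d in %s: expected 4 matrix rows, found %d",
            i, path, length(body))
    }
    hdr <- sub("^>", "", lines[heads[i]])
    motif_id <- strsplit(trimws(hdr), "[ \t]+")[[1]][1]
    rows <- lapply(body, function(l) {
      base <- sub("^\\s*([ACGT]).*$", "\\1", l)
      nums <- gsub("[^0-9eE.+-]", " ", sub("^\\s*[ACGT]", "", l))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) stopf("JASPAR record %s: unparseable row '%s'",
                             motif_id, l)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stopf("JASPAR record %s: rows must cover A,C,G,T", motif_id)
    }
    lens <- vapply(rows, function(r) length(r$vals), 1L)
    if (length(unique(lens)) != 1) {
      stopf("JASPAR record %s: ragged rows (lengths %s)", motif_id,
            paste(lens, collapse = ","))
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    pwms[[motif_id]] <- new_pwm(motif_id, counts, background, pseudocount)
  }
  pwms
}

#' Write PWMs in JASPAR text format
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$motif_id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write BEDPE contact anchor pairs
#'
#' @param path BEDPE file (>= 6 columns, 0-based half-open anchors).
#' @return `read_bedpe`: list with `anchor1`, `anchor2` (`GRanges` of equal
#'   length) and `name` vector.
#' @export
read_bedpe <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    empty <- granges_from_bed0(character(), numeric(), numeric())[0]
    return(list(anchor1 = empty, anchor2 = empty, name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stopf("BEDPE line %d has %d field(s); need >= 6",
          lineno[which(nf < 6)[1]], min(nf))
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[`, "", k)))
  chr1 <- vapply(fields, `[`, "", 1); s1 <- num(2); e1 <- num(3)
  chr2 <- vapply(fields, `[`, "", 4); s2 <- num(5); e2 <- num(6)
  bad <- which(!is.finite(s1) | !is.finite(e1) | !is.finite(s2) |
                 !is.finite(e2) | s1 < 0 | s2 < 0 | s1 >= e1 | s2 >= e2)
  if (length(bad) > 0) {
    stopf("BEDPE line %d: invalid coordinates", lineno[bad[1]])
  }
  name <- if (any(nf >= 7)) vapply(fields, function(f)
    if (length(f) >= 7) f[7] else NA_character_, "") else
      paste0("contact", seq_along(lines))
  list(anchor1 = granges_from_bed0(chr1, s1, e1, name),
       anchor2 = granges_from_bed0(chr2, s2, e2, name),
       name = name)
}

#' @rdname read_bedpe
#' @param contacts List as returned by `read_bedpe`.
#' @export
write_bedpe <- function(contacts, path) {
  a <- bed0_from_granges(contacts$anchor1)
  b <- bed0_from_granges(contacts$anchor2)
  df <- data.frame(a$chrom, a$start, a$end, b$chrom, b$start, b$end,
                   contacts$name %||% a$name, 0, ".", ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SEG-like per-sample CNV segment table
#'
#' Expected columns: `sample`, `chrom`, `start`, `end`, `log2ratio`
#' (0-based half-open coordinates).
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_seg <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample", "chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(df))) {
    stopf("SEG file %s must have columns: %s", path,
          paste(need, collapse = ", "))
  }
  bad <- which(!(df$start >= 0 & df$end > df$start))
  if (length(bad) > 0) stopf("SEG record %d: invalid coordinates", bad[1])
  df[, need]
}

#' Read a genome FASTA into an indexed sequence store
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet` keyed by chromosome name.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Extract sequences for 0-based half-open intervals
#'
#' @param genome A `DNAStringSet` from [read_fasta()].
#' @param gr A `GRanges` (1-based, as used in memory).
#' @return Character vector of sequences (plus-strand orientation).
#' @export
extract_sequences <- function(genome, gr) {
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown) > 0) {
    stopf("chromosome(s) absent from genome: %s",
          paste(unknown, collapse = ", "))
  }
  vapply(seq_along(gr), function(i) {
    len <- length(genome[[chroms[i]]])
    s <- GenomicRanges::start(gr)[i]
    e <- GenomicRanges::end(gr)[i]
    if (s < 1 || e > len) {
      stopf("interval %s:%d-%d outside chromosome bounds (len %d)",
            chroms[i], s, e, len)
    }
    as.character(Biostrings::subseq(genome[[chroms[i]]], s, e))
  }, "")
}

#' Read protein-protein interaction edges
#'
#' @param path TSV with columns `tf_a`, `tf_b`, `dataset` (the source
#'   interactome each edge was observed in).
#' @return data.frame of edges.
#' @export
read_ppi <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("tf_a", "tf_b", "dataset")
  if (!all(need %in% names(df))) {
    stopf("PPI file %s must have columns: %s", path,
          paste(need, collapse = ", "))
  }
  df[, need]
}

#' Promoter windows around annotated TSSs
#'
#' Promoter = TSS +/- `halfwidth` bp, computed strand-aware from the
#' annotated TSS position, clipped at chromosome bounds.
#'
#' @param tss `GRanges` of TSS positions (width-1 intervals; for minus-strand
#'   records the TSS is taken at the interval end).
#' @param halfwidth Window half-width in bp (default 3000).
#' @param seqlens Optional named vector of chromosome lengths for clipping.
#' @return `GRanges` of promoter windows carrying the gene `name`.
#' @export
promoter_windows <- function(tss, halfwidth = 3000, seqlens = NULL) {
  strand <- as.character(GenomicRanges::strand(tss))
  pos <- ifelse(strand == "-", GenomicRanges::end(tss),
                GenomicRanges::start(tss))
  start <- pmax(1, pos - halfwidth)
  end <- pos + halfwidth
  if (!is.null(seqlens)) {
    lens <- seqlens[as.character(GenomicRanges::seqnames(tss))]
    end <- pmin(end, lens)
  }
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(tss),
                               IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$name <- S4Vectors::mcols(tss)$name
  gr
}
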