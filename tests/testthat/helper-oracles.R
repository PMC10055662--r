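# Independent dynamic-programming oracles and small fixture builders.

# full-matrix Levenshtein, independent of the compiled implementation
oracle_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (x[i] != y[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[n + 1, m + 1]
}

# full-matrix global alignment score oracle
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  s <- matrix(0L, n + 1, m + 1)
  s[, 1] <- (0:n) * gap
  s[1, ] <- (0:m) * gap
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- if (x[i] == y[j] && x[i] != "N") match else mismatch
    s[i + 1, j + 1] <- max(s[i, j] + sc, s[i, j + 1] + gap, s[i + 1, j] + gap)
  }
  s[n + 1, m + 1]
}

# all strings over an alphabet up to a length (including "")
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

random_kmers <- function(n, lens, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(lens, 1), replace = TRUE),
          collapse = "")
  }, "")
}

# minimal GTF writer for test genes: exons is a list of per-transcript
# two-column matrices (1-based inclusive)
write_test_gtf <- function(path, gene_id, transcripts, chrom = "chr1",
                           strand = "+") {
  lines <- character(0)
  for (tx in names(transcripts)) {
    ex <- transcripts[[tx]]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tt\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        chrom, ex[i, 1], ex[i, 2], strand, gene_id, tx))
    }
  }
  writeLines(lines, path)
  path
}

# minimal SAM writer: records is a data.frame with read_id, pos (1-based),
# cigar, seq
write_test_sam <- function(path, records, chrom = "chr1", chrom_len = 10000L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)),
             con)
  for (i in seq_len(nrow(records))) {
    writeLines(paste(records$read_id[i], 0L, chrom, records$pos[i], 60L,
                     records$cigar[i], "*", 0L, 0L, records$seq[i], "*",
                     sep = "\t"), con)
  }
  path
}
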