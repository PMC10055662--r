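#' @useDynLib longsplice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate coef complete.cases dbeta integrate lm
#'   median optim p.adjust pbeta qbeta qchisq qnorm quantile rbeta rbinom
#'   rnbinom rpois runif sd setNames var
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over A,C,G,T,N.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

## ---- isoform chain helpers -------------------------------------------------
## A read/molecule isoform is the chain c(start, splice sites..., end); its
## even-length coordinate vector defines the exonic blocks (0-based half-open).

#' Build an isoform key from coordinates
#' @param start,end genomic span (0-based half-open).
#' @param sites numeric vector of internal splice-site coordinates.
#' @return Single string key, coordinates comma-separated.
#' @keywords internal
iso_key <- function(start, end, sites = numeric(0)) {
  paste(c(start, sites, end), collapse = ",")
}

#' Exonic blocks of an isoform key
#' @param key isoform key string.
#' @return Two-column matrix of block start/end (0-based half-open).
#' @keywords internal
iso_blocks <- function(key) {
  v <- as.numeric(strsplit(key, ",", fixed = TRUE)[[1]])
  matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("start", "end")))
}

iso_span <- function(key) {
  b <- iso_blocks(key)
  c(b[1, 1], b[nrow(b), 2])
}

## ---- GTF parsing -----------------------------------------------------------

#' Decompose gene annotation into disjoint sub-exons
#'
#' Reads a Gencode-style GTF and, for every gene, cuts the union of all
#' annotated exons at every annotated exon boundary, producing the maximal
#' disjoint sub-exon intervals that downstream inclusion counting uses as
#' atomic units. Coordinates are converted to 0-based half-open on ingest.
#'
#' @param gtf_path path to a GTF file with exon features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @return Named list (by gene_id) of sub-exon tables. Each element is a
#'   list with `gene_id`, `chrom`, `strand`, `subexons` (data.frame with
#'   0-based half-open `start`/`end`, sorted, pairwise disjoint) and
#'   `transcripts` (named list of per-transcript exon data.frames).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'   'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'   'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
#'   'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'
#' ), gtf)
#' ann <- parse_gtf_subexons(gtf)
#' ann$g1$subexons
#' @export
parse_gtf_subexons <- function(gtf_path) {
  if (!file.exists(gtf_path)) {
    stop("GTF file not found: ", gtf_path)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    warning("no exon features in ", gtf_path)
    return(structure(list(), class = "subexon_annotation"))
  }
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    tx_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GTF is 1-based inclusive; convert to 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$gene_id), function(g) {
    bounds <- sort(unique(c(g$start, g$end)))
    # candidate intervals between consecutive boundaries, kept if exonic
    cand <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    exonic <- vapply(seq_len(nrow(cand)), function(i) {
      any(g$start <= cand$start[i] & g$end >= cand$end[i])
    }, logical(1))
    txs <- lapply(split(g[, c("start", "end")], g$tx_id), function(t) {
      t[order(t$start), , drop = FALSE]
    })
    list(
      gene_id = g$gene_id[1],
      chrom = g$chrom[1],
      strand = g$strand[1],
      subexons = cand[exonic, , drop = FALSE],
      transcripts = txs
    )
  })
  structure(out, class = "subexon_annotation")
}

## ---- polyA detection -------------------------------------------------------

#' Detect a polyA (or polyT) tract in a softclip
#'
#' Slides a fixed window (step 1 nt) from the transcript-proximal end of
#' the sequence and reports a hit when strictly more than `min_base` of
#' one window are A (or T, for the reverse orientation). The reported end
#' position is the last base of the first contiguous run of qualifying
#' windows, i.e. where barcode-bearing sequence can resume.
#'
#' @param seq nucleotide string (transcript-proximal end first).
#' @param window window width in nt (default 20).
#' @param min_base strict lower threshold on A or T per window
#'   (default 15: a window qualifies with more than 15).
#' @return List with `found` (logical) and `end` (1-based position of the
#'   last base of the detected tract, or `NA`).
#' @examples
#' detect_polyA(paste0(strrep("A", 16), "CGCG"))$found  # TRUE
#' detect_polyA(paste0(strrep("A", 15), "CCCCC"))$found # FALSE
#' @export
detect_polyA <- function(seq, window = 20L, min_base = 15L) {
  n <- nchar(seq)
  if (is.na(seq) || n < window) {
    return(list(found = FALSE, end = NA_integer_))
  }
  ch <- strsplit(seq, "")[[1]]
  isA <- cumsum(c(0L, ch == "A"))
  isT <- cumsum(c(0L, ch == "T"))
  starts <- seq_len(n - window + 1L)
  nA <- isA[starts + window] - isA[starts]
  nT <- isT[starts + window] - isT[starts]
  hit <- nA > min_base | nT > min_base
  if (!any(hit)) {
    return(list(found = FALSE, end = NA_integer_))
  }
  first <- which(hit)[1]
  # extend through the first contiguous run of qualifying windows
  run_end <- first
  while (run_end < length(hit) && hit[run_end + 1L]) run_end <- run_end + 1L
  list(found = TRUE, end = run_end + window - 1L)
}

## ---- BAM ingestion ---------------------------------------------------------

#' Chemistry configuration for barcoded long reads
#'
#' @param end `"5p"` (barcode and UMI on the 5' adapter side, 10x 5' kits)
#'   or `"3p"` (barcode after the polyA tail).
#' @param bc_len cell/spot barcode length in nt.
#' @param umi_len UMI length in nt.
#' @param softclip_retain how many transcript-proximal nt of the
#'   barcode-side softclip to retain (default 55).
#' @return A list of class `chemistry`.
#' @export
chemistry_config <- function(end = c("5p", "3p"), bc_len = 16L, umi_len = 10L,
                             softclip_retain = 55L) {
  end <- match.arg(end)
  structure(list(end = end, bc_len = as.integer(bc_len),
                 umi_len = as.integer(umi_len),
                 softclip_retain = as.integer(softclip_retain)),
            class = "chemistry")
}

#' Extract read records from a BAM of spliced alignments
#'
#' Converts every primary, mapped alignment that overlaps an annotated
#' gene into one read record: genomic span, internal splice sites (from N
#' CIGAR operations), retained barcode-side softclip segment and polyA
#' flag. Gene assignment is by maximal exonic overlap with the sub-exon
#' annotation; ties break first by strand agreement, then lexicographic
#' gene id. Softclips must be present in the BAM (no hard clipping of the
#' adapter side).
#'
#' For 5' chemistry the transcript-proximal `softclip_retain` nt of the
#' 5' clip are kept (after reverse complementing minus-strand alignments,
#' so all retained clips read adapter to barcode to transcript). For 3'
#' chemistry the polyA tract is located on the 3' clip first and the
#' segment after it is kept, reverse complemented into the same
#' adapter-to-barcode orientation.
#'
#' @param bam_path path to an indexed or unindexed BAM.
#' @param annotation result of [parse_gtf_subexons()].
#' @param chemistry a [chemistry_config()].
#' @return data.frame with one row per assigned read: `read_id`,
#'   `gene_id`, `start`, `end` (0-based half-open), `splice_sites`
#'   (comma-separated internal coordinates), `strand`, `bc_clip`
#'   (retained barcode-side softclip, adapter->transcript orientation),
#'   `clip3` (transcript-distal clip), `polyA` (logical) and
#'   `unassignable` (TRUE when the barcode-side clip was absent).
#' @export
extract_reads <- function(bam_path, annotation, chemistry = chemistry_config()) {
  stopifnot(inherits(annotation, "subexon_annotation"))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param, use.names = FALSE)
  if (length(aln) == 0) {
    return(empty_reads_df())
  }

  cig <- GenomicAlignments::cigar(aln)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  lead_clip <- mapply(function(o, l) if (length(o) && o[1] == "S") l[1] else 0L,
                      ops, lens)
  trail_clip <- mapply(function(o, l) {
    n <- length(o)
    if (n && o[n] == "S") l[n] else 0L
  }, ops, lens)
  seqs <- as.character(S4Vectors::mcols(aln)$seq)
  seqlen <- nchar(seqs)
  lead_seq <- substr(seqs, 1L, lead_clip)
  trail_seq <- substr(seqs, seqlen - trail_clip + 1L, seqlen)
  minus <- as.character(GenomicAlignments::strand(aln)) == "-"

  # clip on the read's 5' side, oriented adapter -> transcript
  clip5 <- ifelse(minus, revcomp(trail_seq), lead_seq)
  # clip on the read's 3' side, oriented transcript -> adapter
  clip3 <- ifelse(minus, revcomp(lead_seq), trail_seq)

  # gene assignment by maximal exonic overlap
  sub_gr <- annotation_granges(annotation)
  blocks <- GenomicAlignments::grglist(aln)
  hits <- GenomicRanges::findOverlaps(blocks, sub_gr, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(empty_reads_df())
  }
  # exonic overlap per (read, gene) using block-level intersection
  ovdf <- overlap_by_gene(blocks, sub_gr, hits)
  gene_strand <- vapply(annotation, function(g) g$strand, "")
  read_strand <- ifelse(minus, "-", "+")
  ovdf$strand_match <- gene_strand[ovdf$gene_id] == read_strand[ovdf$read]
  ord <- order(ovdf$read, -ovdf$width, -ovdf$strand_match, ovdf$gene_id)
  ovdf <- ovdf[ord, ]
  ovdf <- ovdf[!duplicated(ovdf$read), ]

  idx <- ovdf$read
  jx <- GenomicAlignments::junctions(aln)
  sites <- rep("", length(aln))
  nj <- S4Vectors::elementNROWS(jx)
  if (any(nj > 0)) {
    ul <- unlist(jx, use.names = FALSE)
    grp <- rep(seq_along(jx), nj)
    # intron [a,b] 1-based -> internal sites a-1 and b (0-based half-open)
    per_j <- paste(GenomicRanges::start(ul) - 1L, GenomicRanges::end(ul),
                   sep = ",")
    agg <- tapply(per_j, grp, paste, collapse = ",")
    sites[as.integer(names(agg))] <- agg
  }

  chem <- chemistry
  polyA <- logical(length(idx))
  bc_clip <- character(length(idx))
  clip3_out <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    pa <- detect_polyA(clip3[i])
    polyA[k] <- pa$found
    if (chem$end == "5p") {
      bc_clip[k] <- retain_proximal(clip5[i], chem$softclip_retain)
      clip3_out[k] <- substr(clip3[i], 1L, chem$softclip_retain)
    } else {
      seg <- if (pa$found) substr(clip3[i], pa$end + 1L, nchar(clip3[i])) else ""
      seg <- substr(seg, 1L, chem$softclip_retain)
      bc_clip[k] <- revcomp(seg)
      clip3_out[k] <- retain_proximal(clip5[i], chem$softclip_retain)
    }
  }

  data.frame(
    read_id = S4Vectors::mcols(aln)$qname[idx],
    gene_id = ovdf$gene_id,
    start = GenomicAlignments::start(aln)[idx] - 1L,
    end = GenomicAlignments::end(aln)[idx],
    splice_sites = sites[idx],
    strand = read_strand[idx],
    bc_clip = bc_clip,
    clip3 = clip3_out,
    polyA = polyA,
    unassignable = nchar(bc_clip) == 0L,
    stringsAsFactors = FALSE
  )
}

# transcript-proximal `n` nt of an adapter->transcript oriented clip
retain_proximal <- function(clip, n) {
  L <- nchar(clip)
  if (L <= n) clip else substr(clip, L - n + 1L, L)
}

empty_reads_df <- function() {
  data.frame(read_id = character(0), gene_id = character(0),
             start = integer(0), end = integer(0),
             splice_sites = character(0), strand = character(0),
             bc_clip = character(0), clip3 = character(0),
             polyA = logical(0), unassignable = logical(0),
             stringsAsFactors = FALSE)
}

annotation_granges <- function(annotation) {
  dfs <- lapply(annotation, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = g$subexons$start, end = g$subexons$end,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, dfs)
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  gr$gene_id <- all$gene_id
  gr
}

overlap_by_gene <- function(blocks, sub_gr, hits = NULL) {
  # exonic overlap width per (read, gene): overlap every aligned block
  # with every subexon, vectorized
  unl <- unlist(blocks, use.names = FALSE)
  read_of <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  h <- GenomicRanges::findOverlaps(unl, sub_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(h)
  sh <- S4Vectors::subjectHits(h)
  ov <- pmin(GenomicRanges::end(unl)[qh], GenomicRanges::end(sub_gr)[sh]) -
    pmax(GenomicRanges::start(unl)[qh], GenomicRanges::start(sub_gr)[sh]) + 1L
  df <- data.frame(read = read_of[qh], gene_id = sub_gr$gene_id[sh],
                   width = ov, stringsAsFactors = FALSE)
  aggregate(width ~ read + gene_id, data = df, FUN = sum)
}

## ---- splice-site support filter -------------------------------------------

#' Filter reads carrying weakly supported splice sites
#'
#' Splice sites are counted per gene across all reads (donor and acceptor
#' of a junction are two site keys at distinct coordinates; each site is
#' counted once per read). Reads containing any site observed fewer than
#' `min_count` times are removed — such sites are typically alignment
#' artifacts of high-error reads.
#'
#' @param reads data.frame from [extract_reads()].
#' @param min_count minimum per-gene occurrence for a splice site
#'   (default 10).
#' @return The filtered data.frame (subset of the input rows).
#' @export
filter_reads_by_splice_support <- function(reads, min_count = 10L) {
  if (nrow(reads) == 0 || min_count <= 1L) return(reads)
  keep <- logical(nrow(reads))
  for (g in unique(reads$gene_id)) {
    i <- which(reads$gene_id == g)
    site_list <- strsplit(reads$splice_sites[i], ",", fixed = TRUE)
    site_list <- lapply(site_list, function(s) s[nzchar(s)])
    counts <- table(unlist(site_list))
    ok <- vapply(site_list, function(s) {
      length(s) == 0 || all(counts[s] >= min_count)
    }, logical(1))
    keep[i] <- ok
  }
  reads[keep, , drop = FALSE]
}
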