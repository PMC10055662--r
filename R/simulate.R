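## Synthetic data with ground truth.
##
## Emulates the generative process the pipeline is built for: random true
## UMIs amplified with negative-binomial PCR folds, per-base
## substitution/insertion/deletion errors, 5' truncation, mis-mapping of
## a short middle exon, and cell populations with Beta-distributed psi.
## Every emitted read is traceable to a truth record.

ADAPTER_R1 <- "CTACACGACGCTCTTCCGATCT"   # Illumina TruSeq R1, barcode side
TSO_SEQ <- "TTTCTTATATGGG"               # template-switch oligo stub

#' Per-base sequencing error model
#'
#' Default rates (1.5% substitution, 1.5% insertion, 1.5% deletion)
#' correspond to roughly 95% per-base accuracy, the upper end of the
#' accuracy range of current Nanopore basecallers; they put almost all
#' corrupted 10-mers within edit distance 2 of their source. Rates are
#' configurable and [calibrate_error_model()] can fit them to a target
#' edit-distance histogram.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities.
#' @return List of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.015, ins_rate = 0.015, del_rate = 0.015) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate),
            class = "error_model")
}

#' Corrupt sequences under an error model
#' @param seqs character vector.
#' @param model an [error_model()].
#' @return Character vector of corrupted sequences (lengths may change).
#' @export
corrupt <- function(seqs, model = error_model()) {
  corrupt_seqs(seqs, model$sub_rate, model$ins_rate, model$del_rate)
}

#' Random distinct nucleotide strings
#' @param n count.
#' @param len length in nt.
#' @return Character vector of `n` distinct strings.
#' @export
random_seqs <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

# rejection-sample n strings whose pairwise edit distance is >= min_d
random_seqs_min_dist <- function(n, len, min_d, max_tries = 10000L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    cand <- paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
    tries <- tries + 1L
    if (length(out) == 0 ||
        min(edit_distance_to_ref(out, cand)) >= min_d) {
      out <- c(out, cand)
    }
  }
  if (length(out) < n) stop("could not sample ", n, " separated UMIs")
  out
}

#' Simulate an amplified, error-corrupted UMI pool
#'
#' `n_true` distinct UMIs are each amplified `C = 1 + NB(r, p)` times
#' (so the minimum fold is one and `var(C) = (1/p)(mean(C) - 1)`), and
#' every copy is corrupted independently under the error model. The
#' defaults `r = 4, p = 0.5` give a mean amplification fold of 5.
#'
#' @param n_true number of original molecules (2-50 in the crowding
#'   experiments).
#' @param fold_r,fold_p negative-binomial fold parameters.
#' @param error an [error_model()].
#' @param umi_len UMI length (default 10).
#' @param seed RNG seed.
#' @return List with `reads` (corrupted copies), `truth` (list: `umis`,
#'   `folds`, `source` index per read).
#' @export
simulate_umi_pool <- function(n_true, fold_r = 4, fold_p = 0.5,
                              error = error_model(), umi_len = 10L,
                              seed = 1L) {
  set.seed(seed)
  umis <- random_seqs(n_true, umi_len)
  folds <- 1L + rnbinom(n_true, size = fold_r, prob = fold_p)
  source <- rep(seq_len(n_true), folds)
  reads <- corrupt(umis[source], error)
  list(reads = reads,
       truth = list(umis = umis, folds = folds, source = source))
}

#' Fixed-radius UMI clustering baseline
#'
#' Merges UMIs into connected components of the graph linking pairs at
#' edit distance strictly below `radius` (default 2, the common
#' fixed-threshold setting). Used as a comparison baseline: it inflates
#' counts when errors scatter reads beyond the radius and deflates them
#' when distinct UMIs crowd within it.
#'
#' @param windows UMI strings.
#' @param radius strict edit-distance threshold (default 2).
#' @return Integer component ids, one per window.
#' @export
cluster_umis_fixed_radius <- function(windows, radius = 2L) {
  n <- length(windows)
  if (n == 1) return(1L)
  d <- edit_distance_matrix(windows)
  g <- igraph::graph_from_adjacency_matrix(d < radius, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Pipeline molecule-count estimate for a UMI pool
#'
#' Clusters a pool with [cluster_umis()] and prunes scattered small
#' clusters with [scatter_reduce()].
#'
#' @param windows UMI strings.
#' @param model an [amplification_model()].
#' @param umi_len UMI length.
#' @param seed RNG seed for Louvain.
#' @param min_clusters scatter-reduction guard (default 5).
#' @return Integer estimated number of original molecules.
#' @export
estimate_pool_size <- function(windows, model = amplification_model(2),
                               umi_len = 10L, seed = 1L, min_clusters = 5L) {
  mem <- cluster_umis(windows, umi_len = umi_len, seed = seed)
  sizes <- as.integer(table(mem))
  sum(scatter_reduce(sizes, model, min_clusters = min_clusters))
}

#' Calibrate error rates to a target edit-distance histogram
#'
#' Grid search over (sub, ins, del) rates minimising the L1 distance
#' between the simulated and target histograms of edit distances of
#' corrupted `umi_len`-mers from their source.
#'
#' @param target_hist numeric vector of probabilities over edit
#'   distances `0..length(target_hist)-1` (normalised internally).
#' @param umi_len word length (default 10).
#' @param rates candidate per-base rates for each error type.
#' @param n_draws corrupted words per grid point (default 10000).
#' @param seed RNG seed.
#' @return An [error_model()] with attributes `residual` (L1 distance of
#'   the best fit) and `hist` (its simulated histogram).
#' @export
calibrate_error_model <- function(target_hist, umi_len = 10L,
                                  rates = c(0, 0.005, 0.01, 0.02, 0.04, 0.06),
                                  n_draws = 10000L, seed = 1L) {
  target <- target_hist / sum(target_hist)
  nbin <- length(target)
  best <- NULL
  best_l1 <- Inf
  best_hist <- NULL
  set.seed(seed)
  words <- random_seqs(min(n_draws, 1000L), umi_len)
  words <- words[sample.int(length(words), n_draws, replace = TRUE)]
  for (s in rates) for (ii in rates) for (d in rates) {
    set.seed(seed + 1L)
    cor <- corrupt_seqs(words, s, ii, d)
    ed <- vapply(seq_along(words), function(k) {
      edit_distance(cor[k], words[k])
    }, integer(1))
    h <- tabulate(pmin(ed, nbin - 1L) + 1L, nbins = nbin) / n_draws
    l1 <- sum(abs(h - target))
    if (l1 < best_l1) {
      best_l1 <- l1
      best <- c(s, ii, d)
      best_hist <- h
    }
  }
  m <- error_model(best[1], best[2], best[3])
  attr(m, "residual") <- best_l1
  attr(m, "hist") <- best_hist
  m
}

## ---- toy gene + read-level simulation -------------------------------------

#' Default toy gene catalog
#'
#' One gene with four exons, among them a short (60 bp) middle exon
#' present in both real isoforms, and a 150 bp cassette exon that
#' distinguishes them. Mis-mapping is simulated by dropping the short
#' middle exon, which creates chains matching neither real isoform.
#'
#' @return List with `chrom`, `chrom_len`, `gene_id`, `exons` (0-based
#'   half-open), `isoforms` (named chain keys), `short_exon` (index of
#'   the mis-mapping-prone exon), `cassette_exon`.
#' @export
default_catalog <- function() {
  exons <- rbind(c(1000L, 1200L),   # e1
                 c(1400L, 1460L),   # e2, short middle exon
                 c(1550L, 1700L),   # e3, cassette
                 c(1800L, 2100L))   # e4
  chain <- function(idx) {
    b <- exons[idx, , drop = FALSE]
    sites <- as.vector(t(b))[-c(1, 2 * nrow(b))]
    iso_key(b[1, 1], b[nrow(b), 2], sites)
  }
  list(chrom = "chrS", chrom_len = 3000L, gene_id = "geneA",
       exons = exons,
       isoforms = c(a = chain(1:4), b = chain(c(1, 2, 4))),
       short_exon = 2L, cassette_exon = 3L)
}

#' Write the toy catalog as a GTF
#' @param catalog a [default_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_gtf <- function(catalog, path) {
  lines <- character(0)
  for (nm in names(catalog$isoforms)) {
    b <- iso_blocks(catalog$isoforms[[nm]])
    for (i in seq_len(nrow(b))) {
      lines <- c(lines, sprintf(
        "%s\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"t_%s\";",
        catalog$chrom, b[i, 1] + 1L, b[i, 2], catalog$gene_id, nm))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# remove `depth` exonic bases from the genomic-left (5' for +) end
truncate_chain <- function(key, depth, min_keep = 20L) {
  b <- iso_blocks(key)
  total <- sum(b[, 2] - b[, 1])
  depth <- min(depth, total - min_keep)
  if (depth <= 0) return(key)
  i <- 1
  while (depth > 0 && i <= nrow(b)) {
    w <- b[i, 2] - b[i, 1]
    if (depth >= w) {
      depth <- depth - w
      b[i, 1] <- NA
      i <- i + 1
    } else {
      b[i, 1] <- b[i, 1] + depth
      depth <- 0
    }
  }
  b <- b[!is.na(b[, 1]), , drop = FALSE]
  sites <- as.vector(t(b))[-c(1, 2 * nrow(b))]
  iso_key(b[1, 1], b[nrow(b), 2], sites)
}

# drop a designated exon (by its interval) from a chain, if present
drop_exon_from_chain <- function(key, exon) {
  b <- iso_blocks(key)
  hit <- b[, 1] == exon[1] & b[, 2] == exon[2]
  if (!any(hit)) return(key)
  b <- b[!hit, , drop = FALSE]
  if (nrow(b) == 0) return(key)
  sites <- as.vector(t(b))[-c(1, 2 * nrow(b))]
  iso_key(b[1, 1], b[nrow(b), 2], sites)
}

#' Simulate barcoded reads for the toy gene
#'
#' Each cell receives `mols_per_cell` molecules; a molecule is isoform
#' `a` with its cell's probability psi (drawn from `Beta(psi_alpha,
#' psi_beta)`) and isoform `b` otherwise. Each molecule is amplified
#' `1 + NB(fold_r, fold_p)` times; every PCR copy is independently 5'
#' truncated with probability `truncation_prob` (geometric depth, mean
#' `trunc_mean` bases) and mis-mapped with probability `mismap_prob`
#' (the short middle exon is dropped). Softclips are `adapter + barcode
#' + UMI + TSO`, corrupted under the error model; every read carries a
#' polyA tail on the 3' side.
#'
#' @param n_cells number of cells.
#' @param mols_per_cell molecules per cell.
#' @param psi_alpha,psi_beta Beta law of the per-cell inclusion
#'   probability of isoform `a` (default 6, 4: psi around 0.6).
#' @param fold_r,fold_p amplification fold model (defaults give mean 5).
#' @param fold_r_b negative-binomial size for isoform `b` (default
#'   `fold_r`); setting it away from `fold_r` creates isoform-dependent
#'   amplification bias, which inflates raw-read psi estimates and is
#'   what UMI deduplication corrects.
#' @param truncation_prob per-copy 5' truncation probability.
#' @param trunc_mean mean truncation depth in exonic bases.
#' @param mismap_prob per-copy probability of dropping the short exon.
#' @param error an [error_model()] applied to softclips and, at a
#'   reduced per-window rate, implicitly reflected in the mis-mapping
#'   flag (alignment coordinates themselves are emitted clean).
#' @param umi_len,bc_len tag lengths.
#' @param min_umi_dist minimum pairwise edit distance between the UMIs
#'   of one cell (default 0: fully random). Distinct UMIs closer than
#'   the clustering merge radius are not identifiable by any
#'   deduplication method, so exactness checks (zero-error runs that
#'   must reproduce the truth bit for bit) are only well-posed on
#'   separated pools; statistical scenarios should keep the default.
#' @param seed RNG seed.
#' @param catalog a [default_catalog()].
#' @return List with `reads` (data.frame: read_id, cell, chain, clip5,
#'   clip3), `truth` (molecules data.frame: cell, gene_id, isoform, umi,
#'   fold, psi per cell), `whitelist`, `catalog`.
#' @export
simulate_reads <- function(n_cells = 10L, mols_per_cell = 20L,
                           psi_alpha = 6, psi_beta = 4,
                           fold_r = 4, fold_p = 0.5, fold_r_b = fold_r,
                           truncation_prob = 0, trunc_mean = 150,
                           mismap_prob = 0, error = error_model(0, 0, 0),
                           umi_len = 10L, bc_len = 16L, min_umi_dist = 0L,
                           seed = 1L, catalog = default_catalog()) {
  set.seed(seed)
  whitelist <- random_seqs(n_cells, bc_len)
  short_exon <- catalog$exons[catalog$short_exon, ]
  psi_cell <- rbeta(n_cells, psi_alpha, psi_beta)
  n_mol <- n_cells * mols_per_cell
  mol_cell <- rep(seq_len(n_cells), each = mols_per_cell)
  mol_iso <- ifelse(runif(n_mol) < psi_cell[mol_cell], "a", "b")
  mol_umi <- if (min_umi_dist > 0) {
    unlist(lapply(seq_len(n_cells), function(c) {
      random_seqs_min_dist(mols_per_cell, umi_len, min_umi_dist)
    }))
  } else random_seqs(n_mol, umi_len)
  mol_fold <- 1L + rnbinom(n_mol,
                           size = ifelse(mol_iso == "a", fold_r, fold_r_b),
                           prob = fold_p)
  src <- rep(seq_len(n_mol), mol_fold)
  n_read <- length(src)
  chain <- unname(catalog$isoforms[mol_iso[src]])
  mismap <- runif(n_read) < mismap_prob
  trunc <- runif(n_read) < truncation_prob
  for (i in which(mismap)) {
    chain[i] <- drop_exon_from_chain(chain[i], short_exon)
  }
  for (i in which(trunc)) {
    depth <- rgeom(1, 1 / trunc_mean) + 1L
    chain[i] <- truncate_chain(chain[i], depth)
  }
  clip5_clean <- paste0(ADAPTER_R1, whitelist[mol_cell[src]],
                        mol_umi[src], TSO_SEQ)
  clip5 <- corrupt(clip5_clean, error)
  clip3 <- paste0(strrep("A", 30), "GATCGGAAGAGC")
  reads <- data.frame(
    read_id = sprintf("r%06d", seq_len(n_read)),
    cell = whitelist[mol_cell[src]],
    molecule = src,
    chain = chain,
    clip5 = clip5,
    clip3 = clip3,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    cell = whitelist[mol_cell],
    gene_id = catalog$gene_id,
    isoform = unname(catalog$isoforms[mol_iso]),
    iso_name = mol_iso,
    umi = mol_umi,
    fold = mol_fold,
    polyA = TRUE,
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth, psi_cell = psi_cell,
       whitelist = whitelist, catalog = catalog)
}

#' Module-level read table of a simulation
#'
#' Builds the per-read table consumed by [dedup_table()] directly from a
#' [simulate_reads()] result, bypassing the BAM and barcode-matching
#' stages: cells are taken from the truth and the UMI windows (true UMI
#' with one flanking base on each side) are corrupted under the error
#' model. Used to study the deduplication stage in isolation.
#'
#' @param sim result of [simulate_reads()].
#' @param error an [error_model()] applied to the UMI windows.
#' @param seed RNG seed for the window corruption.
#' @return data.frame with `cell`, `gene_id`, `iso`, `umi_window`,
#'   `read_id`, `polyA`, and `molecule` (truth row of the source
#'   molecule).
#' @export
sim_read_table <- function(sim, error = error_model(), seed = 1L) {
  r <- sim$reads
  set.seed(seed)
  win <- corrupt(paste0(substr(r$cell, nchar(r$cell), nchar(r$cell)),
                        sim$truth$umi[r$molecule],
                        substr(TSO_SEQ, 1, 1)), error)
  data.frame(cell = r$cell, gene_id = sim$catalog$gene_id, iso = r$chain,
             umi_window = win, read_id = r$read_id, polyA = TRUE,
             molecule = r$molecule, stringsAsFactors = FALSE)
}

#' Write simulated reads as a SAM file
#'
#' Emits one primary alignment per read on the toy chromosome, with the
#' softclips carried in the SEQ/CIGAR (leading and trailing S
#' operations) exactly as a spliced aligner would leave them.
#'
#' @param sim result of [simulate_reads()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", sim$catalog$chrom,
                       sim$catalog$chrom_len)), con)
  r <- sim$reads
  for (i in seq_len(nrow(r))) {
    b <- iso_blocks(r$chain[i])
    mlens <- b[, 2] - b[, 1]
    cig <- sprintf("%dM", mlens[1])
    if (nrow(b) > 1) {
      for (j in seq(2, nrow(b))) {
        cig <- paste0(cig, sprintf("%dN%dM", b[j, 1] - b[j - 1, 2], mlens[j]))
      }
    }
    cig <- paste0(nchar(r$clip5[i]), "S", cig, nchar(r$clip3[i]), "S")
    body <- strrep("G", sum(mlens))
    seq <- paste0(r$clip5[i], body, r$clip3[i])
    writeLines(paste(r$read_id[i], 0L, sim$catalog$chrom, b[1, 1] + 1L, 60L,
                     cig, "*", 0L, 0L, seq, "*", sep = "\t"), con)
  }
  invisible(path)
}

#' Write a whitelist file
#' @param whitelist barcode vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(whitelist, path) {
  writeLines(whitelist, path)
  invisible(path)
}

#' Truth E/G count matrices of a read simulation
#'
#' Scores the true molecules (true isoform, polyA observed) against the
#' sub-exon annotation with the same censoring rules the pipeline uses,
#' giving the matrices a perfect pipeline run must reproduce.
#'
#' @param sim result of [simulate_reads()].
#' @param annotation [parse_gtf_subexons()] of the catalog GTF.
#' @return data.frame from [build_count_matrices()].
#' @export
truth_counts <- function(sim, annotation) {
  incl <- inclusion_table(sim$truth, annotation)
  build_count_matrices(incl)
}

#' Simulate per-cell exon counts under the Beta-Binomial model
#'
#' psi_c ~ Beta(alpha, beta), G_c from the coverage model, E_c ~
#' Binomial(G_c, psi_c). The dispersion truth is `1/(alpha+beta+1)`.
#'
#' @param n_cells number of cells.
#' @param alpha,beta Beta shape parameters.
#' @param coverage function(n) returning n informative counts (default
#'   `10 + Poisson(10)`).
#' @param seed RNG seed.
#' @return List with `E`, `G`, `psi`, and truth `mu`, `phi`.
#' @export
simulate_cells <- function(n_cells, alpha, beta,
                           coverage = function(n) 10L + rpois(n, 10),
                           seed = 1L) {
  stopifnot(alpha > 0, beta > 0)
  set.seed(seed)
  psi <- rbeta(n_cells, alpha, beta)
  G <- coverage(n_cells)
  E <- rbinom(n_cells, G, psi)
  list(E = E, G = G, psi = psi,
       mu = alpha / (alpha + beta), phi = 1 / (alpha + beta + 1))
}
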