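## End-to-end orchestration: extract -> barcode -> dedup -> quantify
## (-> phi / differential splicing). Stage outputs are plain TSV so every
## intermediate is inspectable; attrition counts (reads in -> barcoded ->
## deduplicated -> retained) are the primary QC signal and are recorded
## in the run manifest.

#' Pipeline configuration
#'
#' Collects all module thresholds with their defaults: splice-site
#' support 10, barcode edit distance 3 (16 nt barcodes) with start-z 3,
#' UMI edge thresholds 5/7 with min-cut stop 3, meta-isoform symmetric
#' difference below 80 nt and middle exons below 80 bp, amplification
#' slope 1.5 when not estimated, coverage filters G >= 10 in more than
#' 30 cells, FDR 0.05.
#'
#' @param bam,gtf,whitelist,out_dir input/output paths (`bam` may be a
#'   SAM file; it is converted on the fly).
#' @param chemistry a [chemistry_config()].
#' @param min_splice_count splice-site support filter.
#' @param max_ed,max_z,confident_ed barcode thresholds
#'   (`max_ed = NULL` uses [default_max_ed()]).
#' @param thresh,max_middle_exon meta-isoform grouping.
#' @param beta `"auto"` (estimate from single-isoform genes), or a
#'   numeric slope.
#' @param default_beta fallback slope when estimation is not possible.
#' @param min_clusters scatter-reduction guard.
#' @param merge do meta-exon merging before counting.
#' @param min_G,min_cells,fdr,n_boot downstream statistics settings.
#' @param groups optional data.frame (`cell`, `group`) or TSV path,
#'   enabling the differential stage.
#' @param seed seed for all stochastic steps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bam, gtf, whitelist, out_dir,
                            chemistry = chemistry_config(),
                            min_splice_count = 10L, max_ed = NULL,
                            max_z = 3, confident_ed = 1L,
                            thresh = 80L, max_middle_exon = 80L,
                            beta = "auto", default_beta = 1.5,
                            min_clusters = 5L, merge = TRUE,
                            min_G = 10L, min_cells = 30L, fdr = 0.05,
                            n_boot = 200L, groups = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

reads_iso_key <- function(reads) {
  vapply(seq_len(nrow(reads)), function(i) {
    sites <- reads$splice_sites[i]
    sites <- if (nzchar(sites)) strsplit(sites, ",", fixed = TRUE)[[1]]
             else character(0)
    paste(c(reads$start[i], sites, reads$end[i]), collapse = ",")
  }, "")
}

#' Deduplicate an assigned read table into molecules
#'
#' Runs meta-isoform grouping and UMI clustering per cell, corrects
#' mis-mapped isoforms with the global attribution table, and prunes
#' scattered clusters per (cell, gene, isoform) under the amplification
#' model. Mapping correction changes isoform labels only, never the
#' molecule count; scatter reduction flags clusters rather than deleting
#' rows.
#'
#' @param reads data.frame from [extract_reads()] (after splice
#'   filtering).
#' @param matches barcode matches from [assign_barcodes()].
#' @param config a [pipeline_config()] (paths unused here).
#' @return data.frame of molecules: `cell`, `gene_id`, `isoform`
#'   (corrected), `umi`, `size`, `polyA`, `retained`.
#' @export
dedup_molecules <- function(reads, matches, config) {
  chem <- config$chemistry
  m <- matches[matches$pass, c("read_id", "barcode", "end_pos")]
  df <- merge(reads, m, by = "read_id")
  if (nrow(df) == 0) return(empty_molecules())
  df$iso <- reads_iso_key(df)
  df$umi_window <- vapply(seq_len(nrow(df)), function(i) {
    extract_umi_window(df$bc_clip[i], df$end_pos[i], chem$umi_len)$window
  }, "")
  df$cell <- df$barcode
  mols <- dedup_table(df, umi_len = chem$umi_len, seed = config$seed,
                      thresh = config$thresh,
                      max_middle_exon = config$max_middle_exon,
                      beta = config$beta,
                      default_beta = config$default_beta,
                      min_clusters = config$min_clusters)
  mols[, c("cell", "gene_id", "isoform", "umi", "size", "polyA", "retained")]
}

empty_molecules <- function() {
  data.frame(cell = character(0), gene_id = character(0),
             isoform = character(0), umi = character(0), size = integer(0),
             polyA = logical(0), retained = logical(0),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the stage tables (`reads`, `matches`,
#'   `molecules`, `counts`, and `phi`/`diff` when enabled) and the
#'   output directory. All tables are also written as TSV under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$bam, config$gtf, config$whitelist)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_counts <- c()

  bam <- config$bam
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(bam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  annotation <- parse_gtf_subexons(config$gtf)
  reads <- extract_reads(bam, annotation, config$chemistry)
  log_counts["reads_in"] <- nrow(reads)
  reads <- filter_reads_by_splice_support(reads, config$min_splice_count)
  log_counts["reads_splice_filtered"] <- nrow(reads)
  write_tsv(reads, out("reads.tsv"))

  whitelist <- read_whitelist(config$whitelist)
  ab <- assign_barcodes(reads[!reads$unassignable, , drop = FALSE], whitelist,
                        max_ed = config$max_ed, max_z = config$max_z,
                        confident_ed = config$confident_ed,
                        softclip_retain = config$chemistry$softclip_retain)
  log_counts["reads_barcoded"] <- sum(ab$matches$pass)
  write_tsv(ab$matches, out("barcodes.tsv"))

  mols <- dedup_molecules(reads, ab$matches, config)
  log_counts["molecules"] <- nrow(mols)
  log_counts["molecules_retained"] <- sum(mols$retained)
  write_tsv(mols, out("molecules.tsv"))

  kept <- mols[mols$retained, , drop = FALSE]
  kept$cell <- as.character(kept$cell)
  incl <- inclusion_table(kept, annotation)
  map <- NULL
  if (isTRUE(config$merge)) {
    mg <- merge_exons(incl, annotation)
    incl <- mg$incl
    map <- mg$map
    write_tsv(map, out("exon_merge_map.tsv"))
  }
  counts <- build_count_matrices(incl)
  write_tsv(counts, out("counts.tsv"))

  res <- list(out_dir = config$out_dir, reads = reads, matches = ab$matches,
              molecules = mols, counts = counts, merge_map = map)

  if (!is.null(config$groups)) {
    groups <- if (is.character(config$groups)) {
      read.delim(config$groups, stringsAsFactors = FALSE)
    } else config$groups
    dd <- diff_splice(counts, groups, min_G = config$min_G,
                      min_cells = config$min_cells, n_boot = config$n_boot,
                      seed = config$seed)
    write_tsv(dd, out("diff_splice.tsv"))
    res$diff <- dd
  } else {
    phi <- estimate_phi_table(counts, min_G = config$min_G,
                              min_cells = config$min_cells,
                              n_boot = config$n_boot, seed = config$seed)
    write_tsv(phi, out("phi.tsv"))
    res$phi <- phi
  }

  manifest <- c(
    sprintf("package\tlongsplice %s",
            as.character(utils::packageVersion("longsplice"))),
    sprintf("seed\t%d", config$seed),
    sprintf("config_checksum\t%d", config_checksum(config)),
    sprintf("%s\t%d", names(log_counts), log_counts))
  writeLines(manifest, out("manifest.tsv"))
  invisible(res)
}

config_checksum <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "groups")]),
               collapse = "")
  sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 1000000007
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
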