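## Per-cell sub-exon inclusion counting.
##
## Each deduplicated molecule is scored against its gene's disjoint
## sub-exons as a vector over {1 = spliced in, 0 = spliced out, NA =
## censored}. Truncated ends censor rather than count as exclusion: a
## missing exon at the 5' or 3' end without a polyA is NA, because a
## truncated read carries no information about exons it never reached.

#' Score one molecule against its gene's sub-exons
#'
#' Internal splice sites within `max_site_dev` bp of an annotated
#' boundary are snapped to it before scoring; sites farther than that are
#' kept verbatim (novel junction) and the affected sub-exons are scored
#' by coverage. Sub-exons fully inside the molecule's span score 1 when
#' covered and 0 when skipped; terminal sub-exons need at least
#' `min_end_overlap` bp of overlap to count. Sub-exons beyond the 5' end
#' are censored (NA); beyond the 3' end they are censored unless the
#' molecule carries a polyA, in which case the transcript end was
#' observed and downstream sub-exons score 0 (set
#' `polyA_terminal_zero = FALSE` to censor those too).
#'
#' @param iso_key molecule isoform key (see [iso_key()]).
#' @param gene one element of a [parse_gtf_subexons()] annotation.
#' @param polyA logical, molecule observed with a polyA tail.
#' @param min_end_overlap minimum terminal overlap in bp (default 10).
#' @param max_site_dev maximum deviation of internal sites from
#'   annotation in bp (default 1).
#' @param polyA_terminal_zero score sub-exons downstream of an observed
#'   polyA as 0 (default TRUE).
#' @return Integer vector over the gene's sub-exons with values 0, 1, NA.
#' @export
assign_molecule_to_subexons <- function(iso_key, gene, polyA = FALSE,
                                        min_end_overlap = 10L,
                                        max_site_dev = 1L,
                                        polyA_terminal_zero = TRUE) {
  sub <- gene$subexons
  bounds <- sort(unique(c(sub$start, sub$end)))
  blocks <- iso_blocks(iso_key)
  # snap internal sites to annotated boundaries
  if (nrow(blocks) >= 1) {
    coords <- as.vector(t(blocks))
    internal <- seq_along(coords) > 1 & seq_along(coords) < length(coords)
    for (i in which(internal)) {
      d <- abs(bounds - coords[i])
      if (min(d) <= max_site_dev) coords[i] <- bounds[which.min(d)]
    }
    blocks <- matrix(coords, ncol = 2, byrow = TRUE)
    blocks <- blocks[blocks[, 1] < blocks[, 2], , drop = FALSE]
  }
  s <- blocks[1, 1]
  e <- blocks[nrow(blocks), 2]
  ir <- blocks_ir(blocks)
  n <- nrow(sub)
  out <- rep(NA_integer_, n)
  left_is_5p <- !identical(gene$strand, "-")
  for (i in seq_len(n)) {
    a <- sub$start[i]
    b <- sub$end[i]
    if (b <= s || a >= e) {
      # outside the molecule span: censored, unless past an observed polyA
      on_left <- b <= s
      is_3p <- if (left_is_5p) !on_left else on_left
      out[i] <- if (is_3p && polyA && polyA_terminal_zero) 0L else NA_integer_
      next
    }
    ov <- sum(IRanges::width(IRanges::intersect(
      IRanges::IRanges(a + 1L, b), ir)))
    if (a < s || b > e) {
      # terminal sub-exon, partially inside the span
      out[i] <- if (ov >= min_end_overlap) 1L else NA_integer_
      next
    }
    w <- b - a
    if (ov == 0) out[i] <- 0L
    else if (ov == w) out[i] <- 1L
    else out[i] <- if (ov >= min_end_overlap) 1L else NA_integer_
  }
  out
}

#' Inclusion table for a set of molecules
#'
#' @param mols data.frame of molecules with columns `cell`, `gene_id`,
#'   `isoform` and optionally `polyA`.
#' @param annotation a [parse_gtf_subexons()] result.
#' @param ... passed to [assign_molecule_to_subexons()].
#' @return Long data.frame: `cell`, `gene_id`, `exon` (1-based sub-exon
#'   index), `mol` (molecule row index), `value` (0/1/NA). Molecules with
#'   zero informative sub-exons are dropped.
#' @export
inclusion_table <- function(mols, annotation, ...) {
  rows <- vector("list", nrow(mols))
  for (r in seq_len(nrow(mols))) {
    g <- annotation[[mols$gene_id[r]]]
    if (is.null(g)) next
    pa <- if ("polyA" %in% names(mols)) isTRUE(mols$polyA[r]) else FALSE
    v <- assign_molecule_to_subexons(mols$isoform[r], g, polyA = pa, ...)
    if (all(is.na(v))) next
    rows[[r]] <- data.frame(cell = mols$cell[r], gene_id = mols$gene_id[r],
                            exon = seq_along(v), mol = r, value = v,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(cell = character(0), gene_id = character(0),
                      exon = integer(0), mol = integer(0), value = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build the E/G count matrices from an inclusion table
#'
#' For each cell and (meta-)exon, the informative count `G` is the number
#' of non-NA molecule values and the inclusion count `E` the number of
#' ones, so `0 <= E <= G <=` the cell's molecule count for the gene.
#'
#' @param incl long inclusion table (see [inclusion_table()]).
#' @return data.frame with `cell`, `gene_id`, `exon`, `E`, `G`.
#' @export
build_count_matrices <- function(incl) {
  if (nrow(incl) == 0) {
    return(data.frame(cell = character(0), gene_id = character(0),
                      exon = integer(0), E = integer(0), G = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(incl$cell, incl$gene_id, incl$exon, drop = TRUE)
  G <- tapply(!is.na(incl$value), key, sum)
  E <- tapply(incl$value == 1L, key, function(x) sum(x, na.rm = TRUE))
  first <- !duplicated(key)
  out <- data.frame(cell = incl$cell[first], gene_id = incl$gene_id[first],
                    exon = incl$exon[first],
                    E = as.integer(E[as.character(key[first])]),
                    G = as.integer(G[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$exon, out$cell), , drop = FALSE]
}

## ---- meta-exon merging -----------------------------------------------------

# does any exon of transcript tx (data.frame start/end) fully cover [a,b)?
tx_contains <- function(tx, a, b) {
  any(tx$start <= a & tx$end >= b)
}

#' Merge redundant sub-exons into meta-exons
#'
#' Sub-exon pairs that are perfectly co-inclusive across all jointly
#' informative molecules (at least `min_joint` of them, zero discordant)
#' and that co-occur in every annotated transcript containing either are
#' merged into one meta-exon, keeping the values of the member with the
#' most informative molecules. Pairs that are perfectly mutually
#' exclusive empirically and never co-annotated are merged with the
#' second member recoded as exclusion of the first. Merging removes
#' duplicated tests downstream without discarding information.
#'
#' @param incl long inclusion table from [inclusion_table()].
#' @param annotation a [parse_gtf_subexons()] result.
#' @param min_joint minimum jointly informative molecules for an
#'   empirical claim (default 20).
#' @return List with `incl` (transformed table whose `exon` column now
#'   holds meta-exon indices) and `map` (data.frame `gene_id`, `exon`,
#'   `meta`, `recode`).
#' @export
merge_exons <- function(incl, annotation, min_joint = 20L) {
  maps <- list()
  parts <- list()
  for (g in unique(incl$gene_id)) {
    sub <- incl[incl$gene_id == g, , drop = FALSE]
    gene <- annotation[[g]]
    n_ex <- nrow(gene$subexons)
    W <- matrix(NA_integer_, nrow = length(unique(sub$mol)), ncol = n_ex)
    mids <- sort(unique(sub$mol))
    W[cbind(match(sub$mol, mids), sub$exon)] <- sub$value
    parent <- seq_len(n_ex)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    recode <- rep(FALSE, n_ex)
    me_partner <- rep(NA_integer_, n_ex)
    if (n_ex > 1) {
      for (i in seq_len(n_ex - 1)) {
        for (j in seq(i + 1, n_ex)) {
          x <- W[, i]; y <- W[, j]
          joint <- !is.na(x) & !is.na(y)
          if (sum(joint) < min_joint) next
          ai <- gene$subexons$start[i]; bi <- gene$subexons$end[i]
          aj <- gene$subexons$start[j]; bj <- gene$subexons$end[j]
          has_i <- vapply(gene$transcripts, tx_contains, logical(1), ai, bi)
          has_j <- vapply(gene$transcripts, tx_contains, logical(1), aj, bj)
          if (all(x[joint] == y[joint])) {
            # co-inclusive in data; require co-annotation
            if (all(has_i == has_j) && any(has_i)) {
              parent[find(j)] <- find(i)
            }
          } else if (all(x[joint] + y[joint] == 1L)) {
            # mutually exclusive in data and never co-annotated
            if (!any(has_i & has_j) && any(has_i) && any(has_j) &&
                is.na(me_partner[i]) && is.na(me_partner[j]) &&
                find(i) == i && find(j) == j) {
              me_partner[j] <- i
              recode[j] <- TRUE
            }
          }
        }
      }
    }
    root <- vapply(seq_len(n_ex), find, integer(1))
    root[!is.na(me_partner)] <- root[me_partner[!is.na(me_partner)]]
    # representative member of each co-inclusive group: most informative
    informative <- colSums(!is.na(W))
    meta_of <- match(root, unique(root))
    val <- W
    for (m in unique(meta_of)) {
      members <- which(meta_of == m)
      co_members <- members[!recode[members]]
      repc <- co_members[which.max(informative[co_members])]
      mv <- val[, repc]
      for (k in members[recode[members]]) {
        fill <- is.na(mv) & !is.na(W[, k])
        mv[fill] <- 1L - W[fill, k]
      }
      val[, members[1]] <- mv   # store on first member slot
    }
    cells <- mids_cell(sub, mids)
    sub_new <- do.call(rbind, lapply(unique(meta_of), function(m) {
      v <- val[, which(meta_of == m)[1]]
      data.frame(cell = cells, gene_id = g, exon = m,
                 mol = mids, value = v, stringsAsFactors = FALSE)
    }))
    parts[[g]] <- sub_new
    maps[[g]] <- data.frame(gene_id = g, exon = seq_len(n_ex),
                            meta = meta_of, recode = recode,
                            stringsAsFactors = FALSE)
  }
  list(incl = do.call(rbind, parts), map = do.call(rbind, maps))
}

# cell of each molecule id, in mids order
mids_cell <- function(sub, mids) {
  sub$cell[match(mids, sub$mol)]
}
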