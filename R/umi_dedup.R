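## UMI deduplication within meta-isoform groups.
##
## Putative UMI windows from one cell are pooled at the meta-isoform level
## (isoforms inter-convertible by end truncation or mis-mapping of short
## middle exons), scored pairwise by Needleman-Wunsch, and clustered by
## iterative Louvain community detection. Each cluster is one original
## molecule; its representative isoform corrects truncation and mapping
## errors, and implausibly small clusters are pruned with a
## negative-binomial amplification model.

## ---- interval helpers (0-based half-open blocks <-> IRanges) ---------------

blocks_ir <- function(blocks) {
  IRanges::IRanges(start = blocks[, 1] + 1L, end = blocks[, 2])
}

## ---- UMI window extraction -------------------------------------------------

#' Extract the putative UMI window after a matched barcode
#'
#' The UMI occupies the `umi_len` bases following the cell barcode; one
#' flanking base on each side is kept so that an insertion or deletion
#' inside the barcode does not push the true UMI out of the window.
#'
#' @param clip softclip string (adapter->transcript orientation).
#' @param barcode_end 1-based position of the last matched barcode base
#'   within `clip`.
#' @param umi_len UMI length in nt.
#' @param flank flanking bases on each side (default 1).
#' @return List with `window` (string) and `truncated` (TRUE when the
#'   window ran off the clip end and is shorter than `umi_len + 2*flank`).
#' @export
extract_umi_window <- function(clip, barcode_end, umi_len, flank = 1L) {
  from <- max(1L, barcode_end + 1L - flank)
  to <- barcode_end + umi_len + flank
  w <- substr(clip, from, min(to, nchar(clip)))
  list(window = w, truncated = nchar(w) < umi_len + 2L * flank)
}

## ---- meta-isoform grouping -------------------------------------------------

#' Test whether two isoform chains belong to one meta-isoform group
#'
#' Two reads are compatible when their spans overlap, the exonic
#' symmetric difference restricted to the overlap `[so, eo)` (so =
#' max(s1, s2), eo = min(e1, e2)) totals fewer than `thresh` bases, and
#' every maximal differing block is either a middle exon shorter than
#' `max_middle_exon` bp (a plausible mis-mapping) or touches the overlap
#' boundary (an end truncation).
#'
#' @param key1,key2 isoform keys (see [iso_key()]).
#' @param thresh strict upper bound on total symmetric difference within
#'   the overlap (default 80 nt).
#' @param max_middle_exon strict upper bound on a differing middle block
#'   (default 80 bp).
#' @return Logical.
#' @export
meta_isoform_compatible <- function(key1, key2, thresh = 80L,
                                    max_middle_exon = 80L) {
  b1 <- iso_blocks(key1)
  b2 <- iso_blocks(key2)
  so <- max(b1[1, 1], b2[1, 1])
  eo <- min(b1[nrow(b1), 2], b2[nrow(b2), 2])
  if (so >= eo) return(FALSE)
  r1 <- IRanges::restrict(blocks_ir(b1), start = so + 1L, end = eo)
  r2 <- IRanges::restrict(blocks_ir(b2), start = so + 1L, end = eo)
  sdiff <- IRanges::union(IRanges::setdiff(r1, r2), IRanges::setdiff(r2, r1))
  sdiff <- IRanges::reduce(sdiff, min.gapwidth = 1L)
  if (sum(IRanges::width(sdiff)) >= thresh) return(FALSE)
  if (length(sdiff) == 0) return(TRUE)
  touches_end <- IRanges::start(sdiff) == so + 1L | IRanges::end(sdiff) == eo
  all(touches_end | IRanges::width(sdiff) < max_middle_exon)
}

#' Group reads of one cell and gene into meta-isoform groups
#'
#' Single-linkage grouping under [meta_isoform_compatible()]: reads whose
#' isoforms differ only by end truncation or by short middle exons (the
#' signatures of technical artifacts) share a group, and UMI clustering
#' is performed within groups so that a truncated read can rejoin the
#' complete reads of its molecule.
#'
#' @param iso_keys character vector of isoform keys, one per read.
#' @param thresh,max_middle_exon see [meta_isoform_compatible()].
#' @return Integer vector of group ids, same length as `iso_keys`.
#' @export
group_meta_isoforms <- function(iso_keys, thresh = 80L, max_middle_exon = 80L) {
  uk <- sort(unique(iso_keys))
  n <- length(uk)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (find(i) != find(j) &&
            meta_isoform_compatible(uk[i], uk[j], thresh, max_middle_exon)) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gid <- match(roots, unique(roots))
  gid[match(iso_keys, uk)]
}

## ---- UMI graph + iterative Louvain ----------------------------------------

#' Build a UMI similarity graph
#'
#' Nodes are putative UMI windows; edges carry the Needleman-Wunsch
#' global alignment score (+1/-1/-1). For 10 bp UMIs, edges scoring below
#' 5 are dropped (two or more differences), leaving a graph in which
#' copies of one molecule stay connected while distinct UMIs mostly do
#' not.
#'
#' @param windows character vector of UMI windows (one cell, one
#'   meta-isoform group).
#' @param min_edge minimum retained edge weight (default 5, the 10 bp UMI
#'   setting; scale as `ceiling(L/2)` for other lengths).
#' @return An [igraph::graph] with vertex attribute `name` (window index
#'   as character) and edge attribute `weight`.
#' @export
build_umi_graph <- function(windows, min_edge = 5L) {
  n <- length(windows)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (n > 1) {
    sc <- nw_score_matrix(windows)
    keep <- which(upper.tri(sc) & sc >= min_edge, arr.ind = TRUE)
    if (nrow(keep) > 0) {
      g <- igraph::add_edges(g, t(keep),
                             attr = list(weight = sc[keep]))
    }
  }
  g
}

#' Iterative Louvain clustering of a UMI graph
#'
#' Louvain community detection (resolution 1) is applied recursively:
#' each community is re-extracted as a subgraph and re-clustered until
#' the subgraph is highly connected (weighted global min-cut above
#' `mincut_stop`), all its edges are strong (minimum edge weight above
#' `strong_edge`), or it is a single node. The recursion resolves the
#' "crowding" regime in which distinct UMIs are bridged by intermediate
#' error sequences.
#'
#' @param graph graph from [build_umi_graph()].
#' @param resolution Louvain resolution (default 1).
#' @param mincut_stop stop when the weighted min-cut exceeds this
#'   (default 3).
#' @param strong_edge stop when every edge weight exceeds this
#'   (default 7; scale as `ceiling(0.7 L)` for non-10 nt UMIs).
#' @param seed RNG seed for Louvain reproducibility.
#' @param max_exact_mincut exact min-cut is evaluated only on subgraphs
#'   up to this many nodes; larger subgraphs always recurse (they are
#'   precisely the crowded ones).
#' @return Integer cluster membership vector in input vertex order.
#' @export
iterative_louvain <- function(graph, resolution = 1, mincut_stop = 3,
                              strong_edge = 7, seed = 1L,
                              max_exact_mincut = 200L) {
  n <- igraph::vcount(graph)
  membership <- integer(n)
  next_id <- 0L
  recurse <- function(g) {
    idx <- as.integer(igraph::V(g)$name)
    nv <- igraph::vcount(g)
    if (nv == 1L) {
      next_id <<- next_id + 1L
      membership[idx] <<- next_id
      return(invisible(NULL))
    }
    # stop rules apply to connected subgraphs only: split components first
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      for (m in seq_len(comp$no)) {
        recurse(igraph::induced_subgraph(g, which(comp$membership == m)))
      }
      return(invisible(NULL))
    }
    ne <- igraph::ecount(g)
    if (ne > 0) {
      if (min(igraph::E(g)$weight) > strong_edge) {
        next_id <<- next_id + 1L
        membership[idx] <<- next_id
        return(invisible(NULL))
      }
      if (nv <= max_exact_mincut) {
        # connectivity is counted in edges: one strong bridge between two
        # distinct-UMI clusters must not make the subgraph "highly connected"
        mc <- igraph::min_cut(g, capacity = rep(1, ne))
        if (mc > mincut_stop) {
          next_id <<- next_id + 1L
          membership[idx] <<- next_id
          return(invisible(NULL))
        }
      }
    }
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, weights = if (ne > 0) igraph::E(g)$weight
                                              else NULL,
                                  resolution = resolution)
    mem <- igraph::membership(cl)
    if (length(unique(mem)) == 1L) {
      next_id <<- next_id + 1L
      membership[idx] <<- next_id
      return(invisible(NULL))
    }
    for (m in sort(unique(mem))) {
      sub <- igraph::induced_subgraph(g, which(mem == m))
      recurse(sub)
    }
    invisible(NULL)
  }
  if (n > 0) recurse(graph)
  membership
}

#' Cluster a pool of UMI windows
#'
#' Convenience wrapper: [build_umi_graph()] then [iterative_louvain()],
#' with edge thresholds scaled to the UMI length.
#'
#' @param windows UMI window strings.
#' @param umi_len nominal UMI length (default 10; sets the thresholds).
#' @param seed RNG seed.
#' @param min_edge,strong_edge,mincut_stop,resolution see
#'   [build_umi_graph()] and [iterative_louvain()]; defaults derived from
#'   `umi_len`.
#' @return Integer cluster ids, one per window.
#' @export
cluster_umis <- function(windows, umi_len = 10L, seed = 1L,
                         min_edge = ceiling(umi_len / 2),
                         strong_edge = ceiling(0.7 * umi_len),
                         mincut_stop = 3, resolution = 1) {
  ord <- order(windows)  # canonical node order for reproducibility
  g <- build_umi_graph(windows[ord], min_edge = min_edge)
  mem <- iterative_louvain(g, resolution = resolution,
                           mincut_stop = mincut_stop,
                           strong_edge = strong_edge, seed = seed)
  out <- integer(length(windows))
  out[ord] <- mem
  out
}

## ---- representative selection ---------------------------------------------

#' Representative isoform and consensus UMI of one cluster
#'
#' The dominant isoform (most member reads) wins; ties break toward the
#' longest genomic span, then the lexicographically smallest chain. A
#' truncated read in a cluster dominated by complete reads is thereby
#' corrected. The consensus UMI is the per-position majority over member
#' windows of the modal length.
#'
#' @param iso_keys member isoform keys.
#' @param windows member UMI windows.
#' @return List with `isoform`, `umi`, `size`.
#' @export
select_representative <- function(iso_keys, windows) {
  tab <- table(iso_keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    spans <- vapply(top, function(k) diff(iso_span(k)), numeric(1))
    top <- top[spans == max(spans)]
    top <- sort(top)[1]
  }
  list(isoform = top, umi = consensus_umi(windows), size = length(iso_keys))
}

consensus_umi <- function(windows) {
  if (length(windows) == 1) return(windows)
  lens <- nchar(windows)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  w <- windows[lens == modal]
  if (length(w) == 1) return(w)
  m <- do.call(rbind, strsplit(w, ""))
  paste(apply(m, 2, function(col) {
    t <- sort(table(col), decreasing = TRUE)
    nm <- names(t)[t == max(t)]
    sort(nm)[1]
  }), collapse = "")
}

## ---- wrong-mapping correction ---------------------------------------------

#' Correct systematically mis-mapped isoforms via the attribution table
#'
#' For every UMI cluster, each member read's isoform is "attributed" to
#' the cluster's representative isoform; attribution counts are summed
#' over all clusters of all cells. An isoform attributed to other
#' isoforms more often than to itself is a mapping artifact: all its
#' molecules are relabeled to its most frequent attribution target,
#' following chains transitively until stable. Cycles resolve to the
#' chain member with the largest self-attribution.
#'
#' @param read_iso isoform key of each read.
#' @param rep_iso representative isoform of each read's cluster.
#' @return Named character vector mapping every observed isoform to its
#'   corrected label (identity where no correction applies).
#' @export
correct_mapping <- function(read_iso, rep_iso) {
  isos <- sort(unique(c(read_iso, rep_iso)))
  tab <- table(factor(read_iso, levels = isos),
               factor(rep_iso, levels = isos))
  self <- diag(tab)
  other <- rowSums(tab) - self
  target <- vapply(seq_along(isos), function(i) {
    if (other[i] > self[i]) {
      j <- which.max(tab[i, ])
      isos[j]
    } else isos[i]
  }, "")
  names(target) <- isos
  # resolve chains; detect cycles
  resolve <- target
  for (i in seq_along(isos)) {
    seen <- character(0)
    cur <- isos[i]
    while (resolve[cur] != cur && !(resolve[cur] %in% seen)) {
      seen <- c(seen, cur)
      cur <- resolve[cur]
    }
    if (resolve[cur] != cur) {
      # cycle: relabel to the member with the largest self-attribution
      cyc <- c(seen[which(seen == resolve[cur]):length(seen)], cur)
      cyc <- unique(c(cyc, cur))
      best <- cyc[which.max(self[cyc])]
      warning("cyclic isoform relabeling resolved to ", best)
      cur <- best
    }
    resolve[isos[i]] <- cur
  }
  resolve
}

## ---- amplification model + scatter reduction -------------------------------

#' Negative-binomial PCR amplification model
#'
#' Cluster sizes are modelled as `C - 1 ~ NB(r, p)`, which implies the
#' linear mean-variance law `var(C) = beta * (mean(C) - 1)` with
#' `beta = 1/p >= 1`.
#'
#' @param beta slope of the variance-mean relation (floored at 1).
#' @param conf_level confidence level of the variance interval used by
#'   [scatter_reduce()] (default 0.90).
#' @return List of class `amplification_model`.
#' @export
amplification_model <- function(beta = 1.5, conf_level = 0.90) {
  structure(list(beta = max(beta, 1), conf_level = conf_level),
            class = "amplification_model")
}

#' Estimate the amplification slope from single-isoform genes
#'
#' Regresses the per-group variance of UMI cluster sizes on the per-group
#' mean minus one, through the origin, across (gene, cell) groups from
#' genes with a single isoform (where every read demonstrably comes from
#' the same molecule species). Under `C - 1 ~ NB(r, p)` the slope is
#' `1/p`.
#'
#' @param sizes numeric vector of cluster sizes.
#' @param group grouping factor ((gene, cell) identifier), same length.
#' @param min_groups minimum usable groups (default 20); below this the
#'   default model is returned with a warning.
#' @param min_clusters_per_group groups need at least this many clusters
#'   (default 3).
#' @param default_beta fallback slope (default 1.5).
#' @param conf_level see [amplification_model()].
#' @return An [amplification_model()] with extra fields `beta_raw`,
#'   `n_groups`.
#' @export
estimate_beta <- function(sizes, group, min_groups = 20L,
                          min_clusters_per_group = 3L, default_beta = 1.5,
                          conf_level = 0.90) {
  sp <- split(sizes, group)
  sp <- sp[lengths(sp) >= min_clusters_per_group]
  if (length(sp) < min_groups) {
    warning("only ", length(sp), " usable groups; using default beta ",
            default_beta)
    m <- amplification_model(default_beta, conf_level)
    m$beta_raw <- NA_real_
    m$n_groups <- length(sp)
    return(m)
  }
  x <- vapply(sp, function(s) mean(s) - 1, numeric(1))
  y <- vapply(sp, var, numeric(1))
  ok <- is.finite(x) & is.finite(y)
  b <- if (sum(x[ok]^2) > 0) sum(x[ok] * y[ok]) / sum(x[ok]^2) else 1
  m <- amplification_model(b, conf_level)
  m$beta_raw <- b
  m$n_groups <- sum(ok)
  m
}

# chi-square effective degrees of freedom for the scaled sample variance.
# Two readings are provided: "literal" is nu = 2 n k - (n-3)/(n-1) with k
# the (non-excess) sample kurtosis; "box" is the Satterthwaite/Box moment
# approximation nu = 2n / (k - (n-3)/(n-1)), which reduces to ~n for
# normal data. The literal form yields a much tighter interval and hence
# a more decisive trimming rule but over-trims genuine small clusters;
# the moment approximation is the default.
variance_df <- function(x, method = c("box", "literal")) {
  method <- match.arg(method)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  k <- mean((x - mean(x))^4) / m2^2
  if (method == "literal") 2 * n * k - (n - 3) / (n - 1)
  else 2 * n / (k - (n - 3) / (n - 1))
}

#' Prune error-scattered small UMI clusters
#'
#' Copies of the same isoform in the same cell share an amplification
#' fold, so their cluster sizes should satisfy the negative-binomial law
#' `var(C) = beta (mean(C) - 1)`. Sequencing errors scatter reads of a
#' molecule into extra small clusters, inflating the variance above that
#' line. The smallest cluster is removed iteratively while the lower
#' bound of the confidence interval for `var(C)` lies entirely above the
#' model line; never below `min_clusters` clusters.
#'
#' @param sizes integer cluster sizes for one isoform in one cell.
#' @param model an [amplification_model()].
#' @param min_clusters identity below this many clusters (default 5).
#' @param df_method degrees-of-freedom reading for the variance CI, see
#'   [scatter_reduce()] details; `"box"` (default, moment approximation) or `"literal"`.
#' @param median_frac only clusters smaller than this fraction of the
#'   current median cluster size are removal candidates (default 0.5).
#'   Scatter debris is small relative to the typical amplification fold;
#'   without this guard, variance excess caused by erroneously merged
#'   large clusters (crowding) would cascade into removing genuine
#'   molecules.
#' @return Logical vector, TRUE for retained clusters (aligned with
#'   `sizes`; among ties the earliest entries are dropped first).
#' @export
scatter_reduce <- function(sizes, model = amplification_model(),
                           min_clusters = 5L,
                           df_method = c("box", "literal"),
                           median_frac = 0.5) {
  df_method <- match.arg(df_method)
  n0 <- length(sizes)
  retained <- rep(TRUE, n0)
  if (n0 < min_clusters) return(retained)
  alpha <- 1 - model$conf_level
  repeat {
    idx <- which(retained)
    s <- sizes[idx]
    n <- length(s)
    if (n <= min_clusters) break
    S2 <- var(s)
    if (!is.finite(S2) || S2 == 0) break
    target <- model$beta * (mean(s) - 1)
    nu <- variance_df(s, df_method)
    if (!is.finite(nu) || nu <= 0) break
    ci_lower <- nu * S2 / qchisq(1 - alpha / 2, df = nu)
    if (ci_lower > target && min(s) < median_frac * median(s)) {
      drop <- idx[which.min(s)]
      retained[drop] <- FALSE
    } else break
  }
  retained
}

## ---- per-cell driver -------------------------------------------------------

#' Deduplicate reads of one cell into molecules
#'
#' Groups the cell's reads per gene at the meta-isoform level, clusters
#' UMI windows within each group, and selects a representative isoform
#' and consensus UMI per cluster.
#'
#' @param reads data.frame with columns `gene_id`, `iso` (isoform key),
#'   `umi_window`, `read_id` for one cell.
#' @param umi_len nominal UMI length.
#' @param flank flanking bases on each side of the UMI windows. The
#'   flanks come from the barcode and the TSO, so within one cell they
#'   are shared by all molecules and inflate every pairwise score by
#'   about `2 * flank` matches; the edge thresholds are offset
#'   accordingly.
#' @param seed RNG seed.
#' @param thresh,max_middle_exon meta-isoform parameters.
#' @return data.frame of molecules: `gene_id`, `group`, `cluster`,
#'   `isoform`, `umi`, `size`.
#' @export
dedup_cell <- function(reads, umi_len = 10L, flank = 1L, seed = 1L,
                       thresh = 80L, max_middle_exon = 80L) {
  out <- list()
  for (g in unique(reads$gene_id)) {
    rg <- reads[reads$gene_id == g, , drop = FALSE]
    grp <- group_meta_isoforms(rg$iso, thresh, max_middle_exon)
    for (gi in unique(grp)) {
      sel <- grp == gi
      mem <- cluster_umis(rg$umi_window[sel], umi_len = umi_len, seed = seed,
                          min_edge = ceiling(umi_len / 2) + 2L * flank,
                          strong_edge = ceiling(0.7 * umi_len) + 2L * flank)
      for (cl in unique(mem)) {
        msel <- which(sel)[mem == cl]
        rep <- select_representative(rg$iso[msel], rg$umi_window[msel])
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, group = gi, cluster = cl,
          isoform = rep$isoform, umi = rep$umi, size = rep$size,
          member_ids = paste(rg$read_id[msel], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), group = integer(0),
                      cluster = integer(0), isoform = character(0),
                      umi = character(0), size = integer(0),
                      member_ids = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Deduplicate an assigned read table into molecules (all cells)
#'
#' The molecule-level core of the pipeline: per-cell meta-isoform
#' grouping and UMI clustering ([dedup_cell()]), global wrong-mapping
#' correction ([correct_mapping()]), and per-(cell, gene, isoform)
#' scatter reduction ([scatter_reduce()]). Mapping correction changes
#' isoform labels only, never the molecule count; scatter reduction
#' flags clusters via `retained` rather than deleting them.
#'
#' @param df data.frame with columns `cell`, `gene_id`, `iso` (isoform
#'   key), `umi_window`, `read_id`, and optionally `polyA`.
#' @param umi_len,flank UMI window geometry.
#' @param seed RNG seed.
#' @param thresh,max_middle_exon meta-isoform parameters.
#' @param beta `"auto"` (estimate the amplification slope from genes
#'   whose molecules all share one isoform), a numeric slope, or an
#'   [amplification_model()].
#' @param default_beta fallback slope for `"auto"` without enough
#'   calibration groups.
#' @param min_clusters scatter-reduction guard.
#' @param scatter set FALSE to skip scatter reduction (all retained).
#' @return data.frame of molecules: `cell`, `gene_id`, `isoform`
#'   (corrected), `umi`, `size`, `polyA`, `retained`, `member_ids`
#'   (semicolon-joined read ids).
#' @export
dedup_table <- function(df, umi_len = 10L, flank = 1L, seed = 1L,
                        thresh = 80L, max_middle_exon = 80L, beta = "auto",
                        default_beta = 1.5, min_clusters = 5L,
                        scatter = TRUE) {
  has_polyA <- "polyA" %in% names(df)
  mols <- list()
  read_rep <- list()
  for (cell in sort(unique(df$cell))) {
    sub <- df[df$cell == cell, , drop = FALSE]
    mm <- dedup_cell(sub[, c("gene_id", "iso", "umi_window", "read_id")],
                     umi_len = umi_len, flank = flank, seed = seed,
                     thresh = thresh, max_middle_exon = max_middle_exon)
    if (nrow(mm) == 0) next
    mm$cell <- cell
    members <- strsplit(mm$member_ids, ";", fixed = TRUE)
    mm$polyA <- if (has_polyA) {
      vapply(members, function(ids) {
        mean(sub$polyA[match(ids, sub$read_id)]) >= 0.5
      }, logical(1))
    } else FALSE
    mols[[length(mols) + 1L]] <- mm
    for (r in seq_len(nrow(mm))) {
      read_rep[[length(read_rep) + 1L]] <- data.frame(
        iso = sub$iso[match(members[[r]], sub$read_id)],
        rep = mm$isoform[r], stringsAsFactors = FALSE)
    }
  }
  if (length(mols) == 0) {
    return(data.frame(cell = character(0), gene_id = character(0),
                      isoform = character(0), umi = character(0),
                      size = integer(0), polyA = logical(0),
                      retained = logical(0), member_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  mols <- do.call(rbind, mols)
  attr_tab <- do.call(rbind, read_rep)
  relabel <- correct_mapping(attr_tab$iso, attr_tab$rep)
  mols$isoform <- unname(relabel[mols$isoform])

  model <- if (inherits(beta, "amplification_model")) {
    beta
  } else if (is.numeric(beta)) {
    amplification_model(beta)
  } else {
    single_iso <- tapply(mols$isoform, mols$gene_id,
                         function(x) length(unique(x)) == 1)
    cal <- mols[single_iso[mols$gene_id], , drop = FALSE]
    suppressWarnings(
      estimate_beta(cal$size,
                    interaction(cal$cell, cal$gene_id, drop = TRUE),
                    default_beta = default_beta))
  }
  mols$retained <- TRUE
  if (scatter) {
    key <- interaction(mols$cell, mols$gene_id, mols$isoform, drop = TRUE)
    for (k in levels(key)) {
      idx <- which(key == k)
      mols$retained[idx] <- scatter_reduce(mols$size[idx], model,
                                           min_clusters = min_clusters)
    }
  }
  rownames(mols) <- NULL
  mols[, c("cell", "gene_id", "isoform", "umi", "size", "polyA", "retained",
           "member_ids")]
}
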