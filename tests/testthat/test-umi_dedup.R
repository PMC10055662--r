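test_that("UMI windows keep the true UMI under flanking-base tolerance", {
  clip <- paste0(strrep("C", 20), "ACGTACGTAC", strrep("T", 10))
  # barcode ends at position 20; 10 nt UMI follows
  w <- extract_umi_window(clip, 20L, 10L, flank = 1L)
  expect_equal(nchar(w$window), 12L)
  expect_true(grepl("ACGTACGTAC", w$window, fixed = TRUE))
  expect_false(w$truncated)

  # flank 0: exactly the UMI
  w0 <- extract_umi_window(clip, 20L, 10L, flank = 0L)
  expect_equal(w0$window, "ACGTACGTAC")

  # every single-indel placement of the barcode still leaves the UMI
  # inside the 12 nt window (barcode end off by one either way)
  for (be in c(19L, 21L)) {
    wi <- extract_umi_window(clip, be, 10L, flank = 1L)
    expect_true(grepl("ACGTACGTA", wi$window, fixed = TRUE) ||
                  grepl("CGTACGTAC", wi$window, fixed = TRUE))
  }

  # running off the clip end flags truncation
  wt <- extract_umi_window(substr(clip, 1, 25), 20L, 10L)
  expect_true(wt$truncated)
})

test_that("meta-isoform grouping tolerates truncation and short mis-mapping", {
  full <- iso_key(1000, 2100, c(1200, 1400, 1460, 1550, 1700, 1800))
  trunc5 <- iso_key(1420, 2100, c(1460, 1550, 1700, 1800))
  expect_true(meta_isoform_compatible(full, trunc5))

  # a 60 bp middle exon difference (below the 80 bp bound) is compatible
  with_short <- iso_key(1000, 2100, c(1200, 1400, 1460, 1800))
  no_short <- iso_key(1000, 2100, c(1200, 1800))
  expect_true(meta_isoform_compatible(with_short, no_short))

  # a 120 bp cassette exon difference separates groups
  a <- iso_key(1000, 2000, c(1200, 1500, 1620, 1800))
  b <- iso_key(1000, 2000, c(1200, 1800))
  expect_false(meta_isoform_compatible(a, b, thresh = 80))

  # base-set oracle: symmetric difference within the overlap is 120
  ov_bases <- function(key, so, eo) {
    bl <- iso_blocks(key)
    unlist(apply(bl, 1, function(r) {
      s <- max(r[1], so); e <- min(r[2], eo)
      if (s < e) seq(s, e - 1) else integer(0)
    }))
  }
  sd_len <- length(union(setdiff(ov_bases(a, 1000, 2000), ov_bases(b, 1000, 2000)),
                         setdiff(ov_bases(b, 1000, 2000), ov_bases(a, 1000, 2000))))
  expect_equal(sd_len, 120)

  # non-overlapping reads never group
  expect_false(meta_isoform_compatible(iso_key(100, 200), iso_key(300, 400)))

  keys <- c(full, trunc5, a)
  grp <- group_meta_isoforms(keys)
  expect_equal(grp[1], grp[2])
  expect_equal(length(unique(grp)), 2L)
})

test_that("Needleman-Wunsch scores match the DP oracle", {
  expect_equal(nw_score(strrep("A", 10), strrep("A", 10)), 10L)
  u <- "ACGTACGTAC"
  v <- "ACGTTCGTAC"
  expect_equal(nw_score(u, v), 8L)
  expect_equal(nw_score("AAAA", "AAA"), 2L)
  # exhaustive equivalence on short strings, symmetry, self-score
  strs <- all_strings(c("A", "C"), 4)[-1]
  for (a in strs) for (b in strs) {
    expect_identical(nw_score(a, b), as.integer(oracle_nw(a, b)))
  }
  x <- random_kmers(100, 8:12, seed = 3)
  y <- random_kmers(100, 8:12, seed = 4)
  for (i in seq_along(x)) {
    expect_identical(nw_score(x[i], y[i]), nw_score(y[i], x[i]))
    expect_identical(nw_score(x[i], x[i]), nchar(x[i]))
    expect_identical(nw_score(x[i], y[i]), as.integer(oracle_nw(x[i], y[i])))
  }
})

test_that("UMI graph keeps strong edges and drops weak ones", {
  w <- c("AAAAAAAAAAAA", "AAAAAAAAAAAA")   # identical 12 nt windows
  g <- build_umi_graph(w, min_edge = 5)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 12L)

  # score 4 stays below the threshold: no edge
  w2 <- c("AAAAAAAAAA", "AAACCCAAAA")  # 3 mismatches: 10 - 6 = 4
  expect_equal(nw_score(w2[1], w2[2]), 4L)
  expect_equal(igraph::ecount(build_umi_graph(w2, min_edge = 5)), 0L)

  # n identical windows: complete graph
  g3 <- build_umi_graph(rep("ACGTACGTAC", 5), min_edge = 5)
  expect_equal(igraph::ecount(g3), choose(5, 2))
})

test_that("iterative Louvain splits bridged clusters and stops on strength", {
  # two K5 blocks, intra weight 10, joined by one weight-5 bridge
  g <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(g)$name <- as.character(1:10)
  edges <- c()
  for (i in 1:4) for (j in (i + 1):5) edges <- c(edges, i, j)
  for (i in 6:9) for (j in (i + 1):10) edges <- c(edges, i, j)
  g <- igraph::add_edges(g, edges, attr = list(weight = 10))
  g <- igraph::add_edges(g, c(5, 6), attr = list(weight = 5))
  mem <- iterative_louvain(g, seed = 1)
  expect_equal(length(unique(mem)), 2L)
  expect_equal(length(unique(mem[1:5])), 1L)
  expect_equal(length(unique(mem[6:10])), 1L)
  # brute-force check of the stop rule: each block is highly connected
  # (edge min-cut 4 > 3), the joined graph is not (bridge cut = 1)
  sub <- igraph::induced_subgraph(g, 1:5)
  expect_gt(igraph::min_cut(sub, capacity = rep(1, igraph::ecount(sub))), 3)
  expect_lte(igraph::min_cut(g, capacity = rep(1, igraph::ecount(g))), 3)

  # single node: one singleton cluster
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "1"
  expect_equal(iterative_louvain(g1), 1L)

  # complete graph with all weights above strong_edge: one cluster
  gk <- build_umi_graph(rep("ACGTACGTAC", 6), min_edge = 5)
  expect_equal(length(unique(iterative_louvain(gk, strong_edge = 7))), 1L)
})

test_that("cluster partition covers every read exactly once", {
  pool <- simulate_umi_pool(12, seed = 19)
  mem <- cluster_umis(pool$reads, seed = 1)
  expect_equal(length(mem), length(pool$reads))
  expect_true(all(mem >= 1))
  expect_equal(sum(table(mem)), length(pool$reads))
  # deduplicated count never exceeds the read count; equality iff all
  # clusters are singletons
  expect_lte(length(unique(mem)), length(pool$reads))
  singles <- all(table(mem) == 1)
  expect_equal(length(unique(mem)) == length(pool$reads), singles)
})

test_that("representative selection corrects truncation by majority", {
  full <- iso_key(1000, 2000, c(1200, 1300))
  trunc <- iso_key(1250, 2000, c(1300))
  rep1 <- select_representative(c(rep(full, 4), trunc), rep("ACGTACGTACGT", 5))
  expect_equal(rep1$isoform, full)
  expect_equal(rep1$size, 5L)

  # majority vote between correct and mis-mapped chains
  mis <- iso_key(1000, 2000, c(1200, 1300, 1400, 1500))
  rep2 <- select_representative(c(rep(full, 3), rep(mis, 2)),
                                rep("ACGTACGTACGT", 5))
  expect_equal(rep2$isoform, full)

  # singleton cluster: its own isoform
  rep3 <- select_representative(trunc, "ACGTACGTACGT")
  expect_equal(rep3$isoform, trunc)

  # tie broken toward the longer genomic span
  short <- iso_key(1100, 1900)
  long <- iso_key(1000, 2000)
  rep4 <- select_representative(c(short, long), rep("ACGTACGTACGT", 2))
  expect_equal(rep4$isoform, long)

  # consensus UMI is the per-position majority
  expect_equal(consensus_umi(c("AAAA", "AAAT", "AAAA")), "AAAA")
})

test_that("mapping correction follows the attribution-table rule", {
  # isoform n assigned to a more often than to itself: relabeled
  read_iso <- c(rep("a", 50), rep("n", 2), rep("n", 10))
  rep_iso <- c(rep("a", 50), rep("n", 2), rep("a", 10))
  map <- correct_mapping(read_iso, rep_iso)
  expect_equal(unname(map["n"]), "a")
  expect_equal(unname(map["a"]), "a")

  # b mostly assigned to itself: unchanged
  read_iso2 <- c(rep("a", 50), rep("b", 40), rep("b", 5))
  rep_iso2 <- c(rep("a", 50), rep("b", 40), rep("a", 5))
  map2 <- correct_mapping(read_iso2, rep_iso2)
  expect_equal(unname(map2["b"]), "b")

  # relabeling never changes the number of molecules, only labels
  mols <- c("a", "n", "n", "b")
  relabeled <- unname(map[mols])
  expect_equal(length(relabeled), length(mols))
})

test_that("amplification slope recovers the negative-binomial law", {
  # Ci - 1 ~ NB(r, p = 0.5) implies var = (1/p) * mean: slope 2
  set.seed(7)
  sizes <- c(); grp <- c()
  for (g in 1:500) {
    n <- 5 + rpois(1, 5)
    sizes <- c(sizes, 1 + rnbinom(n, size = 4, prob = 0.5))
    grp <- c(grp, rep(g, n))
  }
  m <- estimate_beta(sizes, grp)
  expect_lt(abs(m$beta - 2) / 2, 0.1)

  # degenerate equal sizes: zero variance, slope floored at 1
  mfl <- estimate_beta(rep(4L, 100), rep(1:25, each = 4))
  expect_equal(mfl$beta, 1)

  # Poisson-like folds (p -> 1): slope near 1
  set.seed(8)
  sizes <- c(); grp <- c()
  for (g in 1:300) {
    sizes <- c(sizes, 1 + rpois(8, 4))
    grp <- c(grp, rep(g, 8))
  }
  expect_lt(abs(estimate_beta(sizes, grp)$beta - 1), 0.15)

  # too few groups: fall back to the default with a warning
  expect_warning(mdef <- estimate_beta(1:6, rep(1:2, 3)), "default")
  expect_equal(mdef$beta, 1.5)
})

test_that("scatter reduction prunes singletons but respects its guards", {
  model <- amplification_model(2)
  # equal sizes: zero variance sits below the model line, nothing removed
  expect_true(all(scatter_reduce(rep(5L, 5), model)))
  # fewer than min_clusters: identity
  expect_true(all(scatter_reduce(c(1L, 9L, 9L, 9L), model)))
  # a clear scatter pattern (high fold, excess singletons) loses its
  # singletons but keeps every full-size cluster
  sizes <- c(rep(1L, 6), rep(12L, 12))
  keep <- scatter_reduce(sizes, model)
  expect_true(all(keep[sizes == 12]))
  expect_lt(sum(keep), length(sizes))
  # monotone: output is a subset flag, never grows the input
  expect_equal(length(keep), length(sizes))
})
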