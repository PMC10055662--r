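test_that("k-mer index registers every barcode under each of its k-mers", {
  idx <- build_kmer_index("ACGTACGTACGTACGT", k = 8)
  expect_equal(length(ls(idx$kmer_map)), length(unique(
    substring("ACGTACGTACGTACGT", 1:9, 8:16))))
  # a 16-mer has 9 k-mer positions
  starts <- 1:9
  for (s in starts) {
    km <- substr("ACGTACGTACGTACGT", s, s + 7)
    expect_equal(idx$kmer_map[[km]], 1L)
  }

  # two barcodes sharing a k-mer both retrievable under it
  idx2 <- build_kmer_index(c("AAAAAAAACCCCCCCC", "GGGGGGGGAAAAAAAA"))
  expect_setequal(idx2$kmer_map[["AAAAAAAA"]], c(1L, 2L))

  expect_error(build_kmer_index(c("ACGT"), k = 8), "exceeds")
  expect_error(build_kmer_index(c("AAAAAAAAAA", "AAAAAAAA")), "uniform")
  expect_warning(build_kmer_index(rep("ACGTACGTACGTACGT", 2)), "duplicate")
})

test_that("edit distance matches the DP oracle exhaustively and at random", {
  strs <- all_strings(c("A", "C"), 4)
  for (a in strs) for (b in strs) {
    expect_identical(edit_distance(a, b), oracle_edit_distance(a, b))
  }
  x <- random_kmers(300, 10:16, seed = 21)
  y <- random_kmers(300, 10:16, seed = 22)
  for (i in seq_along(x)) {
    expect_identical(edit_distance(x[i], y[i]), oracle_edit_distance(x[i], y[i]))
  }
})

test_that("infix edit distance finds the best window", {
  r <- infix_edit_distance("ACGT", "TTTTACGTGGG")
  expect_equal(r$dist, 0)
  expect_equal(r$start, 4)
  expect_equal(r$end, 8)
  # brute-force window oracle on random cases
  set.seed(31)
  for (rep in 1:30) {
    pat <- random_kmers(1, 5:8, seed = rep)
    txt <- random_kmers(1, 12:20, seed = rep + 1000)
    best <- min(vapply(seq_len(nchar(txt)), function(s) {
      min(vapply(s:nchar(txt), function(e) {
        oracle_edit_distance(pat, substr(txt, s, e))
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(infix_edit_distance(pat, txt)$dist, best)
  }
})

test_that("match_barcode resolves exact, mutated and ambiguous embeddings", {
  set.seed(12)
  wl <- random_seqs(50, 16)
  idx <- build_kmer_index(wl)
  prior <- initial_position_prior()
  adapter <- "CTACACGACGCTCTTC"

  clip <- paste0(adapter, wl[7], strrep("T", 12))
  m <- match_barcode(clip, idx, prior)
  expect_equal(m$barcode, wl[7])
  expect_equal(m$edit_distance, 0L)
  expect_equal(m$start_pos, nchar(adapter) + 1L)

  # one substitution: same winner at distance 1, verified against a
  # full-whitelist DP oracle
  mut <- wl[7]
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  clip1 <- paste0(adapter, mut, strrep("T", 12))
  m1 <- match_barcode(clip1, idx, prior)
  oracle <- vapply(wl, function(b) {
    min(vapply(1:(nchar(clip1) - 10), function(s) {
      min(vapply(s:nchar(clip1), function(e) {
        oracle_edit_distance(b, substr(clip1, s, e))
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(m1$barcode, wl[7])
  expect_equal(m1$edit_distance, 1L)
  expect_equal(sum(oracle == min(oracle)), 1L)
  expect_equal(unname(min(oracle)), 1)

  # ambiguous minimum: two whitelist entries embedded equally well
  wl2 <- c("AAAAAAAACCCCCCCC", "AAAAAAAACCCCCCCG")
  idx2 <- build_kmer_index(wl2)
  clip2 <- paste0("TTTTTTTTTTTTTTTT", "AAAAAAAACCCCCCCT", strrep("G", 10))
  m2 <- match_barcode(clip2, idx2, initial_position_prior(42))
  expect_true(is.na(m2$barcode))
  expect_gt(m2$n_candidates, 1L)
})

test_that("position prior updates use empirical mean and floored sd", {
  p0 <- initial_position_prior()
  m <- data.frame(edit_distance = c(0L, 0L, 1L), start_pos = c(12L, 12L, 12L))
  p <- update_position_prior(p0, m)
  expect_equal(p$mean, 12)
  expect_equal(p$sd, 1)  # degenerate sample floored at sd_floor

  m2 <- data.frame(edit_distance = c(0L, 1L, 0L), start_pos = c(10L, 12L, 14L))
  p2 <- update_position_prior(p0, m2)
  expect_equal(p2$mean, 12)
  expect_equal(p2$sd, sd(c(10, 12, 14)))

  # nothing confident: identity
  m3 <- data.frame(edit_distance = c(3L, NA), start_pos = c(9L, NA))
  expect_identical(update_position_prior(p0, m3), p0)
})

test_that("match filtering applies inclusive edit and z-score cutoffs", {
  prior <- position_prior(mean = 20, sd = 2)
  m <- data.frame(
    barcode = c("b", "b", "b", NA),
    edit_distance = c(0L, 0L, 3L, NA_integer_),
    start_pos = c(20L, 30L, 21L, NA_integer_))
  out <- filter_matches(m, prior, max_ed = 3, max_z = 3)
  expect_true(out$pass[1])    # modal position, perfect match
  expect_false(out$pass[2])   # 5 sd away
  expect_true(out$pass[3])    # edit distance equal to max_ed is inclusive
  expect_false(out$pass[4])   # unassigned never passes
})

test_that("two-pass assignment is accurate, sensitive and deterministic", {
  set.seed(5)
  wl <- random_seqs(1000, 16)
  n <- 250
  truth <- sample.int(1000, n, replace = TRUE)
  umis <- random_seqs(n, 10)
  clips <- corrupt(paste0("CTACACGACGCTCTTCCGATCT", wl[truth], umis,
                          "TTTCTTATATGGG"), error_model())
  clips <- vapply(clips, function(x) {
    L <- nchar(x)
    substr(x, max(1, L - 54), L)
  }, "")
  reads <- data.frame(read_id = as.character(seq_len(n)),
                      bc_clip = unname(clips), stringsAsFactors = FALSE)
  ab <- assign_barcodes(reads, wl)
  pass <- ab$matches$pass
  expect_gte(mean(pass), 0.90)                                    # recall
  expect_gte(mean(ab$matches$barcode[pass] == wl[truth][pass]), 0.99)
  # determinism: a second full run reproduces every assignment
  ab2 <- assign_barcodes(reads, wl)
  expect_identical(ab$matches, ab2$matches)
})
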