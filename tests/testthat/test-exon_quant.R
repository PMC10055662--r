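make_ann <- function() {
  gtf <- write_test_gtf(tempfile(fileext = ".gtf"), "g", list(
    t1 = rbind(c(101, 200), c(301, 400)),
    t2 = rbind(c(101, 150), c(301, 400))))
  parse_gtf_subexons(gtf)
}
# sub-exons: [100,150) [150,200) [300,400)

test_that("molecules are scored 1/0/NA with terminal censoring", {
  ann <- make_ann()
  g <- ann$g
  # full coverage with generous end overlaps: all spliced in
  v1 <- assign_molecule_to_subexons(iso_key(105, 395, c(200, 300)), g)
  expect_equal(v1, c(1L, 1L, 1L))
  # stops at 195 with no polyA: the downstream sub-exon is censored
  v2 <- assign_molecule_to_subexons(iso_key(105, 195), g, polyA = FALSE)
  expect_equal(v2, c(1L, 1L, NA_integer_))
  # 5' truncated molecule starting at 160: upstream sub-exon censored,
  # never scored as splice-out
  v3 <- assign_molecule_to_subexons(iso_key(160, 400, c(200, 300)), g)
  expect_equal(v3, c(NA_integer_, 1L, 1L))
  # polyA-terminated molecule: downstream sub-exons are an observed end
  v4 <- assign_molecule_to_subexons(iso_key(105, 195), g, polyA = TRUE)
  expect_equal(v4, c(1L, 1L, 0L))
  v4b <- assign_molecule_to_subexons(iso_key(105, 195), g, polyA = TRUE,
                                     polyA_terminal_zero = FALSE)
  expect_equal(v4b, c(1L, 1L, NA_integer_))
  # skipping junction scores the skipped sub-exon 0
  v5 <- assign_molecule_to_subexons(iso_key(105, 395, c(150, 300)), g)
  expect_equal(v5, c(1L, 0L, 1L))
  # terminal overlap below 10 bp is not informative
  v6 <- assign_molecule_to_subexons(iso_key(145, 395, c(200, 300)), g)
  expect_equal(v6[1], NA_integer_)
  # 1 bp slippage of an internal site is snapped to annotation
  v7 <- assign_molecule_to_subexons(iso_key(105, 395, c(151, 301)), g)
  expect_equal(v7, c(1L, 0L, 1L))
})

test_that("count matrices tally informative and inclusion counts", {
  ann <- make_ann()
  mols <- data.frame(
    cell = "c1", gene_id = "g",
    isoform = c(iso_key(105, 195),            # (1,1,NA)
                iso_key(160, 395, c(200, 300)),  # (NA,1,1)
                iso_key(105, 395, c(150, 300))), # (1,0,1)
    polyA = FALSE, stringsAsFactors = FALSE)
  incl <- inclusion_table(mols, ann)
  cm <- build_count_matrices(incl)
  cm <- cm[order(cm$exon), ]
  expect_equal(cm$G, c(2L, 3L, 2L))
  expect_equal(cm$E, c(2L, 2L, 2L))
  # E <= G always, G bounded by molecule count
  expect_true(all(cm$E <= cm$G))
  expect_true(all(cm$G <= nrow(mols)))
  # no molecules: empty matrices
  expect_equal(nrow(build_count_matrices(incl[0, ])), 0L)
})

test_that("censoring under simulated truncation never fakes a splice-out", {
  sim <- simulate_reads(n_cells = 4, mols_per_cell = 10,
                        truncation_prob = 0.6, error = error_model(0, 0, 0),
                        seed = 13)
  gtf <- write_catalog_gtf(sim$catalog, tempfile(fileext = ".gtf"))
  ann <- parse_gtf_subexons(gtf)
  gene <- ann[[sim$catalog$gene_id]]
  first_exon_end <- gene$subexons$end[1]
  r <- sim$reads
  for (i in seq_len(nrow(r))) {
    v <- assign_molecule_to_subexons(r$chain[i], gene, polyA = TRUE)
    s <- iso_blocks(r$chain[i])[1, 1]
    if (s >= first_exon_end) {
      # molecule never reached the first sub-exon: must be NA, not 0
      expect_true(is.na(v[1]))
    }
  }
})

test_that("meta-exon merging joins co-inclusive and mutually exclusive pairs", {
  # three exons; 1 and 3 in both transcripts, cassette 2 only in t1
  gtf <- write_test_gtf(tempfile(fileext = ".gtf"), "g", list(
    t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
    t2 = rbind(c(101, 200), c(501, 600))))
  ann <- parse_gtf_subexons(gtf)
  mols <- data.frame(
    cell = rep(c("c1", "c2"), each = 20), gene_id = "g",
    isoform = rep(c(iso_key(100, 600, c(200, 300, 400, 500)),
                    iso_key(100, 600, c(200, 500))), 20),
    polyA = TRUE, stringsAsFactors = FALSE)
  incl <- inclusion_table(mols, ann)
  mg <- merge_exons(incl, ann)
  # exons 1 and 3 collapse to one meta-exon, the cassette stays alone
  expect_equal(mg$map$meta[1], mg$map$meta[3])
  expect_false(mg$map$meta[2] == mg$map$meta[1])
  cm <- build_count_matrices(mg$incl)
  expect_equal(sort(unique(cm$exon)), c(1L, 2L))

  # mutually exclusive exons (never co-annotated) are merged with
  # the second recoded as exclusion of the first
  gtf2 <- write_test_gtf(tempfile(fileext = ".gtf"), "g", list(
    t1 = rbind(c(101, 200), c(301, 400), c(601, 700)),
    t2 = rbind(c(101, 200), c(451, 550), c(601, 700))))
  ann2 <- parse_gtf_subexons(gtf2)
  mols2 <- data.frame(
    cell = "c1", gene_id = "g",
    isoform = rep(c(iso_key(100, 700, c(200, 300, 400, 600)),
                    iso_key(100, 700, c(200, 450, 550, 600))), 15),
    polyA = TRUE, stringsAsFactors = FALSE)
  incl2 <- inclusion_table(mols2, ann2)
  mg2 <- merge_exons(incl2, ann2)
  # sub-exons: [100,200) [300,400) [450,550) [600,700): A=2, B=3 merge
  expect_equal(mg2$map$meta[2], mg2$map$meta[3])
  expect_true(mg2$map$recode[3])
  cm2 <- build_count_matrices(mg2$incl)
  me <- cm2[cm2$exon == mg2$map$meta[2], ]
  # meta-exon psi now means P(A): 15 of 30 molecules carry A,
  # and all 30 are informative after recoding
  expect_equal(me$G, 30L)
  expect_equal(me$E, 15L)

  # empirically co-inclusive but not co-annotated: no merge
  gtf3 <- write_test_gtf(tempfile(fileext = ".gtf"), "g", list(
    t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
    t2 = rbind(c(101, 200), c(501, 600)),
    t3 = rbind(c(301, 400))))
  ann3 <- parse_gtf_subexons(gtf3)
  mols3 <- data.frame(
    cell = "c1", gene_id = "g",
    isoform = rep(iso_key(100, 600, c(200, 300, 400, 500)), 25),
    polyA = TRUE, stringsAsFactors = FALSE)
  incl3 <- inclusion_table(mols3, ann3)
  mg3 <- merge_exons(incl3, ann3)
  # exon 2 appears alone in t3, so it is not co-annotated with 1/3
  expect_false(mg3$map$meta[2] == mg3$map$meta[1])
})
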