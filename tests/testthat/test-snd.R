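test_that("context filters discard SNDs with indels, excess differences or no outgroup", {
  cols <- filler_columns("chr1", 0, 40)
  cols <- plant(cols, 20, target = "A", query = "G", outgroup = "A")
  rec <- call_snds(cols)
  expect_equal(nrow(rec), 1)
  expect_true(rec$passed_filters)

  # gap two positions away in either sequence
  gap_q <- plant(cols, 22, query = "-")
  rec <- call_snds(gap_q)
  expect_false(rec$passed_filters)
  expect_equal(rec$filter_reason, "indel")
  gap_t <- plant(cols, 18, target = "-")
  expect_equal(call_snds(gap_t)$filter_reason, "indel")

  # three target-query differences inside the 11-bp window (focal counts)
  three <- plant(plant(cols, 18, target = "C", query = "G"),
                 23, target = "C", query = "A")
  rec <- call_snds(three)
  expect_true(all(!rec$passed_filters))
  expect_true(all(rec$filter_reason == "too_many_diffs"))

  # two differences are allowed
  two <- plant(cols, 23, target = "C", query = "A", outgroup = "C")
  rec <- call_snds(two)
  expect_true(all(rec$passed_filters))

  # missing outgroup base at the SND column
  noout <- plant(cols, 20, outgroup = ".")
  noout$outgroup_base[noout$outgroup_base == "."] <- NA
  expect_equal(call_snds(noout)$filter_reason, "no_outgroup")
})

test_that("windows truncated by a contig edge are discarded", {
  cols <- filler_columns("chr1", 0, 40)
  cols <- plant(cols, 3, target = "A", query = "G", outgroup = "A")
  rec <- call_snds(cols)
  expect_equal(rec$filter_reason, "edge")
  # non-contiguous coverage behaves like an edge
  cols2 <- filler_columns("chr1", 0, 40)
  cols2 <- plant(cols2, 20, target = "A", query = "G", outgroup = "A")
  cols2 <- cols2[cols2$pos != 23, ]
  expect_equal(call_snds(cols2)$filter_reason, "edge")
})

test_that("unsorted column input is rejected with a diagnostic", {
  cols <- filler_columns("chr1", 0, 20)
  expect_error(call_snds(cols[c(2:1, 3:21), ]), "sorted")
})

test_that("polarization assigns derivation and the weak-to-strong rule", {
  cols <- filler_columns("chr1", 0, 60)
  cols <- plant(cols, 10, target = "A", query = "G", outgroup = "A")  # derived in query, A->G
  cols <- plant(cols, 30, target = "G", query = "A", outgroup = "A")  # derived in target, A->G
  cols <- plant(cols, 50, target = "A", query = "G", outgroup = "C")  # inconclusive
  rec <- polarize_snds(call_snds(cols))
  expect_equal(rec$derivation, c("derived_in_query", "derived_in_target",
                                 "inconclusive"))
  expect_equal(rec$biased, c(TRUE, TRUE, FALSE))
  # strong-to-weak and strong-to-strong changes are never biased
  cols <- filler_columns("chr1", 0, 60)
  cols <- plant(cols, 10, target = "G", query = "A", outgroup = "G")  # G->A in query
  cols <- plant(cols, 30, target = "G", query = "C", outgroup = "G")  # G->C in query
  rec <- polarize_snds(call_snds(cols))
  expect_true(all(!rec$biased))
})

test_that("every conclusive passing SND lands in exactly one direction catalog", {
  set.seed(31)
  cols <- filler_columns("chr1", 0, 3000)
  snd_pos <- seq(20, 2980, by = 20)
  bases <- c("A", "C", "G", "T")
  for (p in snd_pos) {
    tq <- sample(bases, 2)
    og <- sample(c(tq, sample(bases, 1)), 1)
    cols <- plant(cols, p, target = tq[1], query = tq[2], outgroup = og)
  }
  rec <- polarize_snds(call_snds(cols))
  lens <- c(chr1 = 3001)
  tgt <- build_catalog(rec, "derived_in_target", lens)
  qry <- build_catalog(rec, "derived_in_query", lens)
  conclusive <- rec[rec$passed_filters & rec$derivation != "inconclusive", ]
  expect_equal(nrow(tgt$substitutions) + nrow(qry$substitutions),
               nrow(conclusive))
  expect_length(intersect(tgt$substitutions$pos, qry$substitutions$pos), 0)
  # bias rule soundness on catalog entries
  for (catal in list(tgt, qry)) {
    sub <- catal$substitutions
    expect_equal(sub$biased,
                 sub$ancestral_base %in% c("A", "T") &
                   sub$derived_base %in% c("C", "G"))
  }
})

test_that("filtering is idempotent on surviving windows", {
  set.seed(77)
  cols <- filler_columns("chr1", 0, 2000)
  for (p in seq(15, 1985, by = 15))
    cols <- plant(cols, p, target = "A", query = "G", outgroup = "A")
  rec1 <- call_snds(cols)
  keep_pos <- rec1$pos[rec1$passed_filters]
  ctx <- sort(unique(as.vector(outer(keep_pos, -5:5, `+`))))
  rec2 <- call_snds(cols[cols$pos %in% ctx, ])
  expect_equal(rec2$pos[rec2$passed_filters], keep_pos)
})

test_that("three-way TSV reading normalizes and validates", {
  path <- withr::local_tempfile()
  writeLines(c("chromosome\tposition\ttarget_base\tquery_base\toutgroup_base",
               "chr2\t100\ta\tg\ta",
               "chr2\t101\tT\tT\t."), path)
  cols <- read_threeway_tsv(path)
  expect_equal(cols$target_base, c("A", "T"))
  expect_equal(cols$query_base[1], "G")
  expect_true(is.na(cols$outgroup_base[2]))

  writeLines(c("chr2\t100\tA\tG\tA", "chr2\t50\tA"), path)
  expect_error(read_threeway_tsv(path), "line 2")
  writeLines(c("chr2\t100\tA\tG\tA", "chr2\t50\tA\tG\tA"), path)
  expect_error(read_threeway_tsv(path), "unsorted")
})

test_that("catalog construction sorts, deduplicates and checks conflicts", {
  lens <- c(chr1 = 1000, chr2 = 1000)
  df <- data.frame(chrom = c("chr2", "chr1", "chr1"), pos = c(5, 30, 10),
                   biased = c(TRUE, FALSE, TRUE))
  cc <- ubcs_catalog(df, lens)
  expect_equal(cc$substitutions$pos, c(10, 30, 5))
  expect_equal(cc$substitutions$chrom, c("chr1", "chr1", "chr2"))
  dup <- rbind(df, data.frame(chrom = "chr1", pos = 10, biased = FALSE))
  expect_error(ubcs_catalog(dup, lens), "chr1 10")
  same <- rbind(df, data.frame(chrom = "chr1", pos = 10, biased = TRUE))
  expect_equal(nrow(ubcs_catalog(same, lens)$substitutions), 3)
  expect_error(ubcs_catalog(data.frame(chrom = "chrX", pos = 1, biased = TRUE),
                            lens), "without a length")
})
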