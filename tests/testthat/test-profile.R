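test_that("observed flags match the examples of the window classification", {
  par <- cluster_params()
  lens <- c(chr1 = 1000)
  # 6 substitutions, 5 weak-to-strong: every substitution is a BCS
  b6 <- ubcs_catalog(data.frame(chrom = "chr1", pos = c(10, 50, 100, 150, 200, 250),
                                biased = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
                     lens)
  expect_equal(sum(observed_bcs_flags(b6, "chr1", par)), 6)
  # 4 substitutions: clustered threshold not reached, none flagged
  c4 <- ubcs_catalog(data.frame(chrom = "chr1", pos = c(10, 50, 100, 150),
                                biased = rep(TRUE, 4)), lens)
  expect_equal(sum(observed_bcs_flags(c4, "chr1", par)), 0)
  # 6 substitutions, 50% weak-to-strong: clustered but not biased
  a6 <- ubcs_catalog(data.frame(chrom = "chr1", pos = c(10, 50, 100, 150, 200, 250),
                                biased = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
                     lens)
  expect_equal(sum(observed_bcs_flags(a6, "chr1", par)), 0)
})

test_that("observed flags equal the exhaustive window scan on random catalogs", {
  set.seed(29)
  par <- cluster_params()
  for (i in 1:60) {
    n <- sample(1:18, 1)
    pos <- sort(sample(0:900, n))
    lab <- runif(n) < 0.5
    d <- sample(c(1L, 150L), 1)
    pr <- cluster_params(start_divisor = d)
    cc <- ubcs_catalog(data.frame(chrom = "chr1", pos = pos, biased = lab),
                       c(chr1 = 2000))
    expect_equal(as.logical(observed_bcs_flags(cc, "chr1", pr)),
                 oracle_observed_flags(pos, lab, pr, 2000))
  }
})

test_that("coarser window grids flag a subset of the substitutions", {
  set.seed(37)
  for (i in 1:20) {
    pos <- sort(sample(0:2000, 40))
    lab <- runif(40) < 0.6
    cc <- ubcs_catalog(data.frame(chrom = "chr1", pos = pos, biased = lab),
                       c(chr1 = 3000))
    f1 <- observed_bcs_flags(cc, "chr1", cluster_params(start_divisor = 1))
    f150 <- observed_bcs_flags(cc, "chr1", cluster_params(start_divisor = 150))
    expect_true(all(f1[f150]))
  }
})

test_that("p-hat is the biased fraction and NA for empty regions", {
  lens <- c(chr1 = 3e6)
  cc <- ubcs_catalog(data.frame(chrom = "chr1",
                                pos = seq(1e5, 1e6 - 1e5, length.out = 10),
                                biased = rep(c(TRUE, FALSE), c(7, 3))), lens)
  expect_equal(estimate_p_hat(cc, "chr1", 0, 1e6), 0.7)
  expect_true(is.na(estimate_p_hat(cc, "chr1", 2e6, 3e6)))
  allb <- ubcs_catalog(data.frame(chrom = "chr1", pos = c(10, 20),
                                  biased = TRUE), lens)
  expect_equal(estimate_p_hat(allb, "chr1", 0, 1e6), 1)
})

test_that("region statistics compose observed, expected and their difference", {
  par <- cluster_params()
  lens <- c(chr1 = 1e6)
  # no window reaches min_cluster: observed = expected = 0
  sparse <- ubcs_catalog(data.frame(chrom = "chr1",
                                    pos = seq(1e3, 9e5, length.out = 8),
                                    biased = TRUE), lens)
  rs <- ubcs_region(sparse, "chr1", 0, par)
  expect_equal(rs$observed, 0)
  expect_equal(rs$expected, 0)
  expect_equal(rs$ubcs, 0)
  # one 5-substitution cluster, all biased, plus 5 isolated unbiased
  # substitutions: p-hat = 0.5, observed 5, expected 5 * 0.1875
  pos <- c(100, 150, 200, 250, 300, seq(2e5, 9e5, length.out = 5))
  cc <- ubcs_catalog(data.frame(chrom = "chr1", pos = pos,
                                biased = rep(c(TRUE, FALSE), c(5, 5))), lens)
  rs <- ubcs_region(cc, "chr1", 0, par)
  expect_equal(rs$p_hat, 0.5)
  expect_equal(rs$observed, 5)
  expect_equal(rs$expected, 5 * 0.1875, tolerance = 1e-12)
  expect_equal(rs$ubcs, 5 - 5 * 0.1875, tolerance = 1e-12)
})

test_that("profiles tile chromosomes and mark partial tail regions", {
  par <- cluster_params()
  cc <- ubcs_catalog(data.frame(chrom = "chr1", pos = c(100, 2.2e6),
                                biased = TRUE),
                     c(chr1 = 3e6, chr2 = 2.5e6))
  prof <- ubcs_profile(cc, par)
  expect_equal(sum(prof$chrom == "chr1"), 3)
  expect_equal(sum(prof$chrom == "chr2"), 3)
  expect_equal(prof$partial, c(rep(FALSE, 5), TRUE))
  expect_equal(prof$region_end[6], 2.5e6)
  expect_equal(sum(prof$n_subs), 2)
  expect_equal(attr(prof, "direction"), "derived_in_target")
})

test_that("profile observed counts recount the chromosome-wide flags", {
  set.seed(41)
  par <- cluster_params()
  pos <- sort(sample(0:(3e6 - 1), 600))
  lab <- runif(600) < 0.6
  cc <- ubcs_catalog(data.frame(chrom = "chr1", pos = pos, biased = lab),
                     c(chr1 = 3e6))
  prof <- ubcs_profile(cc, par)
  expect_equal(sum(prof$observed),
               sum(observed_bcs_flags(cc, "chr1", par)))
  expect_equal(sum(prof$n_subs), 600)
  expect_true(all(prof$observed <= prof$n_subs))
  expect_true(all(prof$expected >= 0 & prof$expected <= prof$n_subs))
  expect_equal(prof$ubcs, prof$observed - prof$expected)
})
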