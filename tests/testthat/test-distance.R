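test_that("arm windows are ordered from the telomere end inward", {
  lens <- c(chr1 = 5e6)
  prof <- fake_profile(lens, function(ch, s) s / 1e6 + 1)  # 1,2,3,4,5
  expect_equal(arm_ubcs_values(prof, "chr1", "p", 3), c(1, 2, 3))
  expect_equal(arm_ubcs_values(prof, "chr1", "q", 3), c(5, 4, 3))
  expect_error(arm_ubcs_values(prof, "chr2", "p", 3), "missing")
  expect_error(arm_ubcs_values(prof, "chr1", "p", 9), "fewer than")
})

test_that("telomere proportions are ratios of window sums", {
  lens <- c(chr1 = 21e6)
  py <- fake_profile(lens, function(ch, s) 2 + s / 1e7)
  expect_equal(arm_proportion(py, py, "chr1", "p", 10), 1)
  px2 <- fake_profile(lens, function(ch, s) 2 * (2 + s / 1e7))
  expect_equal(arm_proportion(px2, py, "chr1", "p", 10), 2)
  zero <- fake_profile(lens, function(ch, s) 0)
  expect_true(is.na(arm_proportion(py, zero, "chr1", "p", 10)))
})

test_that("the distance is the median telomere proportion over the control sets", {
  lens <- setNames(rep(21e6, 22), paste0("chr", 1:22))
  base <- fake_profile(lens, function(ch, s) 3)
  x15 <- fake_profile(lens, function(ch, s) 4.5)
  d <- ubcs_distance(x15, base)
  expect_equal(d$proportion, 1.5)
  expect_equal(nrow(d$telomeres), 28)
  # per-telomere multipliers: median of {1,2,3} style sets
  mult <- setNames(rep(2, 22), paste0("chr", 1:22))
  mult[c("chr1", "chr4")] <- 1
  mult[c("chr5", "chr6")] <- 3
  px <- fake_profile(lens, function(ch, s) 3 * mult[[ch]])
  d <- ubcs_distance(px, base)
  expect_equal(d$proportion, 2)
})

test_that("the distance scales with the numerator and is scale invariant", {
  set.seed(43)
  lens <- setNames(rep(21e6, 22), paste0("chr", 1:22))
  vals <- new.env()
  rnd <- fake_profile(lens, function(ch, s) 1 + runif(1))
  rnd2 <- fake_profile(lens, function(ch, s) 1 + runif(1))
  d0 <- ubcs_distance(rnd, rnd2)$proportion
  scale_both <- function(p, k) { p$ubcs <- p$ubcs * k; p }
  expect_equal(ubcs_distance(scale_both(rnd, 7), scale_both(rnd2, 7))$proportion, d0)
  expect_equal(ubcs_distance(scale_both(rnd, 3), rnd2)$proportion, 3 * d0)
  # constant-ratio symmetry: forward and reverse distances are reciprocal
  k <- 1.7
  px <- scale_both(rnd2, k)
  expect_equal(ubcs_distance(px, rnd2)$proportion *
                 ubcs_distance(rnd2, px)$proportion, 1, tolerance = 1e-12)
})

test_that("telomeres with non-positive denominators are excluded with a warning", {
  lens <- setNames(rep(21e6, 22), paste0("chr", 1:22))
  base <- fake_profile(lens, function(ch, s) if (ch == "chr1") -1 else 3)
  px <- fake_profile(lens, function(ch, s) 6)
  expect_warning(d <- ubcs_distance(px, base), "non-positive")
  # chr1 contributes both a p-arm and a q-arm control telomere
  expect_equal(sum(!d$telomeres$defined), 2)
  expect_equal(d$proportion, 2)
  zero <- fake_profile(lens, function(ch, s) 0)
  expect_error(suppressWarnings(ubcs_distance(px, zero)), "undefined")
})

test_that("bootstrap confidence intervals are seeded and degenerate correctly", {
  set.seed(47)
  lens <- setNames(rep(21e6, 22), paste0("chr", 1:22))
  py <- fake_profile(lens, function(ch, s) 2 + runif(1))
  px <- fake_profile(lens, function(ch, s) 3 + runif(1))
  b1 <- bootstrap_distance(px, py, seed = 123)
  b2 <- bootstrap_distance(px, py, seed = 123)
  b3 <- bootstrap_distance(px, py, seed = 124)
  expect_identical(b1$ci, b2$ci)
  expect_false(identical(b1$ci, b3$ci))
  expect_true(b1$ci[1] <= b1$proportion && b1$proportion <= b1$ci[2])
  # identical window ratios everywhere: zero-width interval
  const_x <- fake_profile(lens, function(ch, s) 4)
  const_y <- fake_profile(lens, function(ch, s) 2)
  bc <- bootstrap_distance(const_x, const_y, seed = 1)
  expect_equal(bc$ci, c(2, 2))
})

test_that("proportions rescale linearly to speciation times", {
  expect_equal(speciation_time(1.0, 6)$time_mya, 6)
  expect_equal(speciation_time(1.5, 6)$time_mya, 9)
  est <- structure(list(proportion = 1.0, ci = c(0.9, 1.1)),
                   class = "ubcs_distance")
  st <- speciation_time(est, 6)
  expect_equal(st$time_mya, 6)
  expect_equal(st$ci_mya, c(5.4, 6.6))
})
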