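test_that("binomial upper tail handles boundaries and matches hand sums", {
  expect_equal(binom_from(5, 0, 0.3), 1)
  expect_equal(binom_from(3, 4, 0.9), 0)
  expect_equal(binom_from(5, 4, 0.5), 6 / 32)
  expect_error(binom_from(5, 2, 1.2), "p must be")
})

test_that("bin-frequency enumeration covers the full Cartesian product and normalizes", {
  f <- generate_bin_frequencies(1, 0.5)
  expect_equal(lapply(f, `[[`, "freq"), list(0L, 1L))
  expect_equal(vapply(f, `[[`, numeric(1), "prob"), c(0.5, 0.5))

  f <- generate_bin_frequencies(c(1, 1), 0.5)
  expect_length(f, 4)
  expect_equal(vapply(f, `[[`, numeric(1), "prob"), rep(0.25, 4))

  f <- generate_bin_frequencies(c(2, 3), 0.7)
  expect_length(f, 12)
  expect_equal(sum(vapply(f, `[[`, numeric(1), "prob")), 1, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    sizes <- sample(0:4, sample(1:4, 1), replace = TRUE)
    p <- runif(1)
    f <- generate_bin_frequencies(sizes, p)
    expect_length(f, prod(sizes + 1))
    expect_equal(sum(vapply(f, `[[`, numeric(1), "prob")), 1,
                 tolerance = 1e-12)
  }
})

test_that("representative-window selection matches the enumeration oracle", {
  par <- cluster_params()
  # isolated focal substitution
  expect_length(select_representative_windows(c(500), 1, par, 2000), 0)
  # only 3 other substitutions within reach
  expect_length(select_representative_windows(c(100, 150, 200, 250), 2, par, 2000), 0)
  # 5 substitutions inside one span: a single representative remains
  pos5 <- c(100, 150, 200, 250, 300)
  st <- select_representative_windows(pos5, 3, par, 2000)
  expect_length(st, 1)
  expect_equal(st, oracle_representative_windows(pos5, 3, par, 2000))

  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:14, 1)
    pos <- sort(sample(0:700, n))
    f <- sample(n, 1)
    pr <- cluster_params(start_divisor = sample(c(1L, 150L), 1))
    got <- select_representative_windows(pos, f, pr, 2000)
    expect_equal(got, oracle_representative_windows(pos, f, pr, 2000))
    # upper bound: at most one representative per covering substitution
    cover <- sum(pos >= pos[f] - 299 & pos <= pos[f] + 299)
    expect_lte(length(got), cover)
  }
})

test_that("bin compression reproduces window counts and centres the focal bin", {
  par <- cluster_params()
  pos5 <- c(100, 150, 200, 250, 300)
  st <- select_representative_windows(pos5, 3, par, 2000)
  b <- compress_to_bins(st, pos5, par)
  expect_equal(as.integer(b), 5L)

  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:14, 1)
    pos <- sort(sample(0:700, n))
    f <- sample(n, 1)
    st <- select_representative_windows(pos, f, par, 2000)
    if (length(st) == 0) next
    b <- compress_to_bins(st, pos, par)
    nw <- length(st)
    expect_length(b, 2 * nw - 1)
    # cluster k (bins k..k+n-1) recounts representative window k
    for (k in seq_len(nw)) {
      recount <- sum(pos >= st[k] & pos < st[k] + par$window_size)
      expect_equal(sum(b[k:(k + nw - 1)]), recount)
      expect_gte(recount, par$min_cluster)
    }
    # focal substitution sits in the middle bin
    bounds <- sort(c(st, st + par$window_size))
    mid <- c(bounds[nw], bounds[nw + 1])
    expect_true(pos[f] >= mid[1] && pos[f] < mid[2])
  }
})

test_that("union probability matches closed forms and degenerate limits", {
  par <- cluster_params()
  expect_equal(prob_bcs(5L, 0.5, par), 6 / 32)        # single-cluster tail
  expect_equal(prob_bcs(integer(0), 0.5, par), 0)     # empty window set
  expect_equal(prob_bcs(c(2L, 3L, 2L), 0, par), 0)
  expect_equal(prob_bcs(c(2L, 3L, 2L), 1, par), 1)
  # nondecreasing in p
  probs <- vapply(seq(0, 1, by = 0.1), function(p)
    prob_bcs(c(2L, 3L, 2L), p, par), numeric(1))
  expect_true(all(diff(probs) >= -1e-12))
})

test_that("dynamic program equals brute-force enumeration on random instances", {
  set.seed(17)
  par <- cluster_params()
  # the quoted two-window case
  pos <- c(0, 40, 150, 260, 280, 299, 420)
  for (f in 3:5) {
    st <- select_representative_windows(pos, f, par, 2000)
    dp <- prob_bcs(compress_to_bins(st, pos, par), 0.4, par)
    expect_equal(dp, brute_force_prob_bcs(pos, f, 0.4, par, 2000),
                 tolerance = 1e-12)
  }
  for (i in 1:60) {
    n <- sample(5:12, 1)
    pos <- sort(sample(0:600, n))
    f <- sample(n, 1)
    p <- runif(1)
    pr <- cluster_params(start_divisor = sample(c(1L, 150L), 1))
    st <- select_representative_windows(pos, f, pr, 2000)
    dp <- if (length(st) == 0) 0 else
      prob_bcs(compress_to_bins(st, pos, pr), p, pr)
    expect_equal(dp, brute_force_prob_bcs(pos, f, p, pr, 2000),
                 tolerance = 1e-9)
  }
})

test_that("brute-force oracle honours its own contracts", {
  par <- cluster_params()
  expect_equal(brute_force_prob_bcs(c(500), 1, 0.5, par, 2000), 0)
  pos5 <- c(100, 150, 200, 250, 300)
  expect_equal(brute_force_prob_bcs(pos5, 3, 0.5, par, 2000), 6 / 32)
  expect_equal(brute_force_prob_bcs(pos5, 3, 1, par, 2000), 1)
  expect_error(brute_force_prob_bcs(0:30 * 10, 15, 0.5, par, 2000),
               "enumeration cap")
})

test_that("denser window grids cannot decrease the union probability", {
  set.seed(19)
  d1 <- cluster_params(start_divisor = 1)
  d150 <- cluster_params(start_divisor = 150)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    pos <- sort(sample(0:600, n))
    f <- sample(n, 1)
    p <- runif(1)
    pr_fine <- {
      st <- select_representative_windows(pos, f, d1, 2000)
      if (length(st) == 0) 0 else prob_bcs(compress_to_bins(st, pos, d1), p, d1)
    }
    pr_coarse <- {
      st <- select_representative_windows(pos, f, d150, 2000)
      if (length(st) == 0) 0 else prob_bcs(compress_to_bins(st, pos, d150), p, d150)
    }
    expect_gte(pr_fine, pr_coarse - 1e-12)
  }
})

test_that("dense covering regions fall back to a seeded Monte-Carlo estimate", {
  par <- cluster_params(c_max = 10, mc_draws = 20000L)
  bins <- c(4L, 8L, 4L)  # 16 substitutions > c_max
  set.seed(23)
  expect_warning(mc1 <- prob_bcs(bins, 0.6, par), "Monte-Carlo")
  set.seed(23)
  mc2 <- suppressWarnings(prob_bcs(bins, 0.6, par))
  expect_identical(mc1, mc2)  # seeded reproducibility
  exact <- prob_bcs(bins, 0.6, cluster_params())
  expect_equal(mc1, exact, tolerance = 0.02)
})
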