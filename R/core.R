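#' Representative windows around a focal substitution
#'
#' Candidate windows are the `window_size` bp windows whose start is a
#' multiple of `start_divisor` and which contain the focal substitution.
#' Windows with fewer than `min_cluster` substitutions have zero
#' probability of being a biased cluster and are dropped; windows
#' containing the same substitution set are collapsed to one witness
#' (the smallest start).  The number of representative windows is
#' bounded by the number of substitutions in the covering region.
#'
#' @param positions Sorted substitution coordinates on one chromosome.
#' @param focal_index Index (1-based) of the focal substitution.
#' @param params A [cluster_params()] object.
#' @param chrom_len Chromosome length in bp, or `NULL` for no right
#'   bound.  Windows must lie entirely inside `[0, chrom_len)`.
#' @return Numeric vector of representative window start coordinates
#'   (possibly empty).
#' @export
select_representative_windows <- function(positions, focal_index,
                                          params = cluster_params(),
                                          chrom_len = NULL) {
  stopifnot(focal_index >= 1, focal_index <= length(positions),
            !is.unsorted(positions))
  res <- cpp_select_windows(as.numeric(positions), as.integer(focal_index),
                            params$window_size, params$min_cluster,
                            params$start_divisor,
                            if (is.null(chrom_len)) -1 else as.numeric(chrom_len))
  res$starts
}

#' Compress representative windows to a bin vector
#'
#' The ordered starts and ends of the n representative windows delimit
#' 2n-1 bins; each bin stores the number of substitutions it contains.
#' Cluster k (bins k..k+n-1) reproduces the substitution count of the
#' k-th representative window, and the focal substitution lies in the
#' middle bin.
#'
#' @param window_starts Sorted start coordinates of the representative
#'   windows.
#' @param positions Sorted substitution coordinates.
#' @param params A [cluster_params()] object.
#' @return Integer vector of 2n-1 bin sizes with attribute `n_windows`.
#' @export
compress_to_bins <- function(window_starts, positions,
                             params = cluster_params()) {
  stopifnot(length(window_starts) >= 1, !is.unsorted(window_starts))
  b <- cpp_compress_bins(as.numeric(window_starts), as.numeric(positions),
                         params$window_size)
  structure(b, n_windows = length(window_starts))
}

#' Binomial upper-tail probability
#'
#' Probability that a bin of `bin_size` substitutions contains
#' `start_size` or more biased substitutions when labels are independent
#' Bernoulli(p).
#'
#' @param bin_size Number of substitutions in the bin.
#' @param start_size Minimal number of biased substitutions.
#' @param p Bias probability in `[0, 1]`.
#' @return `P(K >= start_size)` for `K ~ Binomial(bin_size, p)`; 1 when
#'   `start_size <= 0`, 0 when `start_size > bin_size`.
#' @export
binom_from <- function(bin_size, start_size, p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  stopifnot(all(bin_size >= 0))
  ifelse(start_size <= 0, 1,
         ifelse(start_size > bin_size, 0,
                pbinom(start_size - 1, bin_size, p, lower.tail = FALSE)))
}

#' Enumerate joint bin frequencies of biased substitutions
#'
#' Generates, for bins of sizes `bin_sizes` with independent
#' Bernoulli(p) labels, every vector x with `0 <= x_i <= b_i` (the full
#' Cartesian product of ranges) together with its joint probability
#' `prod_i C(b_i, x_i) p^x_i (1-p)^(b_i - x_i)`.  The probabilities sum
#' to one.
#'
#' @param bin_sizes Nonnegative integer bin sizes.
#' @param p Bias probability.
#' @return A list of 2-element lists `list(freq = x, prob = pr)`.
#' @export
generate_bin_frequencies <- function(bin_sizes, p) {
  stopifnot(all(bin_sizes >= 0), p >= 0, p <= 1)
  grid <- expand.grid(lapply(bin_sizes, function(b) 0:b),
                      KEEP.OUT.ATTRS = FALSE)
  probs <- rep(1, nrow(grid))
  for (j in seq_along(bin_sizes))
    probs <- probs * dbinom(grid[[j]], bin_sizes[j], p)
  lapply(seq_len(nrow(grid)), function(i)
    list(freq = as.integer(grid[i, ]), prob = probs[i]))
}

#' Probability that the focal substitution is biased clustered
#'
#' Computes `P(A_1 u ... u A_n)` where `A_k` is the event that cluster k
#' (bins k..k+n-1 of the compressed representation) holds at least a
#' fraction `bias_threshold` of biased substitutions, labels being
#' independent Bernoulli(p).  Evaluated exactly by the telescoping sum
#' `P(A_1) + P(A_2 & !A_1) + ...` with dynamic programming over the
#' joint bin frequencies; when the covering region holds more than
#' `params$c_max` substitutions a seeded Monte-Carlo estimate with
#' `params$mc_draws` label draws is used instead (with a warning).
#'
#' @param bins Bin vector from [compress_to_bins()], or any odd-length
#'   vector of bin sizes.  An empty window set (`length(bins) == 0`)
#'   yields 0.
#' @param p Bias probability in `[0, 1]`.
#' @param params A [cluster_params()] object.
#' @return The union probability in `[0, 1]`.
#' @export
prob_bcs <- function(bins, p, params = cluster_params()) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (length(bins) == 0) return(0)
  if (length(bins) %% 2 != 1) stop("bin vector must have odd length 2n-1")
  if (sum(bins) > params$c_max)
    warning("covering region holds ", sum(bins), " > c_max = ", params$c_max,
            " substitutions; using Monte-Carlo estimate with ",
            params$mc_draws, " draws")
  cpp_prob_bcs(as.integer(bins), p, params$thr_num, params$thr_den,
               params$c_max, params$mc_draws)
}

#' Brute-force union probability by label enumeration
#'
#' Independent verification oracle for [prob_bcs()]: enumerates all
#' `2^s` bias-label assignments of the `s` substitutions in the covering
#' region of the focal substitution and sums the Bernoulli(p)
#' probabilities of the assignments under which some admissible window
#' containing the focal substitution holds at least `min_cluster`
#' substitutions with at least a fraction `bias_threshold` biased.
#' Candidate windows are enumerated directly (no compression).
#'
#' @param positions Sorted substitution coordinates.
#' @param focal_index Index (1-based) of the focal substitution.
#' @param p Bias probability.
#' @param params A [cluster_params()] object.
#' @param chrom_len Optional chromosome length (windows must fit inside).
#' @param max_subs Enumeration cap on the covering-region size
#'   (default 20).
#' @return The exact union probability (up to floating-point summation).
#' @export
brute_force_prob_bcs <- function(positions, focal_index, p,
                                 params = cluster_params(),
                                 chrom_len = NULL, max_subs = 20L) {
  stopifnot(!is.unsorted(positions))
  m <- params$window_size
  d <- params$start_divisor
  pf <- positions[focal_index]
  cover <- which(positions >= pf - m + 1 & positions <= pf + m - 1)
  s <- length(cover)
  if (s > max_subs)
    stop("covering region holds ", s, " substitutions; enumeration cap is ",
         max_subs)
  # admissible candidate windows containing the focal substitution
  s_low <- max(0, pf - m + 1)
  first <- ceiling(s_low / d) * d
  if (first > pf) return(0)
  starts <- seq(first, pf, by = d)
  if (!is.null(chrom_len)) starts <- starts[starts + m <= chrom_len]
  wins <- lapply(starts, function(st)
    which(positions[cover] >= st & positions[cover] < st + m))
  wins <- wins[lengths(wins) >= params$min_cluster]
  if (length(wins) == 0) return(0)
  labels <- as.matrix(expand.grid(rep(list(0:1), s), KEEP.OUT.ATTRS = FALSE))
  event <- rep(FALSE, nrow(labels))
  for (wn in wins) {
    cnt <- length(wn)
    bc <- rowSums(labels[, wn, drop = FALSE])
    event <- event | (bc * params$thr_den >= params$thr_num * cnt)
  }
  k <- rowSums(labels)
  sum((p^k * (1 - p)^(s - k))[event])
}
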