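#' Clustering parameters for the UBCS statistic
#'
#' Bundles the window geometry and bias threshold that define clustered
#' (CS) and biased clustered (BCS) substitutions.  A substitution is a CS
#' when it lies in some `window_size` bp window holding at least
#' `min_cluster` substitutions, and a BCS when such a window additionally
#' holds at least a fraction `bias_threshold` of weak-to-strong
#' substitutions.  Candidate windows start at multiples of
#' `start_divisor`; with the default of 1 every possible window is
#' considered (the exact mode), while `start_divisor = 150` reproduces
#' the coarser historical scheme of windows anchored at multiples of half
#' the window size.
#'
#' @param window_size Window length m in bp (default 300).
#' @param min_cluster Minimal number of substitutions in a qualifying
#'   window (default 5, i.e. the focal substitution plus at least four
#'   others).
#' @param bias_threshold Minimal fraction of weak-to-strong substitutions
#'   in a qualifying window (default 0.8).  Compared by exact integer
#'   arithmetic so that e.g. 4 biased out of 5 passes an 80% threshold.
#' @param start_divisor Window starts are multiples of this divisor
#'   (default 1).  Must divide `window_size` or equal 1.
#' @param region_size Size in bp of the disjoint regions over which the
#'   statistic is aggregated (default 1e6).
#' @param c_max Maximal number of substitutions in the covering region of
#'   a focal substitution for which the exact dynamic program is used
#'   (default 22); denser clusters fall back to a seeded Monte-Carlo
#'   estimate of the union probability.
#' @param mc_draws Number of Monte-Carlo label draws for the fallback
#'   (default 1e5).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(window_size = 300L, min_cluster = 5L,
                           bias_threshold = 0.8, start_divisor = 1L,
                           region_size = 1e6, c_max = 22L,
                           mc_draws = 1e5L) {
  window_size <- as.integer(window_size)
  min_cluster <- as.integer(min_cluster)
  start_divisor <- as.integer(start_divisor)
  stopifnot(window_size > 0, min_cluster >= 1,
            bias_threshold > 0, bias_threshold <= 1,
            start_divisor >= 1, start_divisor <= window_size,
            region_size > 0, c_max >= 1, mc_draws >= 1)
  if (window_size %% start_divisor != 0)
    stop("start_divisor must divide window_size")
  # exact rational form of the threshold for integer comparisons
  thr_den <- 1e6
  thr_num <- round(bias_threshold * thr_den)
  structure(list(window_size = window_size, min_cluster = min_cluster,
                 bias_threshold = bias_threshold, start_divisor = start_divisor,
                 region_size = region_size, c_max = c_max,
                 mc_draws = as.integer(mc_draws),
                 thr_num = thr_num, thr_den = thr_den),
            class = "cluster_params")
}

#' Control telomere sets for the divergence-proportion estimator
#'
#' The p-arm and q-arm control chromosomes exclude the short arms of the
#' acrocentric chromosomes and arms rearranged between human and the
#' other Great Apes.
#'
#' @param ct_p Chromosomes whose p-arm telomeres are used (default
#'   1, 4, 5, 6, 8, 10, 12, 16, 17, 19).
#' @param ct_q Chromosomes whose q-arm telomeres are used (default all
#'   autosomes except 15, 18, 19 and 20).
#' @param autosomes The full autosome list (default 1..22).
#' @return An object of class `control_sets`.
#' @export
control_sets <- function(ct_p = c(1, 4, 5, 6, 8, 10, 12, 16, 17, 19),
                         ct_q = setdiff(1:22, c(15, 18, 19, 20)),
                         autosomes = 1:22) {
  ct_p <- chrom_name(ct_p)
  ct_q <- chrom_name(ct_q)
  autosomes <- chrom_name(autosomes)
  stopifnot(length(ct_p) > 0, length(ct_q) > 0,
            all(ct_p %in% autosomes), all(ct_q %in% autosomes))
  structure(list(ct_p = ct_p, ct_q = ct_q, autosomes = autosomes),
            class = "control_sets")
}

#' Enumerate the control telomeres of a control set
#'
#' @param control A [control_sets()] object.
#' @return A data frame with columns `chrom` and `arm` ("p" or "q"), one
#'   row per control telomere (28 under the defaults).
#' @export
control_telomeres <- function(control = control_sets()) {
  data.frame(chrom = c(control$ct_p, control$ct_q),
             arm = rep(c("p", "q"), c(length(control$ct_p), length(control$ct_q))),
             stringsAsFactors = FALSE)
}

#' Parameters of the UBCS-proportion divergence estimator
#'
#' @param M Number of 1 Mb telomeric windows summed per arm (default 10).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param telomere_draw Telomeres drawn with replacement per replicate
#'   (default 15).
#' @param window_draw Window offsets drawn with replacement per replicate
#'   (default 8 of the M windows).
#' @param trim_fraction Total fraction of extreme replicate values
#'   removed before taking the confidence interval (default 0.05, split
#'   evenly between the tails).
#' @param split_time Human-chimpanzee split time in Mya used to scale
#'   proportions to absolute times (default 6).
#' @return An object of class `distance_params`.
#' @export
distance_params <- function(M = 10L, n_boot = 1000L, telomere_draw = 15L,
                            window_draw = 8L, trim_fraction = 0.05,
                            split_time = 6) {
  M <- as.integer(M)
  stopifnot(M >= 1, n_boot >= 1, telomere_draw >= 1,
            window_draw >= 1, window_draw <= M,
            trim_fraction >= 0, trim_fraction < 1, split_time > 0)
  structure(list(M = M, n_boot = as.integer(n_boot),
                 telomere_draw = as.integer(telomere_draw),
                 window_draw = as.integer(window_draw),
                 trim_fraction = trim_fraction, split_time = split_time),
            class = "distance_params")
}

#' Parameters of the fusion-time estimator
#'
#' @param fusion_site Coordinate of the ancestral fusion point on the
#'   fused chromosome (default chr2:113,500,000).
#' @param fusion_chrom Name of the fused chromosome (default "chr2").
#' @param interval_offset Offset in bp of the interior control interval
#'   from the telomere end (default 5 Mb).
#' @param region_sizes Interval lengths L swept for robustness (default
#'   15 to 20 Mb in 1 Mb steps).
#' @param control_chroms Chromosomes whose telomeres (both arms)
#'   calibrate the rescaling factor (default 1..12, 16, 17).
#' @param split_time Human-chimpanzee split time in Mya (default 6).
#' @param sides Which flanks of the fusion site enter the signal ratio:
#'   "both" (default), "proximal" (left of the site) or "distal".
#' @param n_boot Bootstrap replicates for the confidence interval
#'   (default 1000).
#' @param trim_fraction Total fraction of extreme replicate values
#'   removed (default 0.05).
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(fusion_site = 113.5e6, fusion_chrom = "chr2",
                          interval_offset = 5e6,
                          region_sizes = seq(15e6, 20e6, by = 1e6),
                          control_chroms = c(1:12, 16, 17),
                          split_time = 6, sides = c("both", "proximal", "distal"),
                          n_boot = 1000L, trim_fraction = 0.05) {
  sides <- match.arg(sides)
  stopifnot(fusion_site > 0, interval_offset >= 0, all(region_sizes > 0),
            length(control_chroms) > 0, split_time > 0)
  structure(list(fusion_site = fusion_site, fusion_chrom = fusion_chrom,
                 interval_offset = interval_offset,
                 region_sizes = region_sizes,
                 control_chroms = chrom_name(control_chroms),
                 split_time = split_time, sides = sides,
                 n_boot = as.integer(n_boot), trim_fraction = trim_fraction),
            class = "fusion_params")
}

# normalize chromosome identifiers ("2" -> "chr2"; "chr2" unchanged)
chrom_name <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# trimmed-range confidence interval: drop the trim/2 most extreme values
# from each tail and return the range of the remainder
trimmed_range_ci <- function(values, trim_fraction) {
  v <- sort(values[is.finite(values)])
  n <- length(v)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- floor(n * trim_fraction / 2)
  v <- v[(k + 1):(n - k)]
  range(v)
}
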