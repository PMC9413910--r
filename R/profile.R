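#' Observed biased-clustered-substitution flags
#'
#' A substitution is flagged as an observed BCS when some admissible
#' window (length `window_size`, start a multiple of `start_divisor`,
#' inside the chromosome) containing it holds at least `min_cluster`
#' substitutions of which at least a fraction `bias_threshold` carry the
#' weak-to-strong label.  The flagged substitution itself need not be
#' biased.
#'
#' @param catalog A [ubcs_catalog()].
#' @param chromosome Chromosome name.
#' @param params A [cluster_params()] object.
#' @return Logical vector, one flag per substitution of the chromosome
#'   in position order.
#' @export
observed_bcs_flags <- function(catalog, chromosome, params = cluster_params()) {
  stopifnot(inherits(catalog, "ubcs_catalog"))
  df <- catalog$substitutions
  sel <- df$chrom == chromosome
  cpp_observed_flags(df$pos[sel], as.integer(df$biased[sel]),
                     params$window_size, params$min_cluster,
                     params$thr_num, params$thr_den, params$start_divisor,
                     catalog$chrom_lengths[[chromosome]])
}

#' Proportion of biased substitutions in a region
#'
#' @param catalog A [ubcs_catalog()].
#' @param chromosome Chromosome name.
#' @param start,end Half-open region bounds in bp.
#' @return The fraction of substitutions in `[start, end)` that are
#'   biased, or `NA` when the region holds no substitutions.
#' @export
estimate_p_hat <- function(catalog, chromosome, start, end) {
  df <- catalog$substitutions
  sel <- df$chrom == chromosome & df$pos >= start & df$pos < end
  if (!any(sel)) return(NA_real_)
  mean(df$biased[sel])
}

# per-chromosome region statistics; clusters are chromosome-wide while
# p-hat is taken from the region containing each focal substitution
profile_chromosome <- function(pos, biased, chrom_len, params) {
  rs <- params$region_size
  n_regions <- max(1L, as.integer(ceiling(chrom_len / rs)))
  starts <- (seq_len(n_regions) - 1) * rs
  ends <- pmin(starts + rs, chrom_len)
  n_subs <- integer(n_regions)
  p_hat <- rep(NA_real_, n_regions)
  observed <- numeric(n_regions)
  expected <- numeric(n_regions)
  if (length(pos) > 0) {
    region_idx <- pmin(floor(pos / rs) + 1L, n_regions)
    n_subs <- tabulate(region_idx, nbins = n_regions)
    sums <- tabulate(region_idx[biased], nbins = n_regions)
    p_hat <- ifelse(n_subs > 0, sums / n_subs, NA_real_)
    flags <- cpp_observed_flags(pos, as.integer(biased), params$window_size,
                                params$min_cluster, params$thr_num,
                                params$thr_den, params$start_divisor, chrom_len)
    observed <- tabulate(region_idx[flags], nbins = n_regions)
    pvec <- p_hat[region_idx]
    probs <- cpp_expected_probs(pos, pvec, params$window_size,
                                params$min_cluster, params$thr_num,
                                params$thr_den, params$start_divisor,
                                chrom_len, params$c_max, params$mc_draws)
    n_mc <- attr(probs, "n_mc")
    if (!is.null(n_mc) && n_mc > 0)
      message("ubcs: ", n_mc, " substitution(s) above c_max used the ",
              "Monte-Carlo fallback")
    rs_sum <- rowsum(as.numeric(probs), region_idx)
    expected <- numeric(n_regions)
    expected[as.integer(rownames(rs_sum))] <- rs_sum[, 1]
  }
  data.frame(region_start = starts, region_end = ends, n_subs = n_subs,
             p_hat = p_hat, observed = as.numeric(observed),
             expected = expected, ubcs = as.numeric(observed) - expected,
             partial = ends - starts < rs)
}

#' UBCS statistic for one region
#'
#' Observed number of BCSs inside the region, the exact expected number
#' under independent Bernoulli(p-hat) bias labels, and their difference
#' (the UBCS statistic).  Clusters are built chromosome-wide, so windows
#' may straddle the region boundary; p-hat is always taken from the
#' region containing the focal substitution.
#'
#' @param catalog A [ubcs_catalog()].
#' @param chromosome Chromosome name.
#' @param start Region start (must lie on the region grid).
#' @param params A [cluster_params()] object.
#' @return One-row data frame with columns `chrom`, `region_start`,
#'   `region_end`, `n_subs`, `p_hat`, `observed`, `expected`, `ubcs`
#'   and `partial`.
#' @export
ubcs_region <- function(catalog, chromosome, start, params = cluster_params()) {
  stopifnot(inherits(catalog, "ubcs_catalog"),
            chromosome %in% names(catalog$chrom_lengths),
            start %% params$region_size == 0)
  df <- catalog$substitutions
  sel <- df$chrom == chromosome
  tab <- profile_chromosome(df$pos[sel], df$biased[sel],
                            catalog$chrom_lengths[[chromosome]], params)
  row <- tab[tab$region_start == start, , drop = FALSE]
  if (nrow(row) == 0) stop("region start ", start, " beyond chromosome")
  cbind(chrom = chromosome, row, stringsAsFactors = FALSE)
}

#' UBCS profile along all chromosomes
#'
#' Computes the region statistics of [ubcs_region()] for every
#' consecutive `region_size` tile of every chromosome in the catalog.
#' The final tile of a chromosome whose length is not a multiple of the
#' region size is emitted with `partial = TRUE`.
#'
#' @param catalog A [ubcs_catalog()].
#' @param params A [cluster_params()] object.
#' @param pair Optional species-pair label stored with the profile.
#' @return A data frame of class `ubcs_profile`, regions in chromosome
#'   order, with attributes `direction`, `pair`, `region_size` and
#'   `chrom_lengths`.
#' @export
ubcs_profile <- function(catalog, params = cluster_params(), pair = NULL) {
  stopifnot(inherits(catalog, "ubcs_catalog"))
  df <- catalog$substitutions
  out <- lapply(names(catalog$chrom_lengths), function(ch) {
    sel <- df$chrom == ch
    cbind(chrom = ch,
          profile_chromosome(df$pos[sel], df$biased[sel],
                             catalog$chrom_lengths[[ch]], params),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out,
            direction = catalog$direction,
            pair = if (is.null(pair)) NA_character_ else pair,
            region_size = params$region_size,
            chrom_lengths = catalog$chrom_lengths,
            class = c("ubcs_profile", "data.frame"))
}
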