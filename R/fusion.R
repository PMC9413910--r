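# sum of region UBCS values whose centre lies in [start, end); regions
# are the profile's 1 Mb tiles, so an interval of L bp collects L / 1 Mb
# regions when aligned with the grid
region_ubcs_sum <- function(profile, chromosome, start, end, warn = TRUE) {
  rows <- profile[profile$chrom == chromosome, , drop = FALSE]
  if (nrow(rows) == 0) stop("chromosome ", chromosome, " missing from profile")
  len <- max(rows$region_end)
  if (start < 0 || end > len) {
    if (warn)
      warning("interval [", start, ", ", end, ") truncated to chromosome ",
              chromosome, " bounds")
    start <- max(0, start)
    end <- min(len, end)
  }
  centre <- (rows$region_start + rows$region_end) / 2
  sum(rows$ubcs[centre >= start & centre < end])
}

# region-level UBCS values (not summed) of the fusion flanks, for the
# block bootstrap
fusion_flank_values <- function(profile, chromosome, fusion_site, L, sides) {
  rows <- profile[profile$chrom == chromosome, , drop = FALSE]
  centre <- (rows$region_start + rows$region_end) / 2
  sel <- switch(sides,
                proximal = centre >= fusion_site - L & centre < fusion_site,
                distal   = centre >= fusion_site & centre < fusion_site + L,
                both     = centre >= fusion_site - L & centre < fusion_site + L)
  rows$ubcs[sel]
}

#' UBCS ratio next to the fusion site
#'
#' The proportion q1 of summed UBCS between the human-derived and the
#' query-derived profiles over the interval(s) flanking the fusion
#' site: with `sides = "both"` the two L-bp intervals on either side of
#' the site are summed.  q1 reflects the decline in the accumulation of
#' biased clustered substitutions at the site after the fusion event.
#'
#' @param profile_human Human-derived (target-derived) profile.
#' @param profile_query Query-derived profile.
#' @param fusion_site Fusion-site coordinate in bp.
#' @param L Flanking interval length in bp.
#' @param chromosome Fused chromosome (default "chr2").
#' @param sides "both" (default), "proximal" or "distal".
#' @return The ratio, or `NA` when the query-derived denominator is not
#'   positive.
#' @export
fusion_signal_ratio <- function(profile_human, profile_query, fusion_site, L,
                                chromosome = "chr2", sides = "both") {
  span <- switch(sides,
                 proximal = c(fusion_site - L, fusion_site),
                 distal = c(fusion_site, fusion_site + L),
                 both = c(fusion_site - L, fusion_site + L))
  num <- region_ubcs_sum(profile_human, chromosome, span[1], span[2])
  den <- region_ubcs_sum(profile_query, chromosome, span[1], span[2])
  if (!is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

#' Telomeric rescaling factor from control telomeres
#'
#' For every control telomere (both arms of each control chromosome)
#' the human-derived UBCS sum over the first L bp of the telomere is
#' divided by the sum over the same length starting `offset` bp from
#' the telomere end.  q2, the median of these ratios, calibrates how
#' much stronger the UBCS signal is at a telomere start than a few Mb
#' inward, and rescales the query-derived signal measured next to the
#' fusion site (where the outermost chimpanzee sequence is not
#' alignable to the human reference).
#'
#' @param profile_human Human-derived profile.
#' @param control_chroms Control chromosome names.
#' @param offset Offset of the interior interval in bp (default 5 Mb).
#' @param L Interval length in bp.
#' @return A list with the median `q2` and the per-telomere `table`
#'   (telomeres with non-positive denominators carry `NA` ratios and
#'   are excluded from the median).
#' @export
telomere_rescale_ratio <- function(profile_human, control_chroms,
                                   offset = 5e6, L) {
  control_chroms <- chrom_name(control_chroms)
  rows <- lapply(control_chroms, function(ch) {
    len <- attr(profile_human, "chrom_lengths")[[ch]]
    if (is.null(len))
      len <- max(profile_human$region_end[profile_human$chrom == ch])
    p_num <- region_ubcs_sum(profile_human, ch, 0, L)
    p_den <- region_ubcs_sum(profile_human, ch, offset, offset + L)
    q_num <- region_ubcs_sum(profile_human, ch, len - L, len)
    q_den <- region_ubcs_sum(profile_human, ch, len - offset - L, len - offset)
    data.frame(chrom = ch, arm = c("p", "q"),
               num = c(p_num, q_num), den = c(p_den, q_den))
  })
  tab <- do.call(rbind, rows)
  tab$ratio <- ifelse(tab$den > 0, tab$num / tab$den, NA_real_)
  if (anyNA(tab$ratio))
    warning(sum(is.na(tab$ratio)),
            " control telomere(s) with non-positive denominator excluded")
  list(q2 = median(tab$ratio, na.rm = TRUE), table = tab)
}

#' Fusion time from a measured ratio R
#'
#' R is the proportion of the post-split period during which the two
#' ancestral chromosomes were not yet fused, so the fusion time is
#' `split_time * (1 - R)`, clamped to `[0, split_time]`.
#'
#' @param R Measured proportion.
#' @param split_time Split time in Mya (default 6).
#' @return Fusion time in Mya.
#' @export
fusion_time_from_ratio <- function(R, split_time = 6) {
  if (any(R > 1, na.rm = TRUE))
    warning("R > 1 clamped to a fusion time of 0")
  pmin(pmax(split_time * (1 - R), 0), split_time)
}

#' Estimate the chromosome fusion time
#'
#' For each interval length L in `params$region_sizes` the ratio
#' `R(L) = q1(L) / q2(L)` is formed from [fusion_signal_ratio()] and
#' [telomere_rescale_ratio()]; the point estimate is
#' `split_time * (1 - median_L R(L))`, clamped to `[0, split_time]`.
#' The 95% confidence interval is obtained by a seeded bootstrap: each
#' replicate draws one L uniformly, resamples the 1-Mb regions of the
#' fusion flanks (jointly for the human- and query-derived profiles) to
#' recompute q1, resamples the control telomeres with replacement to
#' recompute q2, and converts the resulting R to a time; the interval
#' is the trimmed range of the replicate times.
#'
#' @param profile_human Human-derived profile covering the fused
#'   chromosome and the control chromosomes.
#' @param profile_query Query-derived profile of the fused chromosome.
#' @param params A [fusion_params()] object.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `fusion_estimate` with the per-L ratios,
#'   the point estimate `time_mya` and the bootstrap `ci_mya`.
#' @export
estimate_fusion_time <- function(profile_human, profile_query,
                                 params = fusion_params(), seed = 1L) {
  Ls <- params$region_sizes
  q1 <- vapply(Ls, function(L)
    fusion_signal_ratio(profile_human, profile_query, params$fusion_site, L,
                        params$fusion_chrom, params$sides), numeric(1))
  resc <- lapply(Ls, function(L)
    telomere_rescale_ratio(profile_human, params$control_chroms,
                           params$interval_offset, L))
  q2 <- vapply(resc, function(r) r$q2, numeric(1))
  R_by_L <- q1 / q2
  if (all(is.na(R_by_L))) stop("all fusion ratios are undefined")
  R_med <- median(R_by_L, na.rm = TRUE)
  time_mya <- fusion_time_from_ratio(R_med, params$split_time)

  # per-telomere rescale ratios, one column per L
  ratio_mat <- vapply(resc, function(r) r$table$ratio,
                      numeric(nrow(resc[[1]]$table)))
  hq_vals <- lapply(Ls, function(L) list(
    h = fusion_flank_values(profile_human, params$fusion_chrom,
                            params$fusion_site, L, params$sides),
    q = fusion_flank_values(profile_query, params$fusion_chrom,
                            params$fusion_site, L, params$sides)))
  n_tel <- nrow(resc[[1]]$table)
  set.seed(seed)
  reps <- vapply(seq_len(params$n_boot), function(r) {
    li <- sample.int(length(Ls), 1)
    hv <- hq_vals[[li]]$h
    qv <- hq_vals[[li]]$q
    ri <- sample.int(length(hv), length(hv), replace = TRUE)
    den1 <- sum(qv[ri])
    q1b <- if (den1 > 0) sum(hv[ri]) / den1 else NA_real_
    ti <- sample.int(n_tel, n_tel, replace = TRUE)
    q2b <- median(ratio_mat[ti, li], na.rm = TRUE)
    Rb <- q1b / q2b
    if (!is.finite(Rb)) return(NA_real_)
    suppressWarnings(fusion_time_from_ratio(Rb, params$split_time))
  }, numeric(1))
  ci <- suppressWarnings(trimmed_range_ci(reps, params$trim_fraction))

  structure(list(R_by_L = stats::setNames(R_by_L, Ls),
                 q1_by_L = stats::setNames(q1, Ls),
                 q2_by_L = stats::setNames(q2, Ls),
                 R = R_med, time_mya = time_mya, ci_mya = ci,
                 rescale_table = resc[[1]]$table,
                 split_time = params$split_time,
                 n_boot = params$n_boot, seed = seed),
            class = "fusion_estimate")
}

#' @export
print.fusion_estimate <- function(x, ...) {
  cat("Fusion-time estimate:", format(x$time_mya, digits = 3), "Mya",
      "(95% CI", format(x$ci_mya[1], digits = 3), "-",
      format(x$ci_mya[2], digits = 3), ")\n")
  cat("  median R =", format(x$R, digits = 4),
      "over", length(x$R_by_L), "interval sizes\n")
  invisible(x)
}
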