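#' Telomeric UBCS values of one chromosome arm
#'
#' Returns the UBCS values of the M 1-Mb windows at the telomeric end of
#' an arm: the first M complete regions for the p arm, the last M
#' complete regions in reversed order (telomere first) for the q arm.
#'
#' @param profile A [ubcs_profile()].
#' @param chromosome Chromosome name.
#' @param arm "p" or "q".
#' @param M Number of windows.
#' @return Numeric vector of M UBCS values, telomere end first.
#' @export
arm_ubcs_values <- function(profile, chromosome, arm = c("p", "q"), M = 10L) {
  arm <- match.arg(arm)
  rows <- profile[profile$chrom == chromosome & !profile$partial, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("chromosome ", chromosome, " missing from profile")
  if (nrow(rows) < M)
    stop("chromosome ", chromosome, " has fewer than M = ", M, " regions")
  rows <- rows[order(rows$region_start), , drop = FALSE]
  if (arm == "p") rows$ubcs[seq_len(M)]
  else rev(tail(rows$ubcs, M))
}

#' Average UBCS proportion between two genomes on one telomere
#'
#' The ratio `T = sum_j U(x_j) / sum_j U(y_j)` over the M telomeric
#' windows of the arm, windows ordered from the telomere end inward.
#'
#' @param profile_x,profile_y Profiles tiled identically.
#' @param chromosome Chromosome name.
#' @param arm "p" or "q".
#' @param M Number of windows (default 10).
#' @return The ratio, or `NA` when the denominator sum is not positive
#'   (such telomeres are excluded from the median downstream).
#' @export
arm_proportion <- function(profile_x, profile_y, chromosome,
                           arm = c("p", "q"), M = 10L) {
  arm <- match.arg(arm)
  num <- sum(arm_ubcs_values(profile_x, chromosome, arm, M))
  den <- sum(arm_ubcs_values(profile_y, chromosome, arm, M))
  if (!is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

# per-telomere window matrices for the two profiles
telomere_window_matrices <- function(profile_x, profile_y, control, M) {
  tel <- control_telomeres(control)
  Ux <- t(vapply(seq_len(nrow(tel)), function(i)
    arm_ubcs_values(profile_x, tel$chrom[i], tel$arm[i], M), numeric(M)))
  Uy <- t(vapply(seq_len(nrow(tel)), function(i)
    arm_ubcs_values(profile_y, tel$chrom[i], tel$arm[i], M), numeric(M)))
  list(telomeres = tel, Ux = Ux, Uy = Uy)
}

#' UBCS-proportion evolutionary distance between two genomes
#'
#' The distance is the median of the telomere ratios `T_p(i)` over the
#' p-arm control chromosomes and `T_q(i)` over the q-arm control
#' chromosomes.  Telomeres whose denominator sum is not positive are
#' excluded with a warning.
#'
#' @param profile_x Numerator profile (the more distant species'
#'   signal).
#' @param profile_y Denominator profile.
#' @param control A [control_sets()] object.
#' @param params A [distance_params()] object.
#' @return An object of class `ubcs_distance`: the per-telomere ratio
#'   table and the median proportion.
#' @export
ubcs_distance <- function(profile_x, profile_y, control = control_sets(),
                          params = distance_params()) {
  mats <- telomere_window_matrices(profile_x, profile_y, control, params$M)
  num <- rowSums(mats$Ux)
  den <- rowSums(mats$Uy)
  ratio <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(ratio))
    warning(sum(is.na(ratio)), " telomere(s) with non-positive denominator ",
            "excluded from the median")
  if (all(is.na(ratio)))
    stop("all telomere ratios are undefined")
  tab <- cbind(mats$telomeres,
               data.frame(T = ratio, defined = !is.na(ratio)))
  structure(list(telomeres = tab,
                 proportion = median(ratio, na.rm = TRUE),
                 M = params$M, control = control),
            class = "ubcs_distance")
}

#' @export
print.ubcs_distance <- function(x, ...) {
  cat("UBCS proportion (median over", sum(x$telomeres$defined),
      "telomeres):", format(x$proportion, digits = 4), "\n")
  if (!is.null(x$ci))
    cat("  bootstrap CI: [", format(x$ci[1], digits = 4), ",",
        format(x$ci[2], digits = 4), "]\n")
  invisible(x)
}

#' Bootstrap confidence interval for the UBCS-proportion distance
#'
#' Each replicate draws `telomere_draw` telomeres with replacement from
#' the control pool and `window_draw` of the M window offsets with
#' replacement (one window draw shared by all sampled telomeres of the
#' replicate), recomputes the per-telomere ratios from the sampled
#' windows and takes their median.  The confidence interval is the
#' range of replicate values remaining after trimming the
#' `trim_fraction/2` most extreme values from each tail.
#'
#' @inheritParams ubcs_distance
#' @param seed Integer seed for the replicate draws.
#' @param per_telomere_windows Draw a separate window sample for every
#'   telomere within a replicate instead of one shared draw
#'   (default `FALSE`).
#' @return An object of class `ubcs_distance` with elements `ci` and
#'   `replicates` added.
#' @export
bootstrap_distance <- function(profile_x, profile_y, control = control_sets(),
                               params = distance_params(), seed = 1L,
                               per_telomere_windows = FALSE) {
  est <- ubcs_distance(profile_x, profile_y, control, params)
  mats <- telomere_window_matrices(profile_x, profile_y, control, params$M)
  n_tel <- nrow(mats$telomeres)
  draw <- params$telomere_draw
  if (draw > n_tel) {
    warning("telomere_draw = ", draw, " exceeds the ", n_tel,
            " available telomeres; using the pool size")
    draw <- n_tel
  }
  set.seed(seed)
  reps <- vapply(seq_len(params$n_boot), function(r) {
    ti <- sample.int(n_tel, draw, replace = TRUE)
    if (per_telomere_windows) {
      ratio <- vapply(ti, function(i) {
        wi <- sample.int(params$M, params$window_draw, replace = TRUE)
        den <- sum(mats$Uy[i, wi])
        if (den > 0) sum(mats$Ux[i, wi]) / den else NA_real_
      }, numeric(1))
    } else {
      wi <- sample.int(params$M, params$window_draw, replace = TRUE)
      num <- rowSums(mats$Ux[ti, wi, drop = FALSE])
      den <- rowSums(mats$Uy[ti, wi, drop = FALSE])
      ratio <- ifelse(den > 0, num / den, NA_real_)
    }
    if (all(is.na(ratio))) NA_real_ else median(ratio, na.rm = TRUE)
  }, numeric(1))
  est$ci <- trimmed_range_ci(reps, params$trim_fraction)
  est$replicates <- reps
  est$seed <- seed
  est
}

#' Scale a UBCS proportion to a speciation time
#'
#' Multiplies the proportion point estimate (and its confidence
#' interval, when present) by the fixed human-chimpanzee split time.
#'
#' @param estimate A `ubcs_distance` object, or a bare proportion.
#' @param split_time Split time in Mya (default 6).
#' @return A list with `time_mya` and, when available, `ci_mya`.
#' @export
speciation_time <- function(estimate, split_time = 6) {
  prop <- if (inherits(estimate, "ubcs_distance")) estimate$proportion else estimate
  out <- list(time_mya = prop * split_time)
  if (inherits(estimate, "ubcs_distance") && !is.null(estimate$ci))
    out$ci_mya <- estimate$ci * split_time
  out
}
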