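# shared fixture builders (all generated in code; no stored data)

# aligned-column run with identical filler bases everywhere
filler_columns <- function(chrom, from, to, base = "T") {
  data.frame(chrom = chrom, pos = from:to, target_base = base,
             query_base = base, outgroup_base = base,
             stringsAsFactors = FALSE)
}

# plant an SND (or arbitrary column) into a column run
plant <- function(cols, pos, target = NULL, query = NULL, outgroup = NULL) {
  i <- match(pos, cols$pos)
  stopifnot(!is.na(i))
  if (!is.null(target)) cols$target_base[i] <- target
  if (!is.null(query)) cols$query_base[i] <- query
  if (!is.null(outgroup)) cols$outgroup_base[i] <- outgroup
  cols
}

# hand-built profile: value_fun(chrom, region_start) -> ubcs value
fake_profile <- function(chrom_lengths, value_fun,
                         direction = "derived_in_target",
                         region_size = 1e6) {
  rows <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    n <- ceiling(chrom_lengths[[ch]] / region_size)
    starts <- (seq_len(n) - 1) * region_size
    ends <- pmin(starts + region_size, chrom_lengths[[ch]])
    data.frame(chrom = ch, region_start = starts, region_end = ends,
               n_subs = 100L, p_hat = 0.4, observed = 0, expected = 0,
               ubcs = vapply(starts, function(s) value_fun(ch, s), numeric(1)),
               partial = ends - starts < region_size,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(rows, direction = direction, pair = NA_character_,
            region_size = region_size, chrom_lengths = chrom_lengths,
            class = c("ubcs_profile", "data.frame"))
}

# clustered positions for null-calibration style experiments
clustered_positions <- function(chrom_len, n_clusters, n_background,
                                cluster_size_mean = 6, span = 250) {
  centres <- runif(n_clusters, 0, chrom_len)
  sizes <- rpois(n_clusters, cluster_size_mean)
  pos <- c(runif(n_background, 0, chrom_len),
           rep(centres, sizes) + runif(sum(sizes), -span / 2, span / 2))
  sort(unique(floor(pmin(pmax(pos, 5), chrom_len - 6))))
}

# enumeration oracle for representative-window selection: all candidate
# starts, deduplicated by contained-substitution set
oracle_representative_windows <- function(positions, focal_index, params,
                                          chrom_len) {
  m <- params$window_size
  d <- params$start_divisor
  pf <- positions[focal_index]
  first <- ceiling(max(0, pf - m + 1) / d) * d
  if (first > pf) return(numeric(0))
  starts <- seq(first, pf, by = d)
  starts <- starts[starts + m <= chrom_len]
  sets <- lapply(starts, function(s)
    which(positions >= s & positions < s + m))
  keep <- lengths(sets) >= params$min_cluster &
    !duplicated(vapply(sets, paste, character(1), collapse = ","))
  starts[keep]
}

# enumeration oracle for observed BCS flags
oracle_observed_flags <- function(positions, biased, params, chrom_len) {
  m <- params$window_size
  d <- params$start_divisor
  out <- rep(FALSE, length(positions))
  for (s in seq(0, chrom_len - m, by = d)) {
    inw <- which(positions >= s & positions < s + m)
    if (length(inw) >= params$min_cluster &&
        sum(biased[inw]) * params$thr_den >= params$thr_num * length(inw))
      out[inw] <- TRUE
  }
  out
}
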