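#' Parameters of the synthetic substitution process
#'
#' The generator emulates the statistical structure the UBCS method
#' assumes: point substitutions along a chromosome with local
#' clustering (a Neyman-Scott process: Poisson cluster centres with
#' Poisson numbers of offspring scattered uniformly over a short span),
#' a weak-to-strong bias fraction elevated inside clusters, cluster
#' centres enriched near chromosome ends with an exponentially decaying
#' profile, and all intensities scaling linearly with divergence time.
#'
#' All rates are per Mb and per Mya, so expected counts are
#' `rate * time * length`.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param time Divergence time in Mya (default 6).
#' @param bg_rate Background (non-clustered) substitutions per Mb per
#'   Mya (default 40).
#' @param cluster_rate Interior cluster centres per Mb per Mya (default
#'   0.1).
#' @param tel_cluster_rate Additional cluster-centre intensity at the
#'   chromosome end, per Mb per Mya (default 4); decays exponentially
#'   inward with length `tel_decay`.
#' @param tel_decay Decay length of the telomeric enrichment in bp
#'   (default 3 Mb).
#' @param cluster_size_mean Mean substitutions per cluster (default 6).
#' @param cluster_span Span in bp over which cluster members scatter
#'   (default 250).
#' @param p0 Weak-to-strong fraction outside clusters (default 0.3).
#' @param p1 Weak-to-strong fraction inside clusters (default 0.92).
#' @param min_spacing Minimal distance between retained substitutions
#'   in bp (default 12), emulating the post-filter catalogs in which no
#'   11-bp window holds more than two differences.
#' @param fusion_chrom,fusion_site Optional: chromosome and coordinate
#'   of an internal telomere-style source (the ancestral fusion site).
#' @param site_rate Cluster-centre intensity at the fusion site, per Mb
#'   per Mya (default `tel_cluster_rate`).
#' @param site_time Accumulation time in Mya of the fusion-site source
#'   (default `time`); on the human lineage the site accumulates only
#'   while it is still a telomere, i.e. for split minus fusion time.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(chrom_lengths, time = 6, bg_rate = 40,
                       cluster_rate = 0.1, tel_cluster_rate = 4,
                       tel_decay = 3e6, cluster_size_mean = 6,
                       cluster_span = 250, p0 = 0.3, p1 = 0.92,
                       min_spacing = 12, fusion_chrom = NULL,
                       fusion_site = NULL, site_rate = tel_cluster_rate,
                       site_time = time) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 1000),
            time > 0, bg_rate >= 0, cluster_rate >= 0, tel_cluster_rate >= 0,
            tel_decay > 0, cluster_size_mean > 0, cluster_span > 0,
            p0 >= 0, p1 >= p0, p1 <= 1, min_spacing >= 0)
  structure(list(chrom_lengths = chrom_lengths, time = time,
                 bg_rate = bg_rate, cluster_rate = cluster_rate,
                 tel_cluster_rate = tel_cluster_rate, tel_decay = tel_decay,
                 cluster_size_mean = cluster_size_mean,
                 cluster_span = cluster_span, p0 = p0, p1 = p1,
                 min_spacing = min_spacing, fusion_chrom = fusion_chrom,
                 fusion_site = fusion_site, site_rate = site_rate,
                 site_time = site_time),
            class = "sim_params")
}

# exponentially decaying source: expected count rate*time*decay*(1-exp(-span/decay)),
# distances rexp(decay) truncated to span
rexp_source <- function(rate_per_mb_mya, time, decay, span) {
  lambda <- rate_per_mb_mya * time * (decay / 1e6) * (1 - exp(-span / decay))
  n <- rpois(1, lambda)
  if (n == 0) return(numeric(0))
  x <- rexp(n, rate = 1 / decay)
  while (any(x >= span)) x[x >= span] <- rexp(sum(x >= span), rate = 1 / decay)
  x
}

#' Simulate a substitution catalog
#'
#' Draws background substitutions from a homogeneous Poisson process,
#' cluster centres from an inhomogeneous process with telomere-elevated
#' rate (plus an optional internal fusion-site source), scatters
#' Poisson numbers of cluster members uniformly over the cluster span
#' (reflected at chromosome ends), and labels members Bernoulli(p1),
#' background Bernoulli(p0).  Identical seeds yield identical catalogs.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param direction Derivation direction recorded in the catalog.
#' @return A [ubcs_catalog()].
#' @export
simulate_catalog <- function(params, seed = NULL,
                             direction = "derived_in_target") {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  t <- params$time
  out <- lapply(names(params$chrom_lengths), function(ch) {
    L <- params$chrom_lengths[[ch]]
    Lmb <- L / 1e6
    # background
    n_bg <- rpois(1, params$bg_rate * t * Lmb)
    pos_bg <- runif(n_bg, 0, L)
    # cluster centres: interior + both telomeres (+ fusion site)
    centres <- runif(rpois(1, params$cluster_rate * t * Lmb), 0, L)
    half <- L / 2
    left <- rexp_source(params$tel_cluster_rate, t, params$tel_decay, half)
    right <- rexp_source(params$tel_cluster_rate, t, params$tel_decay, half)
    centres <- c(centres, left, L - 1 - right)
    if (!is.null(params$fusion_chrom) && ch == params$fusion_chrom) {
      site <- params$fusion_site
      for (side in c(-1, 1)) {
        span <- if (side < 0) site else L - site
        dx <- rexp_source(params$site_rate, params$site_time,
                          params$tel_decay, span)
        centres <- c(centres, site + side * dx)
      }
    }
    # cluster members
    sizes <- rpois(length(centres), params$cluster_size_mean)
    members <- rep(centres, sizes) +
      runif(sum(sizes), -params$cluster_span / 2, params$cluster_span / 2)
    # reflect at chromosome ends
    members <- abs(members)
    members <- L - 1 - abs(L - 1 - members)
    pos <- c(pos_bg, members)
    lab <- c(rbinom(n_bg, 1, params$p0) == 1,
             rbinom(sum(sizes), 1, params$p1) == 1)
    # keep an 11-bp context margin so alignment fixtures round-trip
    pos <- floor(pmin(pmax(pos, 5), L - 6))
    o <- order(pos)
    pos <- pos[o]
    lab <- lab[o]
    # minimal spacing by rejection of the later point
    if (length(pos) > 1) {
      keep <- cpp_min_spacing(pos, params$min_spacing)
      pos <- pos[keep]
      lab <- lab[keep]
    }
    if (length(pos) == 0) return(NULL)
    data.frame(chrom = ch, pos = pos, biased = lab, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(chrom = character(), pos = numeric(), biased = logical())
  ubcs_catalog(df, params$chrom_lengths, direction)
}

#' Simulate a species pair with divergence times t_x and t_y
#'
#' Two independent catalogs whose substitution and cluster intensities
#' scale linearly with `t_x` and `t_y`; the true UBCS proportion of the
#' pair (numerator `t_y`) is `t_y / t_x`.
#'
#' @param t_x,t_y Divergence times in Mya.
#' @param params A [sim_params()] object; its `time` is overridden.
#'   Default: 22 autosomes of 21 Mb.
#' @param seed Integer seed (catalog y uses `seed + 1000`).
#' @return A list with `catalog_x` and `catalog_y`.
#' @export
simulate_species_pair <- function(t_x, t_y, params = NULL, seed = 1L) {
  stopifnot(t_x > 0, t_y > 0)
  if (is.null(params))
    params <- sim_params(stats::setNames(rep(21e6, 22), paste0("chr", 1:22)),
                         tel_decay = 3e6, tel_cluster_rate = 4)
  px <- params
  px$time <- t_x
  py <- params
  py$time <- t_y
  list(catalog_x = simulate_catalog(px, seed = seed),
       catalog_y = simulate_catalog(py, seed = seed + 1000L))
}

#' Simulate a chromosome-fusion scenario
#'
#' Control chromosomes accumulate telomeric clusters for the full
#' `split_time` in both derivation directions.  The fused chromosome
#' carries an internal telomere-style source at the fusion site: on the
#' human-derived side it accumulates only while the site is still a
#' telomere, i.e. for `split_time - fusion_time`; on the query-derived
#' side it accumulates for the full period but with its profile shifted
#' outward by `query_offset` bp (equivalently, amplitude damped by
#' `exp(-query_offset / tel_decay)`), emulating the unalignable
#' repeat-capped outermost chimpanzee sequence whose effect the
#' telomeric rescaling factor q2 corrects.
#'
#' @param split_time Split time in Mya (default 6).
#' @param fusion_time True fusion time in Mya (between 0 and
#'   `split_time`).
#' @param params A [sim_params()] object; default: control chromosomes
#'   1-12, 16, 17 of 55 Mb plus a 100 Mb fused "chr2" with the site at
#'   50 Mb, telomere decay 6 Mb, 12 telomeric cluster centres per Mb
#'   per Mya against a background of 300 substitutions per Mb per Mya
#'   (keeping the per-region weak-to-strong fraction in the 0.3-0.45
#'   band observed on real chromosomes).
#' @param seed Integer seed (query catalog uses `seed + 1000`).
#' @param query_offset Outward shift of the query-derived site profile
#'   in bp (default 5 Mb, matching the default rescaling-interval
#'   offset).
#' @return A list with `human` and `query` catalogs, and the `params`
#'   used.
#' @export
simulate_fusion_scenario <- function(split_time = 6, fusion_time = 1,
                                     params = NULL, seed = 1L,
                                     query_offset = 5e6) {
  stopifnot(fusion_time >= 0, fusion_time <= split_time)
  if (is.null(params)) {
    lens <- stats::setNames(rep(55e6, 14), paste0("chr", c(1:12, 16, 17)))
    lens["chr2"] <- 100e6
    params <- sim_params(lens, time = split_time, bg_rate = 300,
                         tel_decay = 6e6, tel_cluster_rate = 12,
                         fusion_chrom = "chr2", fusion_site = 50e6)
  }
  ph <- params
  ph$time <- split_time
  ph$site_time <- split_time - fusion_time
  ph$site_rate <- params$tel_cluster_rate
  pq <- params
  pq$time <- split_time
  pq$site_time <- split_time
  pq$site_rate <- params$tel_cluster_rate * exp(-query_offset / params$tel_decay)
  human <- simulate_catalog(ph, seed = seed, direction = "derived_in_target")
  query <- simulate_catalog(pq, seed = seed + 1000L,
                            direction = "derived_in_query")
  list(human = human, query = query, params = params,
       split_time = split_time, fusion_time = fusion_time)
}

#' Write an alignment fixture reproducing a catalog
#'
#' Emits a three-way TSV (and optionally a MAF) of aligned columns
#' whose SND calling and polarization reproduce the input catalog
#' exactly: every substitution appears with 5 clean context columns on
#' each side, the outgroup carrying the ancestral base.  Optionally
#' injects decoy columns violating each filter rule (an indel in the
#' context window, three differences in an 11-bp window, and a missing
#' outgroup base), placed beyond the last substitution of each
#' chromosome.
#'
#' @param catalog A [ubcs_catalog()].
#' @param tsv_path Output path of the three-way TSV.
#' @param maf_path Optional output path of a MAF rendering the same
#'   target/query columns.
#' @param decoys Inject filter-violating decoy SNDs (default `TRUE`).
#' @return Invisibly, a list with the paths and the number of decoy
#'   SNDs per rule.
#' @export
make_alignment_fixture <- function(catalog, tsv_path, maf_path = NULL,
                                   decoys = TRUE) {
  stopifnot(inherits(catalog, "ubcs_catalog"))
  df <- catalog$substitutions
  if (is.null(df$derived_base)) df$derived_base <- ifelse(df$biased, "G", "A")
  if (is.null(df$ancestral_base)) df$ancestral_base <- ifelse(df$biased, "A", "G")
  to_target <- catalog$direction == "derived_in_target"
  n_decoy <- c(indel = 0L, too_many_diffs = 0L, no_outgroup = 0L)
  chunks <- lapply(names(catalog$chrom_lengths), function(ch) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    len <- catalog$chrom_lengths[[ch]]
    # context filler columns
    ctx <- unique(as.vector(outer(sub$pos, -5:5, `+`)))
    cols <- data.frame(pos = ctx, t = "T", q = "T", o = "T",
                       stringsAsFactors = FALSE)
    at <- match(sub$pos, cols$pos)
    cols$t[at] <- if (to_target) sub$derived_base else sub$ancestral_base
    cols$q[at] <- if (to_target) sub$ancestral_base else sub$derived_base
    cols$o[at] <- sub$ancestral_base
    # decoys go into the widest gap between substitutions (12 bp clear
    # of any real SND so no real context window is disturbed)
    gap_lo <- c(10, sub$pos + 12)
    gap_hi <- c(sub$pos - 12, len - 20)
    gi <- which.max(gap_hi - gap_lo)
    if (decoys && gap_hi[gi] - gap_lo[gi] >= 140) {
      base <- gap_lo[gi] + 10
      dec <- data.frame(pos = as.vector(outer(base + c(0, 50, 52, 54, 100), -5:5, `+`)),
                        t = "T", q = "T", o = "T", stringsAsFactors = FALSE)
      set_col <- function(d, p, t, q, o) {
        i <- match(p, d$pos)
        d$t[i] <- t; d$q[i] <- q; d$o[i] <- o
        d
      }
      dec <- set_col(dec, base, "A", "G", "A")          # SND next to an indel
      dec <- set_col(dec, base + 2, "T", "-", "T")      # the indel
      for (off in c(0, 2, 4))                           # 3 diffs in 11 bp
        dec <- set_col(dec, base + 50 + off, "A", "G", "A")
      dec <- set_col(dec, base + 100, "A", "G", ".")    # missing outgroup
      cols <- rbind(cols, dec)
      n_decoy <<- n_decoy + c(indel = 1L, too_many_diffs = 3L, no_outgroup = 1L)
    }
    cols <- cols[order(cols$pos), , drop = FALSE]
    cols <- cols[!duplicated(cols$pos), , drop = FALSE]
    cbind(chrom = ch, cols, stringsAsFactors = FALSE)
  })
  cols <- do.call(rbind, chunks)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s", cols$chrom,
                   format(cols$pos, scientific = FALSE, trim = TRUE),
                   cols$t, cols$q, cols$o)
  writeLines(c("chromosome\tposition\ttarget_base\tquery_base\toutgroup_base",
               lines), tsv_path)
  if (!is.null(maf_path))
    write_maf_columns(cols, catalog$chrom_lengths, maf_path)
  invisible(list(tsv = tsv_path, maf = maf_path, decoys = n_decoy))
}

# render aligned columns as a MAF: one block per contiguous position run
write_maf_columns <- function(cols, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (ch in unique(cols$chrom)) {
    cc <- cols[cols$chrom == ch, , drop = FALSE]
    runs <- cumsum(c(1, diff(cc$pos) != 1))
    for (r in unique(runs)) {
      blk <- cc[runs == r, , drop = FALSE]
      tseq <- paste(blk$t, collapse = "")
      qseq <- paste(blk$q, collapse = "")
      src_size <- format(chrom_lengths[[ch]], scientific = FALSE)
      writeLines(c("a score=0",
                   sprintf("s target.%s %s %d + %s %s", ch,
                           format(blk$pos[1], scientific = FALSE, trim = TRUE),
                           sum(blk$t != "-"), src_size, tseq),
                   sprintf("s query.%s %s %d + %s %s", ch,
                           format(blk$pos[1], scientific = FALSE, trim = TRUE),
                           sum(blk$q != "-"), src_size, qseq),
                   ""), con)
    }
  }
  invisible(path)
}
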