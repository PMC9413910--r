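#' Read a three-way aligned-column TSV
#'
#' Each row is one aligned column on the target genome: tab-separated
#' `chromosome`, `position` (0-based target coordinate), `target_base`,
#' `query_base`, `outgroup_base`, with "." marking an absent outgroup
#' base (e.g. a position that cannot be lifted over).  A header line is
#' optional.  Bases are uppercased; "-" denotes a gap.  Positions must be
#' nondecreasing within each chromosome.
#'
#' @param path Input file path.
#' @return A data frame of aligned columns with `outgroup_base` equal to
#'   `NA` where the outgroup is absent.
#' @export
read_threeway_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos = numeric(),
                      target_base = character(), query_base = character(),
                      outgroup_base = character(), stringsAsFactors = FALSE))
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  start <- if (has_header) 2L else 1L
  if (start > length(lines))
    return(data.frame(chrom = character(), pos = numeric(),
                      target_base = character(), query_base = character(),
                      outgroup_base = character(), stringsAsFactors = FALSE))
  rows <- strsplit(lines[start:length(lines)], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop("malformed row at line ", bad + start - 1L, " of ", path,
         " (expected 5 tab-separated fields, found ", nf[bad], ")")
  }
  m <- matrix(unlist(rows), ncol = 5, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed position at line ", bad + start - 1L, " of ", path)
  }
  df <- data.frame(chrom = m[, 1], pos = pos,
                   target_base = toupper(m[, 3]), query_base = toupper(m[, 4]),
                   outgroup_base = toupper(m[, 5]), stringsAsFactors = FALSE)
  df$outgroup_base[df$outgroup_base == "."] <- NA_character_
  unsorted <- stats::ave(df$pos, df$chrom, FUN = function(p) c(0, diff(p)) < 0)
  if (any(unsorted == 1)) {
    bad <- which(unsorted == 1)[1]
    stop("unsorted input at line ", bad + start - 1L, " of ", path,
         " (positions must be nondecreasing within a chromosome)")
  }
  df
}

#' Call single-nucleotide differences with context filters
#'
#' Scans a stream of aligned columns ordered by (chromosome, position)
#' and emits one record per column where target and query differ and
#' both bases are A, C, G or T.  Each record is checked against an
#' 11-bp context window (the SND in the middle, `context_half_width`
#' columns on each side) and fails the filters when (i) a gap or indel
#' occurs anywhere in the window, (ii) the window holds more than two
#' target-query differences (the focal SND counts as one of them), or
#' (iii) no outgroup base is available at the SND column.  A window
#' truncated by a contig or alignment edge, or with non-contiguous
#' position coverage, also fails (reason "edge").
#'
#' @param columns Data frame of aligned columns as from
#'   [read_threeway_tsv()] or [read_maf()].
#' @param context_half_width Columns of context on each side (default 5).
#' @param verbose Log the number of SNDs discarded per filter rule.
#' @return A data frame of SND records with `passed_filters` and
#'   `filter_reason` ("pass", "indel", "too_many_diffs", "no_outgroup"
#'   or "edge").
#' @export
call_snds <- function(columns, context_half_width = 5L, verbose = FALSE) {
  w <- as.integer(context_half_width)
  stopifnot(w >= 0)
  need <- c("chrom", "pos", "target_base", "query_base")
  stopifnot(all(need %in% names(columns)))
  if (is.null(columns$outgroup_base)) columns$outgroup_base <- NA_character_
  if (nrow(columns) == 0)
    return(empty_snd_records())
  o <- order(columns$chrom)        # stable: keeps file order within chrom
  columns <- columns[o, , drop = FALSE]
  unsorted <- stats::ave(columns$pos, columns$chrom,
                         FUN = function(p) c(0, diff(p)) < 0)
  if (any(unsorted == 1))
    stop("aligned columns are not sorted by position within chromosome")

  tb <- toupper(columns$target_base)
  qb <- toupper(columns$query_base)
  acgt <- c("A", "C", "G", "T")
  is_gap <- tb == "-" | qb == "-"
  is_diff <- tb %in% acgt & qb %in% acgt & tb != qb
  cum_gap <- cumsum(is_gap)
  cum_diff <- cumsum(is_diff)
  n <- nrow(columns)
  idx <- which(is_diff)
  if (length(idx) == 0) {
    out <- empty_snd_records()
    if (verbose) message("call_snds: no candidate SNDs")
    return(out)
  }
  lo <- idx - w
  hi <- idx + w
  chrom <- columns$chrom
  pos <- columns$pos
  # a window is admissible when it stays inside the chromosome run and
  # covers exactly 2w+1 consecutive target positions
  in_range <- lo >= 1 & hi <= n
  same_chrom <- rep(FALSE, length(idx))
  contiguous <- rep(FALSE, length(idx))
  ok <- which(in_range)
  same_chrom[ok] <- chrom[lo[ok]] == chrom[idx[ok]] &
    chrom[hi[ok]] == chrom[idx[ok]]
  okc <- ok[same_chrom[ok]]
  contiguous[okc] <- (pos[hi[okc]] - pos[lo[okc]]) == 2 * w
  gap_in_win <- rep(NA, length(idx))
  diffs_in_win <- rep(NA_integer_, length(idx))
  gap_in_win[okc] <- (cum_gap[hi[okc]] - c(0, cum_gap)[lo[okc]]) > 0
  diffs_in_win[okc] <- cum_diff[hi[okc]] - c(0, cum_diff)[lo[okc]]

  og <- toupper(columns$outgroup_base[idx])
  og[!(og %in% acgt)] <- NA_character_

  reason <- rep("pass", length(idx))
  reason[!in_range | !same_chrom] <- "edge"
  sel <- reason == "pass" & gap_in_win
  reason[sel] <- "indel"
  sel <- reason == "pass" & !contiguous
  reason[sel] <- "edge"
  sel <- reason == "pass" & diffs_in_win > 2
  reason[sel] <- "too_many_diffs"
  sel <- reason == "pass" & is.na(og)
  reason[sel] <- "no_outgroup"

  out <- data.frame(chrom = chrom[idx], pos = pos[idx],
                    target_base = tb[idx], query_base = qb[idx],
                    outgroup_base = og,
                    passed_filters = reason == "pass",
                    filter_reason = reason, stringsAsFactors = FALSE)
  if (verbose) {
    tab <- table(factor(reason, levels = c("pass", "indel", "too_many_diffs",
                                           "no_outgroup", "edge")))
    message("call_snds: ", paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  out
}

empty_snd_records <- function() {
  data.frame(chrom = character(), pos = numeric(), target_base = character(),
             query_base = character(), outgroup_base = character(),
             passed_filters = logical(), filter_reason = character(),
             stringsAsFactors = FALSE)
}

#' Polarize SND records with the outgroup base
#'
#' An SND is derived in the query when the target base equals the
#' outgroup base, derived in the target when the query base equals the
#' outgroup base, and inconclusive otherwise.  A conclusive SND is a
#' biased (weak-to-strong) substitution when the outgroup base is A or T
#' and the derived base is C or G.
#'
#' @param records SND records from [call_snds()].
#' @return The records with `derivation` ("derived_in_target",
#'   "derived_in_query" or "inconclusive"; `NA` for records that failed
#'   the filters) and logical `biased` columns added.  Inconclusive
#'   records carry `biased = FALSE` and are excluded downstream.
#' @export
polarize_snds <- function(records) {
  n <- nrow(records)
  derivation <- rep(NA_character_, n)
  ok <- records$passed_filters & !is.na(records$outgroup_base)
  tg <- records$target_base
  qr <- records$query_base
  og <- records$outgroup_base
  derivation[ok & tg == og] <- "derived_in_query"
  derivation[ok & qr == og] <- "derived_in_target"
  derivation[ok & tg != og & qr != og] <- "inconclusive"
  derived <- ifelse(derivation == "derived_in_target", tg,
                    ifelse(derivation == "derived_in_query", qr, NA_character_))
  biased <- !is.na(derivation) & derivation != "inconclusive" &
    og %in% c("A", "T") & derived %in% c("C", "G")
  records$derivation <- derivation
  records$biased <- biased
  records
}
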