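#' Read a pairwise MAF into aligned columns
#'
#' Each alignment block must carry exactly two "s" lines: the target
#' sequence first, the query second.  Chromosome names are taken from
#' the part of the source name after the first dot.  The target must be
#' on the "+" strand; minus-strand query text in a MAF is already
#' reverse-complemented into target orientation and is used as given.
#' Columns are emitted in target-coordinate order; target-gap columns
#' (query insertions) are preserved, carrying the coordinate of the
#' next target base, so downstream context filters can see them.
#'
#' @param path MAF file path.
#' @return A data frame of aligned columns (`outgroup_base` all `NA`;
#'   join an outgroup with [add_outgroup()]).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  empty_cols <- data.frame(chrom = character(), pos = numeric(),
                           target_base = character(), query_base = character(),
                           outgroup_base = character(), stringsAsFactors = FALSE)
  s_idx <- which(startsWith(lines, "s "))
  if (length(s_idx) == 0) return(empty_cols)
  a_idx <- which(startsWith(lines, "a"))
  blocks <- findInterval(s_idx, a_idx)
  out <- list()
  last_end <- list()
  for (b in unique(blocks)) {
    si <- s_idx[blocks == b]
    if (length(si) != 2)
      stop("MAF block ", b, " has ", length(si),
           " 's' lines; exactly a target and a query sequence are required")
    tf <- strsplit(trimws(lines[si[1]]), "\\s+")[[1]]
    qf <- strsplit(trimws(lines[si[2]]), "\\s+")[[1]]
    if (length(tf) != 7 || length(qf) != 7)
      stop("malformed 's' line in MAF block ", b)
    if (tf[5] != "+")
      stop("target sequence of MAF block ", b, " is not on the + strand")
    chrom <- sub("^[^.]*\\.", "", tf[2])
    start <- as.numeric(tf[3])
    tseq <- toupper(strsplit(tf[7], "")[[1]])
    qseq <- toupper(strsplit(qf[7], "")[[1]])
    if (length(tseq) != length(qseq))
      stop("sequence length mismatch in MAF block ", b)
    tpos <- start + cumsum(tseq != "-") - (tseq != "-")
    prev <- last_end[[chrom]]
    if (!is.null(prev) && start < prev)
      stop("MAF blocks out of order or overlapping on target ", chrom,
           " at position ", start)
    last_end[[chrom]] <- start + sum(tseq != "-")
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom, pos = tpos, target_base = tseq, query_base = qseq,
      outgroup_base = NA_character_, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Join outgroup bases onto aligned columns by target coordinate
#'
#' @param columns Aligned columns, e.g. from [read_maf()].
#' @param outgroup Either a data frame with columns `chrom`, `pos` and
#'   `outgroup_base`, or the path of a three-way TSV whose outgroup
#'   column is used.
#' @return The columns with `outgroup_base` filled where available.
#' @export
add_outgroup <- function(columns, outgroup) {
  if (is.character(outgroup)) outgroup <- read_threeway_tsv(outgroup)
  stopifnot(all(c("chrom", "pos", "outgroup_base") %in% names(outgroup)))
  key <- paste(columns$chrom, columns$pos)
  okey <- paste(outgroup$chrom, outgroup$pos)
  hit <- match(key, okey)
  columns$outgroup_base <- ifelse(is.na(hit), NA_character_,
                                  toupper(outgroup$outgroup_base[hit]))
  columns
}

#' Write or read a UBCS profile as BED-like TSV
#'
#' Columns: `chromosome`, `region_start`, `region_end`, `n_subs`,
#' `p_hat`, `observed`, `expected`, `ubcs`, `partial` (0/1).  Profile
#' metadata (direction, pair label, region size, chromosome lengths)
#' travels in header comments; floats are serialized with 17
#' significant digits so the round trip is lossless.
#'
#' @param profile A [ubcs_profile()].
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile`
#'   returns the profile.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ubcs_profile"))
  lens <- attr(profile, "chrom_lengths")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#direction=%s", attr(profile, "direction")),
               sprintf("#pair=%s", attr(profile, "pair")),
               sprintf("#region_size=%s",
                       format(attr(profile, "region_size"), scientific = FALSE))),
             con)
  for (ch in names(lens))
    writeLines(sprintf("#chrom_length\t%s\t%s", ch,
                       format(lens[[ch]], scientific = FALSE)), con)
  writeLines(paste(c("chromosome", "region_start", "region_end", "n_subs",
                     "p_hat", "observed", "expected", "ubcs", "partial"),
                   collapse = "\t"), con)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  writeLines(sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                     profile$chrom,
                     format(profile$region_start, scientific = FALSE, trim = TRUE),
                     format(profile$region_end, scientific = FALSE, trim = TRUE),
                     profile$n_subs, num(profile$p_hat),
                     num(profile$observed), num(profile$expected),
                     num(profile$ubcs), as.integer(profile$partial)), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(paste0("^#", key, "="), "", hit[1])
  }
  lens_lines <- grep("^#chrom_length\t", meta, value = TRUE)
  lens <- NULL
  if (length(lens_lines) > 0) {
    parts <- strsplit(lens_lines, "\t", fixed = TRUE)
    lens <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
    names(lens) <- vapply(parts, function(p) p[2], character(1))
  }
  df <- read.delim(text = body, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chromosome", "region_start", "region_end", "n_subs", "p_hat",
            "observed", "expected", "ubcs", "partial")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("profile file lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(chrom = df$chromosome, region_start = df$region_start,
                    region_end = df$region_end, n_subs = df$n_subs,
                    p_hat = df$p_hat, observed = df$observed,
                    expected = df$expected, ubcs = df$ubcs,
                    partial = df$partial == 1, stringsAsFactors = FALSE)
  structure(out,
            direction = get_meta("direction"),
            pair = get_meta("pair"),
            region_size = as.numeric(get_meta("region_size")),
            chrom_lengths = lens,
            class = c("ubcs_profile", "data.frame"))
}
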