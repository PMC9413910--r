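#' Substitution catalog
#'
#' A catalog holds, for one species pair and one derivation direction,
#' the sorted positions of derived substitutions per chromosome together
#' with their weak-to-strong ("biased") labels.
#'
#' @param substitutions Data frame with columns `chrom`, `pos` (0-based),
#'   `biased` (logical or 0/1); optionally `derived_base` and
#'   `ancestral_base`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param direction Either "derived_in_target" or "derived_in_query".
#' @return An object of class `ubcs_catalog`.
#' @export
ubcs_catalog <- function(substitutions, chrom_lengths,
                         direction = c("derived_in_target", "derived_in_query")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(substitutions),
            all(c("chrom", "pos", "biased") %in% names(substitutions)),
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  df <- substitutions
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$biased <- as.logical(df$biased)
  if (anyNA(df$biased)) stop("biased labels must be TRUE/FALSE")
  if (any(df$pos < 0)) stop("positions must be nonnegative")
  unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
  if (length(unknown) > 0)
    stop("chromosomes without a length: ", paste(unknown, collapse = ", "))
  if (any(df$pos >= chrom_lengths[df$chrom]))
    stop("positions beyond the chromosome length")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  n <- nrow(df)
  if (n > 1) {
    dup <- c(FALSE, df$chrom[-1] == df$chrom[-n] & df$pos[-1] == df$pos[-n])
    if (any(dup)) {
      di <- which(dup)
      conflict <- df$biased[di] != df$biased[di - 1L]
      if (any(conflict)) {
        i <- di[conflict][1]
        stop("conflicting bias labels at ", df$chrom[i], " ", df$pos[i])
      }
      df <- df[!dup, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(list(substitutions = df,
                 chrom_lengths = chrom_lengths[sort(names(chrom_lengths))],
                 direction = direction),
            class = "ubcs_catalog")
}

#' @export
print.ubcs_catalog <- function(x, ...) {
  cat("UBCS substitution catalog (", x$direction, ")\n", sep = "")
  cat("  chromosomes:", length(x$chrom_lengths),
      " substitutions:", nrow(x$substitutions),
      " biased:", sum(x$substitutions$biased), "\n")
  invisible(x)
}

#' Build a direction-specific catalog from polarized SND records
#'
#' Retains the records that passed all filters and whose derivation
#' matches `direction`, sorts and deduplicates positions, and preserves
#' the bias labels.  Duplicate positions with conflicting labels raise an
#' error naming the coordinate.
#'
#' @param records Polarized SND records from [polarize_snds()].
#' @param direction "derived_in_target" or "derived_in_query".
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return A [ubcs_catalog()] object.
#' @export
build_catalog <- function(records, direction = c("derived_in_target", "derived_in_query"),
                          chrom_lengths) {
  direction <- match.arg(direction)
  stopifnot(all(c("chrom", "pos", "passed_filters", "derivation", "biased") %in%
                  names(records)))
  keep <- records$passed_filters & !is.na(records$derivation) &
    records$derivation == direction
  df <- records[keep, , drop = FALSE]
  to_target <- direction == "derived_in_target"
  derived <- if (to_target) df$target_base else df$query_base
  ancestral <- if (to_target) df$query_base else df$target_base
  ubcs_catalog(data.frame(chrom = df$chrom, pos = df$pos, biased = df$biased,
                          derived_base = derived, ancestral_base = ancestral,
                          stringsAsFactors = FALSE),
               chrom_lengths, direction)
}

#' Write or read a substitution catalog as TSV
#'
#' The format is tab-separated with columns `chromosome`, `position`,
#' `derived_base`, `ancestral_base`, `direction` and `biased` (0/1);
#' chromosome lengths are stored in `#chrom_length` header comments so
#' the round trip is lossless.
#'
#' @param catalog A [ubcs_catalog()].
#' @param path Output (or input) file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog`
#'   returns a [ubcs_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ubcs_catalog"))
  df <- catalog$substitutions
  if (is.null(df$derived_base)) df$derived_base <- ifelse(df$biased, "G", "A")
  if (is.null(df$ancestral_base)) df$ancestral_base <- ifelse(df$biased, "A", "G")
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(catalog$chrom_lengths))
    writeLines(sprintf("#chrom_length\t%s\t%s", ch,
                       format(catalog$chrom_lengths[[ch]], scientific = FALSE)), con)
  writeLines(paste(c("chromosome", "position", "derived_base", "ancestral_base",
                     "direction", "biased"), collapse = "\t"), con)
  out <- data.frame(df$chrom, format(df$pos, scientific = FALSE, trim = TRUE),
                    df$derived_base, df$ancestral_base,
                    catalog$direction, as.integer(df$biased))
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#chrom_length\t", lines, value = TRUE)
  lens <- NULL
  if (length(hdr) > 0) {
    parts <- strsplit(hdr, "\t", fixed = TRUE)
    lens <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
    names(lens) <- vapply(parts, function(p) p[2], character(1))
  }
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1) stop("catalog file has no data rows: ", path)
  df <- read.delim(text = body, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chromosome", "position", "derived_base", "ancestral_base",
            "direction", "biased")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("catalog file lacks column(s): ", paste(missing_cols, collapse = ", "))
  direction <- unique(df$direction)
  if (length(direction) != 1)
    stop("catalog mixes derivation directions")
  if (is.null(lens))
    stop("catalog file lacks #chrom_length headers: ", path)
  ubcs_catalog(data.frame(chrom = df$chromosome, pos = df$position,
                          biased = df$biased == 1,
                          derived_base = df$derived_base,
                          ancestral_base = df$ancestral_base,
                          stringsAsFactors = FALSE),
               lens, direction)
}
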