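#' Construct a table of genomic intervals
#'
#' Intervals are kept in the package-wide internal convention: 0-based,
#' half-open \code{[start, end)}, so an interval of length 1 at the first base
#' of a chromosome is \code{start = 0, end = 1}. BED files are already in this
#' convention; 1-based inclusive coordinates (gene-model TSVs, GTF, printed
#' genome-browser coordinates) are converted at the reading boundary.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions; must satisfy
#'   \code{start < end}.
#' @param strand character vector in \code{"+"}, \code{"-"}, \code{"."};
#'   recycled if length 1.
#' @param ... further equal-length columns carried along (e.g. \code{name},
#'   \code{score}).
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} and any extra columns, one row per interval.
#' @examples
#' genomic_intervals("chr1", 0L, 100L)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  n <- length(chrom)
  if (length(strand) == 1L) strand <- rep(strand, n)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the internal-convention invariants: non-empty chromosome names,
#' \code{0 <= start < end}, strand in \code{+ - .}.
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} columns.
#' @return \code{x}, invisibly; errors describe the first offending row.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("interval table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    stop("empty chromosome name at row ", which(is.na(x$chrom) | !nzchar(x$chrom))[1L])
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0L | x$start >= x$end)
  if (length(bad) > 0L) {
    stop(
      "invalid interval at row ", bad[1L], ": start=", x$start[bad[1L]],
      " end=", x$end[bad[1L]], " (need 0 <= start < end)"
    )
  }
  badstr <- which(!x$strand %in% c("+", "-", "."))
  if (length(badstr) > 0L) {
    stop("invalid strand '", x$strand[badstr[1L]], "' at row ", badstr[1L])
  }
  invisible(x)
}

#' Convert printed 1-based inclusive coordinates to an internal interval
#'
#' Genome browsers and papers print coordinates like
#' "chr7: 121,943,497-121,943,663", which are 1-based and inclusive at both
#' ends. Internally the same region is \code{[start_1based - 1, end_1based)}.
#'
#' @param chrom chromosome name.
#' @param start_1based,end_1based printed bounds, \code{1 <= start <= end}.
#' @param strand optional strand, default \code{"."}.
#' @return a one-row interval data.frame (see [genomic_intervals()]).
#' @examples
#' iv <- convert_printed_coords("chr7", 121943497, 121943663)
#' iv$end - iv$start  # 167 bp
#' @export
convert_printed_coords <- function(chrom, start_1based, end_1based, strand = ".") {
  if (any(start_1based < 1)) stop("printed coordinates are 1-based; start must be >= 1")
  if (any(start_1based > end_1based)) stop("printed start exceeds end")
  genomic_intervals(chrom, as.integer(start_1based) - 1L, as.integer(end_1based),
    strand = strand
  )
}

#' Display internal intervals as 1-based inclusive coordinate strings
#'
#' Inverse of [convert_printed_coords()]: internal \code{[start, end)} is shown
#' as \code{chrom:start+1-end}.
#'
#' @param x interval data.frame.
#' @return character vector, one printed coordinate per row.
#' @export
format_printed_coords <- function(x) {
  validate_intervals(x)
  sprintf("%s:%d-%d", x$chrom, x$start + 1L, x$end)
}

# length-n logical: does interval i of a overlap >= min_bp bases with any row of b
# (strand-blind). Plain O(n*m) on vectors; callers operate at peak/locus scale.
overlaps_any <- function(a, b, min_bp = 1L) {
  if (nrow(b) == 0L || nrow(a) == 0L) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    if (!any(same)) return(FALSE)
    ov <- pmin(b$end[same], a$end[i]) - pmax(b$start[same], a$start[i])
    any(ov >= min_bp)
  }, logical(1L))
}
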