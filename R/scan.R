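#' Scanner configuration for GGAA-family microsatellites
#'
#' A microsatellite locus is defined as a maximal in-frame tiling of 4-mer
#' blocks drawn from the repeat unit and an allowed set of single-block
#' interruptions, with the boundaries trimmed so the locus begins and ends on
#' a perfect unit. The defaults target the GGAA multimerized ETS-binding
#' element with GGAG interruptions intercalated among the GGAA units, the
#' structure seen at fusion-oncoprotein-responsive enhancers.
#'
#' @param unit 4-mer repeat unit (default \code{"GGAA"}).
#' @param allowed_interruptions character vector of 4-mers that may interrupt
#'   the tract without breaking it (default \code{"GGAG"}); must differ from
#'   \code{unit}.
#' @param min_seed_run minimum number of consecutive perfect units required to
#'   nucleate a reported locus (default 4).
#' @param min_total_units minimum number of perfect units in a reported locus
#'   (default 8). Together with \code{min_seed_run} this suppresses the
#'   genome-wide background of short GGAA runs.
#' @param scan_both_strands if TRUE (default), the reverse-complement unit
#'   (TTCC for GGAA) is also scanned and reported as a minus-strand locus in
#'   forward-sequence coordinates.
#' @return a \code{ggaa_scan_config} list.
#' @export
scan_config <- function(unit = "GGAA", allowed_interruptions = "GGAG",
                        min_seed_run = 4L, min_total_units = 8L,
                        scan_both_strands = TRUE) {
  unit <- toupper(unit)
  allowed_interruptions <- toupper(allowed_interruptions)
  if (nchar(unit) != 4L) stop("repeat unit must be a 4-mer")
  if (any(nchar(allowed_interruptions) != 4L)) {
    stop("interruption units must be 4-mers")
  }
  if (unit %in% allowed_interruptions) {
    stop("interruption set must not contain the unit itself")
  }
  if (min_seed_run < 1L) stop("min_seed_run must be >= 1")
  if (min_total_units < min_seed_run) {
    stop("min_total_units must be >= min_seed_run")
  }
  structure(
    list(
      unit = unit, allowed_interruptions = allowed_interruptions,
      min_seed_run = as.integer(min_seed_run),
      min_total_units = as.integer(min_total_units),
      scan_both_strands = isTRUE(scan_both_strands)
    ),
    class = "ggaa_scan_config"
  )
}

#' Reverse-complement a DNA string
#'
#' @param seq DNA string over A, C, G, T, N (case preserved as upper).
#' @return the reverse complement.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr(
      "ACGTN", "TGCAN",
      paste(rev(strsplit(toupper(s), "", fixed = TRUE)[[1L]]), collapse = "")
    )
  }, character(1L), USE.NAMES = FALSE)
}

# all (overlapping) start positions of a fixed 4-mer in seq, 1-based
kmer_positions <- function(seq, kmer) {
  m <- gregexpr(paste0("(?=", kmer, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

# scan one strand of one sequence; returns 0-based half-open loci on that
# strand's own coordinates. code: 2 = unit, 1 = interruption, 0 = neither.
scan_one_strand <- function(seq, config) {
  n <- nchar(seq)
  empty <- data.frame(
    start = integer(), end = integer(), total_units = integer(),
    longest_run = integer(), interruption_count = integer(),
    sequence = character(), stringsAsFactors = FALSE
  )
  if (n < 4L) return(empty)
  code <- integer(n - 3L)
  code[kmer_positions(seq, config$unit)] <- 2L
  for (intr in config$allowed_interruptions) {
    p <- kmer_positions(seq, intr)
    code[p[code[p] == 0L]] <- 1L
  }
  hits <- which(code > 0L)
  if (length(hits) == 0L) return(empty)
  # chain starts: in-frame predecessor block absent
  starts <- hits[hits <= 4L | code[pmax(hits - 4L, 1L)] == 0L]
  starts <- starts[code[starts] > 0L]
  loci <- vector("list", length(starts))
  k <- 0L
  for (p in starts) {
    q <- p
    while (q + 4L <= n - 3L && code[q + 4L] > 0L) q <- q + 4L
    blocks <- code[seq.int(p, q, by = 4L)]
    # trim boundaries to perfect units
    u <- which(blocks == 2L)
    if (length(u) == 0L) next
    blocks <- blocks[u[1L]:u[length(u)]]
    p2 <- p + (u[1L] - 1L) * 4L
    total_units <- sum(blocks == 2L)
    runs <- rle(blocks)
    longest_run <- max(runs$lengths[runs$values == 2L])
    if (total_units < config$min_total_units || longest_run < config$min_seed_run) next
    k <- k + 1L
    e2 <- p2 + length(blocks) * 4L # 1-based exclusive
    loci[[k]] <- data.frame(
      start = p2 - 1L, end = e2 - 1L, total_units = total_units,
      longest_run = longest_run,
      interruption_count = sum(blocks == 1L),
      sequence = substring(seq, p2, e2 - 1L), stringsAsFactors = FALSE
    )
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, loci[seq_len(k)])
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  # chains in shifted frames can overlap for self-overlapping units; keep a
  # deterministic non-overlapping subset (earlier start, then longer, wins)
  keep <- logical(nrow(out))
  last_end <- -1L
  for (i in seq_len(nrow(out))) {
    if (out$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- out$end[i]
    }
  }
  out[keep, , drop = FALSE]
}

#' Scan DNA for GGAA-family tandem microsatellites
#'
#' Reports every maximal in-frame tiling of unit/interruption 4-mer blocks
#' that begins and ends with a perfect unit, contains at least
#' \code{min_total_units} perfect units and a contiguous run of at least
#' \code{min_seed_run} of them. Positions containing N never match. With
#' \code{scan_both_strands}, the reverse complement is scanned and loci are
#' reported as minus-strand intervals on the forward coordinates, with
#' \code{sequence} given on the unit's own strand.
#'
#' @param sequences named character vector of DNA sequences (names become
#'   chromosome names), or a single unnamed string (chromosome \code{"seq"}).
#' @param config a [scan_config()] object.
#' @return interval data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{total_units},
#'   \code{longest_run}, \code{interruption_count}, \code{sequence}; sorted by
#'   chromosome and start. Loci on the same strand never overlap.
#' @examples
#' scan_microsatellites(strrep("GGAA", 10), scan_config())
#' @export
scan_microsatellites <- function(sequences, config = scan_config()) {
  if (!inherits(config, "ggaa_scan_config")) stop("config must come from scan_config()")
  if (is.null(names(sequences))) {
    if (length(sequences) != 1L) stop("multiple sequences must be named")
    names(sequences) <- "seq"
  }
  res <- list()
  for (chrom in names(sequences)) {
    seq <- toupper(sequences[[chrom]])
    n <- nchar(seq)
    plus <- scan_one_strand(seq, config)
    if (nrow(plus) > 0L) {
      plus <- data.frame(
        chrom = chrom, start = plus$start, end = plus$end, strand = "+",
        plus[c("total_units", "longest_run", "interruption_count", "sequence")],
        stringsAsFactors = FALSE
      )
      res[[length(res) + 1L]] <- plus
    }
    if (config$scan_both_strands && n >= 4L) {
      minus <- scan_one_strand(revcomp(seq), config)
      if (nrow(minus) > 0L) {
        minus <- data.frame(
          chrom = chrom, start = n - minus$end, end = n - minus$start,
          strand = "-",
          minus[c("total_units", "longest_run", "interruption_count", "sequence")],
          stringsAsFactors = FALSE
        )
        res[[length(res) + 1L]] <- minus
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), total_units = integer(), longest_run = integer(),
      interruption_count = integer(), sequence = character(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  validate_intervals(out)
  out
}

#' Summarize scanned loci as a display table
#'
#' Coordinates are shown 1-based inclusive (browser style); internal
#' half-open \code{[start, end)} maps to \code{start+1 .. end}.
#'
#' @param loci output of [scan_microsatellites()].
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{strand}, \code{total_units}, \code{longest_run},
#'   \code{interruption_count}, sorted by (chrom, start).
#' @export
locus_summary <- function(loci) {
  out <- data.frame(
    chrom = loci$chrom, start = loci$start + 1L, end = loci$end,
    strand = loci$strand, total_units = loci$total_units,
    longest_run = loci$longest_run,
    interruption_count = loci$interruption_count,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
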