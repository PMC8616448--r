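# round half away from zero (the convention used for printed percentages;
# base R round() is banker's rounding)
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Transcription start site of each gene
#'
#' In half-open coordinates the first transcribed base is \code{start} for a
#' plus-strand gene and \code{end - 1} for a minus-strand gene.
#'
#' @param genes gene-model data.frame with \code{start}, \code{end},
#'   \code{strand} (+/- only).
#' @return integer vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("gene ", genes$gene_id[bad[1L]], ": strand required to define the TSS")
  }
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Flag ChIP-seq peaks coincident with microsatellite loci
#'
#' A peak is microsatellite-coincident when it overlaps at least
#' \code{min_overlap_bp} bases of any locus, on either strand. Peak order is
#' preserved.
#'
#' @param peaks interval data.frame of peaks.
#' @param msat_loci interval data.frame of microsatellite loci (e.g. from
#'   [scan_microsatellites()]).
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return \code{peaks} with a logical \code{msat_coincident} column added.
#' @export
annotate_peaks_with_msats <- function(peaks, msat_loci, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  validate_intervals(peaks)
  validate_intervals(msat_loci)
  peaks$msat_coincident <- overlaps_any(peaks, msat_loci, min_bp = as.integer(min_overlap_bp))
  peaks
}

#' Which genes contain a peak within their genomic span
#'
#' "Inside the gene" means the full genomic span, introns included. The
#' containment rule is configurable: \code{any-overlap} (>= 1 bp of the peak
#' overlaps the gene body; default), \code{fully-contained} (the whole peak
#' lies within the gene body), or \code{midpoint-inside} (the peak midpoint,
#' \code{floor((start+end)/2)}, lies within the gene body).
#'
#' @param genes gene-model data.frame.
#' @param peaks interval data.frame, typically pre-filtered to
#'   microsatellite-coincident peaks.
#' @param rule containment rule, see above.
#' @return data.frame, one row per gene in input order: \code{gene_id},
#'   \code{has_internal_peak}, \code{n_internal_peaks}, \code{peaks}
#'   (comma-separated 1-based coordinates of the overlapping peaks, or "").
#' @export
genes_with_internal_peaks <- function(genes, peaks,
                                      rule = c("any-overlap", "fully-contained", "midpoint-inside")) {
  rule <- match.arg(rule)
  validate_intervals(genes)
  validate_intervals(peaks)
  hit_rows <- lapply(seq_len(nrow(genes)), function(i) {
    same <- which(peaks$chrom == genes$chrom[i])
    if (length(same) == 0L) return(integer())
    s <- peaks$start[same]
    e <- peaks$end[same]
    gs <- genes$start[i]
    ge <- genes$end[i]
    ok <- switch(rule,
      "any-overlap" = pmin(e, ge) - pmax(s, gs) >= 1L,
      "fully-contained" = s >= gs & e <= ge,
      "midpoint-inside" = {
        mid <- (s + e) %/% 2L
        mid >= gs & mid < ge
      }
    )
    same[ok]
  })
  data.frame(
    gene_id = genes$gene_id,
    has_internal_peak = lengths(hit_rows) > 0L,
    n_internal_peaks = lengths(hit_rows),
    peaks = vapply(hit_rows, function(idx) {
      if (length(idx) == 0L) "" else paste(format_printed_coords(peaks[idx, ]), collapse = ",")
    }, character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Nearest peak on each side of every gene's TSS
#'
#' For each gene, finds the nearest peak upstream and downstream of the
#' transcription start site within a window, in the gene's strand frame: for
#' a minus-strand gene, genomically rightward of the TSS is upstream. The
#' distance is the minimum gap between the TSS and either peak edge; a peak
#' overlapping the TSS is reported on the downstream side with distance 0.
#' Equidistant peaks on one side are broken deterministically (smaller start
#' wins) and all ties are listed.
#'
#' @param genes gene-model data.frame (strand required).
#' @param peaks interval data.frame of peaks.
#' @param max_distance_bp search window on each side of the TSS, in bases
#'   (default 10000); peaks farther than this are excluded.
#' @return data.frame with one row per (gene, side) for which a peak was
#'   found: \code{gene_id}, \code{relation} (upstream/downstream),
#'   \code{chrom}, \code{peak_start}, \code{peak_end} (internal 0-based
#'   half-open), \code{distance_bp}, and \code{tie_peaks} (comma-separated
#'   1-based coordinates of every equidistant peak, "" when unique).
#' @export
nearest_peaks_to_tss <- function(genes, peaks, max_distance_bp = 10000L) {
  if (max_distance_bp < 0L) stop("max_distance_bp must be >= 0")
  validate_intervals(genes)
  validate_intervals(peaks)
  tss <- gene_tss(genes)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    same <- which(peaks$chrom == genes$chrom[i])
    if (length(same) == 0L) next
    s <- peaks$start[same]
    e <- peaks$end[same]
    t0 <- tss[i]
    over <- s <= t0 & t0 < e
    left <- e <= t0 & !over
    dist <- ifelse(over, 0L, ifelse(left, t0 - e, s - t0))
    # gene-strand frame: + strand, genomic left = upstream; - strand, swapped.
    # TSS-overlapping peaks go downstream by the stated tie rule.
    side <- ifelse(over, "downstream",
      ifelse(left == (genes$strand[i] == "+"), "upstream", "downstream")
    )
    ok <- dist <= max_distance_bp
    for (rel in c("upstream", "downstream")) {
      idx <- which(ok & side == rel)
      if (length(idx) == 0L) next
      dmin <- min(dist[idx])
      best <- idx[dist[idx] == dmin]
      best <- best[order(s[best])]
      pick <- best[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], relation = rel,
        chrom = genes$chrom[i],
        peak_start = s[pick], peak_end = e[pick],
        distance_bp = as.integer(dmin),
        tie_peaks = if (length(best) > 1L) {
          paste(format_printed_coords(peaks[same[best], ]), collapse = ",")
        } else "",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      gene_id = character(), relation = character(), chrom = character(),
      peak_start = integer(), peak_end = integer(), distance_bp = integer(),
      tie_peaks = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count and percentage of genes carrying an internal peak
#'
#' @param gene_flags logical vector (one per gene), e.g. the
#'   \code{has_internal_peak} column of [genes_with_internal_peaks()].
#' @return list with \code{n_with}, \code{n_total} and \code{percentage}
#'   (rounded to the nearest integer, half away from zero).
#' @examples
#' count_genes_with_peaks(rep(c(TRUE, FALSE), c(180, 1276)))$percentage # 12
#' @export
count_genes_with_peaks <- function(gene_flags) {
  if (length(gene_flags) == 0L) stop("empty gene flag vector")
  n_with <- sum(gene_flags)
  n_total <- length(gene_flags)
  list(
    n_with = n_with, n_total = n_total,
    percentage = round_half_away(100 * n_with / n_total)
  )
}
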