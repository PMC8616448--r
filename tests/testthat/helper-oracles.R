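# Independent brute-force oracles. These re-derive every quantity from the
# definition, by exhaustive search over substrings / pairs / tables, and are
# deliberately kept free of the package's own scanning and interval code.

# --- exhaustive-tiling microsatellite oracle -------------------------------

# every maximal in-frame tiling of unit/interruption blocks, found by testing
# each 4-mer block membership with plain substring equality and walking the
# per-frame boolean run structure; then trimmed to perfect units and filtered.
oracle_scan_one_strand <- function(seq, cfg) {
  n <- nchar(seq)
  out <- list()
  if (n >= 4L) {
    inset <- function(p) {
      b <- substr(seq, p, p + 3L)
      if (b == cfg$unit) 2L else if (b %in% cfg$allowed_interruptions) 1L else 0L
    }
    for (frame in 0:3) {
      ps <- seq.int(frame + 1L, n - 3L, by = 4L)
      if (length(ps) == 0L || ps[1L] > n - 3L) next
      codes <- vapply(ps, inset, integer(1L))
      r <- rle(codes > 0L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        blk <- codes[starts[j]:ends[j]]
        u <- which(blk == 2L)
        if (length(u) == 0L) next
        blk <- blk[u[1L]:u[length(u)]]
        p0 <- ps[starts[j] + u[1L] - 1L]
        runs <- rle(blk)
        lr <- max(runs$lengths[runs$values == 2L])
        tu <- sum(blk == 2L)
        if (tu < cfg$min_total_units || lr < cfg$min_seed_run) next
        out[[length(out) + 1L]] <- data.frame(
          start = p0 - 1L, end = p0 - 1L + 4L * length(blk),
          total_units = tu, longest_run = lr,
          interruption_count = sum(blk == 1L),
          sequence = substr(seq, p0, p0 + 4L * length(blk) - 1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      start = integer(), end = integer(), total_units = integer(),
      longest_run = integer(), interruption_count = integer(),
      sequence = character(), stringsAsFactors = FALSE
    ))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, -(df$end - df$start)), , drop = FALSE]
  keep <- logical(nrow(df))
  last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  df[keep, , drop = FALSE]
}

oracle_scan <- function(seq, cfg, chrom = "seq") {
  plus <- oracle_scan_one_strand(seq, cfg)
  res <- list()
  if (nrow(plus) > 0L) {
    res[[1L]] <- cbind(
      data.frame(chrom = chrom, stringsAsFactors = FALSE),
      plus[c("start", "end")], strand = "+",
      plus[c("total_units", "longest_run", "interruption_count", "sequence")]
    )
  }
  if (cfg$scan_both_strands) {
    n <- nchar(seq)
    minus <- oracle_scan_one_strand(revcomp(seq), cfg)
    if (nrow(minus) > 0L) {
      res[[length(res) + 1L]] <- cbind(
        data.frame(chrom = chrom, stringsAsFactors = FALSE),
        data.frame(start = n - minus$end, end = n - minus$start),
        strand = "-",
        minus[c("total_units", "longest_run", "interruption_count", "sequence")]
      )
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
  df <- do.call(rbind, res)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- all-pairs interval oracles --------------------------------------------

oracle_overlap_flags <- function(peaks, loci, min_bp = 1L) {
  flags <- rep(FALSE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(loci))) {
      if (peaks$chrom[i] != loci$chrom[j]) next
      ov <- min(peaks$end[i], loci$end[j]) - max(peaks$start[i], loci$start[j])
      if (ov >= min_bp) flags[i] <- TRUE
    }
  }
  flags
}

oracle_inside <- function(genes, peaks, rule) {
  vapply(seq_len(nrow(genes)), function(i) {
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != genes$chrom[i]) next
      hit <- switch(rule,
        "any-overlap" = min(peaks$end[j], genes$end[i]) -
          max(peaks$start[j], genes$start[i]) >= 1L,
        "fully-contained" = peaks$start[j] >= genes$start[i] &&
          peaks$end[j] <= genes$end[i],
        "midpoint-inside" = {
          mid <- (peaks$start[j] + peaks$end[j]) %/% 2L
          mid >= genes$start[i] && mid < genes$end[i]
        }
      )
      if (hit) return(TRUE)
    }
    FALSE
  }, logical(1L))
}

# per gene, per side: nearest-distance and the winning peak index, or NULL
oracle_nearest_tss <- function(genes, peaks, window) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    t0 <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
    best <- list(upstream = NULL, downstream = NULL)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != genes$chrom[i]) next
      s <- peaks$start[j]
      e <- peaks$end[j]
      if (s <= t0 && t0 < e) {
        d <- 0L
        side <- "downstream"
      } else if (e <= t0) {
        d <- t0 - e
        side <- if (genes$strand[i] == "+") "upstream" else "downstream"
      } else {
        d <- s - t0
        side <- if (genes$strand[i] == "+") "downstream" else "upstream"
      }
      if (d > window) next
      b <- best[[side]]
      if (is.null(b) || d < b$d || (d == b$d && s < b$s)) {
        best[[side]] <- list(d = d, s = s, e = e)
      }
    }
    for (side in c("upstream", "downstream")) {
      if (!is.null(best[[side]])) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i], relation = side,
          peak_start = best[[side]]$s, peak_end = best[[side]]$e,
          distance_bp = best[[side]]$d, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      gene_id = character(), relation = character(),
      peak_start = integer(), peak_end = integer(),
      distance_bp = integer(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

# --- exact-test and FDR oracles --------------------------------------------

# upper-tail hypergeometric by direct enumeration of every table consistent
# with the margins, using base choose() and renormalisation
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0L, c1 - (c + d)):min(r1, c1)
  w <- choose(r1, ks) * choose(n - r1, c1 - ks)
  sum(w[ks >= a]) / sum(w)
}

# Benjamini-Hochberg step-up computed from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)
}

# --- random fixture builders -----------------------------------------------

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                             max_len = 120L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  genomic_intervals(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE),
    strand = "."
  )
}

random_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                         max_len = 300L) {
  g <- random_intervals(n, chroms, max_pos, max_len)
  g$strand <- sample(c("+", "-"), n, replace = TRUE)
  g$gene_id <- sprintf("g%03d", seq_len(n))
  g[c("gene_id", "chrom", "start", "end", "strand")]
}

# random DNA with planted repeat tracts for scanner oracle tests
plant_random_sequence <- function(bg_len, n_loci, cfg, max_units = 8L) {
  seq <- paste(sample(c("A", "C", "G", "T"), bg_len, replace = TRUE), collapse = "")
  for (k in seq_len(n_loci)) {
    nu <- sample(2:max_units, 1L)
    blocks <- cfg$unit
    for (j in seq_len(nu - 1L)) {
      if (stats::runif(1) < 0.2) blocks <- c(blocks, sample(cfg$allowed_interruptions, 1L))
      blocks <- c(blocks, cfg$unit)
    }
    tract <- paste(blocks, collapse = "")
    if (stats::runif(1) < 0.5) tract <- revcomp(tract)
    pos <- sample.int(nchar(seq) - nchar(tract), 1L)
    substr(seq, pos, pos + nchar(tract) - 1L) <- tract
  }
  seq
}
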