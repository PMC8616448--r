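test_that("peak/microsatellite coincidence respects half-open boundaries", {
  loci <- genomic_intervals("chr1", c(49L, 50L), c(100L, 100L))
  p <- genomic_intervals("chr1", 10L, 50L)
  expect_true(annotate_peaks_with_msats(p, loci[1, ])$msat_coincident)
  expect_false(annotate_peaks_with_msats(p, loci[2, ])$msat_coincident)
  expect_error(annotate_peaks_with_msats(p, loci, min_overlap_bp = 0), ">= 1")
})

test_that("coincidence flags match the all-pairs oracle on random instances", {
  withr::local_seed(101)
  for (i in 1:60) {
    peaks <- random_intervals(sample(1:40, 1))
    loci <- random_intervals(sample(1:40, 1))
    min_bp <- sample(1:20, 1)
    got <- annotate_peaks_with_msats(peaks, loci, min_bp)$msat_coincident
    expect_identical(got, oracle_overlap_flags(peaks, loci, min_bp))
  }
})

test_that("coincidence flags also agree with the IRanges overlap engine", {
  withr::local_seed(909)
  for (i in 1:10) {
    peaks <- random_intervals(30, chroms = "chr1")
    loci <- random_intervals(30, chroms = "chr1")
    got <- annotate_peaks_with_msats(peaks, loci)$msat_coincident
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(peaks$start + 1L, peaks$end),
      IRanges::IRanges(loci$start + 1L, loci$end)
    )
    expect_identical(got, hits)
  }
})

test_that("inside-gene flags: no peaks -> all FALSE; contained peak -> TRUE", {
  genes <- data.frame(
    gene_id = "g1", chrom = "chr1", start = 1000L, end = 9000L,
    strand = "+", stringsAsFactors = FALSE
  )
  none <- genes_with_internal_peaks(genes, genomic_intervals(character(), integer(), integer()))
  expect_false(any(none$has_internal_peak))

  pk <- genomic_intervals("chr1", 3000L, 3200L)
  for (rule in c("any-overlap", "fully-contained", "midpoint-inside")) {
    expect_true(genes_with_internal_peaks(genes, pk, rule)$has_internal_peak)
  }
})

test_that("inside-gene flags match the oracle under every containment rule", {
  withr::local_seed(202)
  for (i in 1:60) {
    genes <- random_genes(sample(1:30, 1))
    peaks <- random_intervals(sample(1:30, 1))
    for (rule in c("any-overlap", "fully-contained", "midpoint-inside")) {
      got <- genes_with_internal_peaks(genes, peaks, rule)
      expect_identical(got$has_internal_peak, oracle_inside(genes, peaks, rule))
    }
  }
})

test_that("nearest-TSS distances follow the edge-gap definition", {
  genes <- data.frame(
    gene_id = "g", chrom = "c", start = 5000L, end = 9000L, strand = "+",
    stringsAsFactors = FALSE
  )
  peaks <- genomic_intervals("c", c(1000L, 5400L), c(1100L, 5500L))
  got <- nearest_peaks_to_tss(genes, peaks, 10000L)
  expect_identical(got$distance_bp[got$relation == "upstream"], 3900L)
  expect_identical(got$distance_bp[got$relation == "downstream"], 400L)

  spanning <- genomic_intervals("c", 4900L, 5100L)
  got <- nearest_peaks_to_tss(genes, spanning, 10000L)
  expect_identical(got$relation, "downstream")
  expect_identical(got$distance_bp, 0L)

  genes$strand <- "."
  expect_error(nearest_peaks_to_tss(genes, peaks), "strand")
})

test_that("genome reflection preserves gene-frame sides with the half-open one-base shift", {
  # reflecting gene and peak coordinates flips every strand, so the gene-frame
  # upstream/downstream labels are preserved. Because the edge-gap definition
  # counts the TSS base into downstream gaps (downstream = s - t, upstream =
  # t - e, as in the worked 3900/400 example), reflection shifts upstream
  # distances by +1 and non-zero downstream distances by -1, exactly.
  withr::local_seed(303)
  L <- 100000L
  for (i in 1:40) {
    genes <- random_genes(5, chroms = "c", max_pos = 5000L)
    peaks <- random_intervals(15, chroms = "c", max_pos = 6000L)
    fwd <- nearest_peaks_to_tss(genes, peaks, L)
    mg <- genes
    mg$start <- L - genes$end
    mg$end <- L - genes$start
    mg$strand <- ifelse(genes$strand == "+", "-", "+")
    mp <- peaks
    mp$start <- L - peaks$end
    mp$end <- L - peaks$start
    mir <- nearest_peaks_to_tss(mg, mp, L)
    key <- function(x) {
      x <- x[order(x$gene_id, x$relation), ]
      rownames(x) <- NULL
      x
    }
    a <- key(fwd)
    b <- key(mir)
    expect_identical(
      a[c("gene_id", "relation")],
      b[c("gene_id", "relation")]
    )
    gi <- match(a$gene_id, genes$gene_id)
    tss <- ifelse(genes$strand[gi] == "+", genes$start[gi], genes$end[gi] - 1L)
    spanning <- a$peak_start <= tss & tss < a$peak_end
    left_gap <- (genes$strand[gi] == "+") == (a$relation == "upstream")
    shift <- ifelse(spanning, 0L, ifelse(left_gap, 1L, -1L))
    expect_identical(b$distance_bp, a$distance_bp + shift)
  }
})

test_that("nearest-TSS assignments match the brute-force oracle on both strands", {
  withr::local_seed(404)
  for (i in 1:60) {
    genes <- random_genes(sample(1:20, 1))
    peaks <- random_intervals(sample(1:30, 1))
    window <- sample(c(0L, 50L, 200L, 1000L), 1)
    got <- nearest_peaks_to_tss(genes, peaks, window)
    exp <- oracle_nearest_tss(genes, peaks, window)
    cols <- c("gene_id", "relation", "peak_start", "peak_end", "distance_bp")
    o <- function(x) {
      x <- x[cols]
      x[order(x$gene_id, x$relation), ]
    }
    expect_equal(o(got), o(exp), ignore_attr = TRUE)
  }
})

test_that("shrinking the TSS window never adds assignments", {
  withr::local_seed(505)
  genes <- random_genes(20)
  peaks <- random_intervals(40)
  prev <- NULL
  for (w in c(2000L, 500L, 100L, 0L)) {
    cur <- nearest_peaks_to_tss(genes, peaks, w)
    if (!is.null(prev)) {
      expect_lte(nrow(cur), nrow(prev))
      expect_true(all(
        paste(cur$gene_id, cur$relation) %in% paste(prev$gene_id, prev$relation)
      ))
    }
    prev <- cur
  }
})

test_that("equidistant peaks break ties by smaller start and list all ties", {
  genes <- data.frame(
    gene_id = "g", chrom = "c", start = 5000L, end = 6000L, strand = "+",
    stringsAsFactors = FALSE
  )
  peaks <- genomic_intervals("c", c(5300L, 5300L), c(5400L, 5350L))
  peaks$start <- c(5300L, 5290L)
  peaks$end <- c(5400L, 5310L)
  # both start 300 bp downstream? compute: distances are s - t = 300 and 290
  got <- nearest_peaks_to_tss(genes, peaks, 10000L)
  expect_identical(got$peak_start, 5290L)

  tie <- genomic_intervals("c", c(5300L, 5300L), c(5400L, 5500L))
  got <- nearest_peaks_to_tss(genes, tie, 10000L)
  expect_identical(got$peak_end, 5400L) # smaller start then shorter listed first
  expect_match(got$tie_peaks, ",")
})

test_that("gene-with-peak percentages use exact arithmetic", {
  expect_error(count_genes_with_peaks(logical()), "empty")
  expect_identical(count_genes_with_peaks(rep(FALSE, 10))$percentage, 0)
  withr::local_seed(77)
  for (i in 1:50) {
    flags <- stats::runif(sample(1:500, 1)) < 0.3
    got <- count_genes_with_peaks(flags)
    expect_identical(got$n_with, sum(flags))
    expect_identical(got$percentage, floor(100 * sum(flags) / length(flags) + 0.5))
  }
})
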