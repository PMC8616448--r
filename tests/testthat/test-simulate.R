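# scaled-down world for unit tests; the acceptance suite exercises the
# full stated defaults
small_config <- function(seed = 1L, ...) {
  base <- list(
    genome = list(n_chroms = 2L, chrom_length_bp = 20000L),
    msats = list(count = 10L),
    peaks = list(decoy_count = 15L),
    genes = list(count = 50L, length_range = c(1000L, 4000L)),
    de = list(n_genes = 2000L, n_reg_A = 150L, n_reg_B = 40L, n_overlap = 15L)
  )
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (is.null(base[[nm]])) {
      over[[nm]]
    } else {
      utils::modifyList(base[[nm]], over[[nm]])
    }
  }
  do.call(sim_config, c(list(seed = seed), base))
}

test_that("one seed fixes every generated artifact byte-for-byte", {
  cfg <- small_config(seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_all(cfg, d1)
  s2 <- simulate_all(cfg, d2)
  expect_identical(s1$genome$sequences, s2$genome$sequences)
  for (f in names(s1$files)) {
    if (f == "provenance") next
    expect_identical(
      readLines(s1$files[[f]]), readLines(s2$files[[f]]),
      info = f
    )
  }
})

test_that("component substreams are independent of other config blocks", {
  a <- simulate_genome(small_config(seed = 3L))
  b <- simulate_genome(small_config(seed = 3L, alleles = list(n_samples = 30L)))
  expect_identical(a$sequences, b$sequences)
})

test_that("the scanner recovers the planted locus truth exactly, via FASTA round-trip", {
  cfg <- small_config(seed = 11L)
  d <- withr::local_tempdir()
  sim <- simulate_all(cfg, d)
  seqs <- read_fasta(sim$files[["genome_fasta"]])
  found <- scan_microsatellites(seqs, cfg$msats$scan)
  expect_equal(found, sim$genome$loci, ignore_attr = TRUE)
  # and the truth BED round-trips the same coordinates
  bed <- read_bed(sim$files[["truth_loci_bed"]])
  expect_identical(bed$start, sim$genome$loci$start)
  expect_identical(bed$total_units, sim$genome$loci$total_units)
})

test_that("zero interruption probability makes every locus fully contiguous", {
  cfg <- small_config(seed = 2L, msats = list(count = 10L, interruption_prob = 0))
  g <- simulate_genome(cfg)
  expect_identical(g$loci$longest_run, g$loci$total_units)
  expect_true(all(g$loci$interruption_count == 0L))
})

test_that("peak placement hits the exact planted fractions; decoys never coincide", {
  cfg <- small_config(seed = 7L)
  g <- simulate_genome(cfg)
  pg <- simulate_peaks_genes(cfg, g)
  ann <- annotate_peaks_with_msats(pg$peaks, g$loci)
  planted <- !is.na(pg$truth$peak_msat)
  expect_identical(ann$msat_coincident, unname(planted[ann$name]))
  expect_identical(sum(ann$msat_coincident), as.integer(round(0.6 * nrow(g$loci))))

  flags <- genes_with_internal_peaks(pg$genes, ann[ann$msat_coincident, ])
  expect_identical(
    flags$has_internal_peak,
    unname(pg$truth$gene_contains[flags$gene_id])
  )
  expect_identical(
    count_genes_with_peaks(flags$has_internal_peak)$n_with,
    as.integer(round(0.12 * cfg$genes$count))
  )

  none <- sim_config(
    seed = 7L, genome = list(n_chroms = 2L, chrom_length_bp = 20000L),
    msats = list(count = 10L),
    peaks = list(msat_fraction = 0, decoy_count = 15L),
    genes = list(count = 30L, containing_fraction = 0, length_range = c(1000L, 4000L))
  )
  g0 <- simulate_genome(none)
  pg0 <- simulate_peaks_genes(none, g0)
  ann0 <- annotate_peaks_with_msats(pg0$peaks, g0$loci)
  expect_false(any(ann0$msat_coincident))
})

test_that("paired DE tables reproduce the planted overlap structure exactly", {
  cfg <- small_config(seed = 21L)
  de <- simulate_de_pair(cfg)
  cA <- classify_regulation(de$table_A)
  cB <- classify_regulation(de$table_B)
  expect_identical(sum(cA$direction != "unchanged"), de$truth$n_reg_A)
  expect_identical(sum(cB$direction != "unchanged"), de$truth$n_reg_B)
  ov <- overlap_summary(cB, cA, de$table_A$gene_id)
  expect_identical(ov$n_overlap, 15L)
  expect_identical(ov$concordant_up, de$truth$concordant_up)
  expect_identical(ov$concordant_down, de$truth$concordant_down)
  expect_identical(ov$discordant, de$truth$discordant)

  sure <- small_config(seed = 22L, de = list(
    n_genes = 2000L, n_reg_A = 150L,
    n_reg_B = 40L, n_overlap = 15L, concordance_prob = 1
  ))
  de2 <- simulate_de_pair(sure)
  expect_identical(de2$truth$discordant, 0L)
})

test_that("allele generator is invertible and hits r = 1 exactly at zero noise", {
  cfg <- small_config(seed = 31L, alleles = list(target_r = 1))
  al <- simulate_alleles(cfg)
  calls <- allele_calls(al$alleles, flank_bp = cfg$alleles$flank_bp)
  expect_identical(calls$units1, al$truth$repeats1)
  expect_identical(calls$units2, as.integer(al$truth$repeats2))
  out <- correlate_length_expression(calls, al$expression)
  expect_equal(out$r, 1.0)
})

test_that("unachievable placements fail loudly", {
  tiny <- sim_config(
    seed = 1L,
    genome = list(n_chroms = 1L, chrom_length_bp = 600L),
    msats = list(count = 20L, unit_range = c(20L, 30L))
  )
  expect_error(simulate_genome(tiny), "too small")
  cfg <- small_config(seed = 1L)
  expect_error(
    simulate_genome(small_config(seed = 1L, msats = list(count = 5L, unit_range = c(2L, 6L)))),
    "min_total_units"
  )
})
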