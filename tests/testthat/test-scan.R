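test_that("scan config enforces its invariants", {
  expect_error(scan_config(unit = "GGA"), "4-mer")
  expect_error(scan_config(allowed_interruptions = "GGAA"), "unit itself")
  expect_error(scan_config(min_seed_run = 0), "min_seed_run")
  expect_error(scan_config(min_total_units = 2, min_seed_run = 4), "min_total_units")
})

test_that("sequences without the unit yield no loci", {
  expect_identical(nrow(scan_microsatellites(strrep("ACGT", 10), scan_config())), 0L)
  expect_identical(nrow(scan_microsatellites("AC", scan_config())), 0L)
})

test_that("an interrupted 28-unit tract is reported as one locus (28 units, run of 16)", {
  # reconstruction of a reference-genome-style tract: 28 GGAA units total,
  # 16 contiguous, with single GGAG units intercalated
  tract <- paste0(
    strrep("GGAA", 16), "GGAG", strrep("GGAA", 4), "GGAG", strrep("GGAA", 8)
  )
  seq <- paste0("TCTCTCCTAA", tract, "CACACGTAGA")
  got <- scan_microsatellites(c(chr7 = seq), scan_config())
  expect_identical(nrow(got), 1L)
  expect_identical(got$total_units, 28L)
  expect_identical(got$longest_run, 16L)
  expect_identical(got$interruption_count, 2L)
  expect_identical(got$start, 10L)
  expect_identical(got$end, 10L + 4L * 30L)
  expect_identical(got$sequence, tract)
  # agreement with the exhaustive-tiling oracle
  expect_equal(got, oracle_scan(seq, scan_config(), chrom = "chr7"), ignore_attr = TRUE)
})

test_that("scanner equals the exhaustive-tiling oracle on random planted sequences", {
  withr::local_seed(2024)
  cfg <- scan_config(min_seed_run = 2, min_total_units = 3)
  for (i in 1:200) {
    seq <- plant_random_sequence(300L, sample(0:3, 1), cfg)
    got <- scan_microsatellites(c(s = seq), cfg)
    exp <- oracle_scan(seq, cfg, chrom = "s")
    expect_equal(got, exp, ignore_attr = TRUE)
  }
})

test_that("scanner equals the oracle on a 2 kb sequence at default thresholds", {
  withr::local_seed(99)
  cfg <- scan_config()
  seq <- plant_random_sequence(2000L, 4L, cfg, max_units = 20L)
  expect_equal(
    scan_microsatellites(c(s = seq), cfg),
    oracle_scan(seq, cfg, chrom = "s"),
    ignore_attr = TRUE
  )
})

test_that("reported loci are maximal and begin/end with a perfect unit", {
  withr::local_seed(5)
  cfg <- scan_config(min_seed_run = 2, min_total_units = 3)
  blockset <- c(cfg$unit, cfg$allowed_interruptions)
  for (i in 1:40) {
    seq <- plant_random_sequence(400L, 2L, cfg)
    loci <- scan_microsatellites(c(s = seq), cfg)
    for (k in seq_len(nrow(loci))) {
      s <- loci$start[k]
      e <- loci$end[k]
      fwd <- if (loci$strand[k] == "+") seq else revcomp(seq)
      s2 <- if (loci$strand[k] == "+") s else nchar(seq) - e
      e2 <- if (loci$strand[k] == "+") e else nchar(seq) - s
      expect_identical(substr(fwd, s2 + 1L, s2 + 4L), cfg$unit)
      expect_identical(substr(fwd, e2 - 3L, e2), cfg$unit)
      # maximality after trimming: walking outward in frame, no further unit
      # is reachable through interruption blocks on either side
      j <- s2 - 4L
      while (j >= 0L && substr(fwd, j + 1L, j + 4L) %in% cfg$allowed_interruptions) j <- j - 4L
      if (j >= 0L) expect_false(substr(fwd, j + 1L, j + 4L) == cfg$unit)
      j <- e2
      while (j + 4L <= nchar(seq) && substr(fwd, j + 1L, j + 4L) %in% cfg$allowed_interruptions) j <- j + 4L
      if (j + 4L <= nchar(seq)) expect_false(substr(fwd, j + 1L, j + 4L) == cfg$unit)
    }
  }
})

test_that("scanning the reverse complement mirrors loci with strands flipped", {
  withr::local_seed(31)
  cfg <- scan_config(min_seed_run = 2, min_total_units = 3)
  for (i in 1:30) {
    seq <- plant_random_sequence(300L, 2L, cfg)
    n <- nchar(seq)
    a <- scan_microsatellites(c(s = seq), cfg)
    b <- scan_microsatellites(c(s = revcomp(seq)), cfg)
    mirrored <- data.frame(
      chrom = b$chrom, start = n - b$end, end = n - b$start,
      strand = chartr("+-", "-+", b$strand),
      b[c("total_units", "longest_run", "interruption_count", "sequence")],
      stringsAsFactors = FALSE
    )
    mirrored <- mirrored[order(mirrored$chrom, mirrored$start, mirrored$strand), ]
    expect_equal(a, mirrored, ignore_attr = TRUE)
  }
})

test_that("N bases terminate a locus", {
  cfg <- scan_config(min_seed_run = 2, min_total_units = 4)
  seq <- paste0(strrep("GGAA", 4), "NGAA", strrep("GGAA", 4))
  got <- scan_microsatellites(c(s = seq), cfg)
  expect_identical(got$total_units, c(4L, 4L))
  long <- scan_microsatellites(c(s = strrep("GGAN", 20)), cfg)
  expect_identical(nrow(long), 0L)
})

test_that("locus summary displays 1-based coordinates and keeps cardinality", {
  empty <- locus_summary(scan_microsatellites("ACGT", scan_config()))
  expect_identical(nrow(empty), 0L)

  loci <- scan_microsatellites(c(s = strrep("GGAA", 16)), scan_config())
  smry <- locus_summary(loci)
  expect_identical(smry$start, 1L)
  expect_identical(smry$end, 64L)

  withr::local_seed(8)
  cfg <- scan_config(min_seed_run = 2, min_total_units = 3)
  seq <- plant_random_sequence(500L, 3L, cfg)
  loci <- scan_microsatellites(c(s = seq), cfg)
  expect_identical(nrow(locus_summary(loci)), nrow(loci))
})
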