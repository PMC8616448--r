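#' Simulation configuration with a stated-world default
#'
#' One seed fixes every output. Component blocks (genome, msats, peaks, genes,
#' de, alleles) are merged over the defaults below, which emulate the
#' statistical structure of a fusion-oncoprotein target-gene study: a small
#' multi-chromosome genome at human GC content carrying planted GGAA
#' microsatellites with GGAG interruptions; ChIP-seq peaks covering a
#' controlled fraction of them plus decoys; gene models with 12% of genes
#' containing a microsatellite-coincident peak; paired knockdown DE tables at
#' transcriptome scale with marginals 1456 and 174 regulated genes, 67
#' overlapping of which 39 are direction-concordant; and 12 cell lines whose
#' microsatellite allele length correlates with expression at r = 0.9.
#' Each component draws from its own substream (a fixed offset from the
#' master seed), so editing one block does not perturb the others.
#'
#' @param seed master integer seed.
#' @param genome,msats,peaks,genes,de,alleles named lists overriding the
#'   defaults (see the method vignette for each field's meaning and units).
#' @return a \code{ggaa_sim_config} list.
#' @export
sim_config <- function(seed = 1L, genome = list(), msats = list(),
                       peaks = list(), genes = list(), de = list(),
                       alleles = list()) {
  defaults <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 4L, chrom_length_bp = 100000L, gc_fraction = 0.41),
    msats = list(
      count = 40L, unit_range = c(8L, 30L), interruption_prob = 0.15,
      minus_fraction = 0.5, scan = scan_config()
    ),
    peaks = list(
      msat_fraction = 0.6, width_range = c(200L, 800L), decoy_count = 60L
    ),
    genes = list(
      count = 150L, length_range = c(2000L, 15000L), minus_fraction = 0.5,
      containing_fraction = 0.12
    ),
    de = list(
      n_genes = 25000L, n_reg_A = 1456L, n_reg_B = 174L, n_overlap = 67L,
      concordance_prob = 39 / 67, frac_down = 0.4, na_padj_fraction = 0.1,
      lfc_range = c(1, 5), independent = FALSE,
      p_reg_A = NULL, p_reg_B = NULL
    ),
    alleles = list(
      n_samples = 12L, flank_bp = 80L, unit_range = c(10L, 30L),
      target_r = 0.9, het_prob = 0.5
    )
  )
  cfg <- defaults
  for (blk in c("genome", "msats", "peaks", "genes", "de", "alleles")) {
    cfg[[blk]] <- utils::modifyList(cfg[[blk]], get(blk))
  }
  stopifnot(
    cfg$genome$gc_fraction >= 0, cfg$genome$gc_fraction <= 1,
    cfg$msats$interruption_prob >= 0, cfg$msats$interruption_prob <= 1,
    cfg$peaks$msat_fraction >= 0, cfg$peaks$msat_fraction <= 1,
    cfg$genes$containing_fraction >= 0, cfg$genes$containing_fraction <= 1,
    cfg$alleles$target_r >= -1, cfg$alleles$target_r <= 1
  )
  structure(cfg, class = "ggaa_sim_config")
}

# substream offsets: one independent stream per component
.stream_offsets <- c(genome = 101L, peaks = 211L, genes = 307L, de = 401L, alleles = 503L)

seed_stream <- function(config, stream) {
  set.seed((config$seed + .stream_offsets[[stream]]) %% .Machine$integer.max)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ), collapse = "")
}

# one planted tract: unit blocks with single-block interruptions at junctions
build_locus_blocks <- function(n_units, interruption_prob, unit, interruptions) {
  blocks <- unit
  for (j in seq_len(max(0L, n_units - 1L))) {
    if (stats::runif(1) < interruption_prob) {
      blocks <- c(blocks, sample(interruptions, 1L))
    }
    blocks <- c(blocks, unit)
  }
  blocks
}

#' Generate a genome with planted GGAA microsatellites
#'
#' Background sequence is random at the configured GC fraction; planted loci
#' are placed non-overlapping with at least a two-unit gap. The assembled
#' genome is rejection-checked with the configured scanner: if the scan does
#' not reproduce the planted truth exactly (a spurious background locus, or a
#' planted locus extended by a chance flanking match), the genome is redrawn.
#' Planted truth is therefore the complete truth.
#'
#' @param config a [sim_config()] object.
#' @return list with \code{sequences} (named character vector, one per
#'   chromosome) and \code{loci} (truth table in [scan_microsatellites()]
#'   format).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "ggaa_sim_config"))
  g <- config$genome
  m <- config$msats
  sc <- m$scan
  gap <- 2L * nchar(sc$unit)
  if (any(m$unit_range < sc$min_total_units)) {
    stop("unit_range must stay at or above the scanner's min_total_units so planted truth is recoverable")
  }
  seed_stream(config, "genome")
  for (attempt in seq_len(20L)) {
    chrom_names <- paste0("chr", seq_len(g$n_chroms))
    chrom_of <- sort(sample(seq_len(g$n_chroms), m$count, replace = TRUE))
    seqs <- character(g$n_chroms)
    names(seqs) <- chrom_names
    truth <- list()
    ok <- TRUE
    for (ci in seq_len(g$n_chroms)) {
      n_here <- sum(chrom_of == ci)
      bg <- strsplit(random_dna(g$chrom_length_bp, g$gc_fraction), "", fixed = TRUE)[[1L]]
      occupied <- matrix(integer(), ncol = 2L)
      for (k in seq_len(n_here)) {
        n_units <- sample(seq.int(m$unit_range[1L], m$unit_range[2L]), 1L)
        blocks <- build_locus_blocks(
          n_units, m$interruption_prob, sc$unit,
          sc$allowed_interruptions
        )
        locus_seq <- paste(blocks, collapse = "")
        len <- nchar(locus_seq)
        strand <- if (stats::runif(1) < m$minus_fraction) "-" else "+"
        placed <- FALSE
        for (try in seq_len(200L)) {
          s0 <- sample.int(g$chrom_length_bp - len - 2L * gap, 1L) + gap # 0-based
          if (nrow(occupied) > 0L &&
            any(pmin(occupied[, 2L] + gap, s0 + len + gap) > pmax(occupied[, 1L] - gap, s0))) {
            next
          }
          occupied <- rbind(occupied, c(s0, s0 + len))
          ins <- if (strand == "+") locus_seq else revcomp(locus_seq)
          bg[(s0 + 1L):(s0 + len)] <- strsplit(ins, "", fixed = TRUE)[[1L]]
          runs <- rle(blocks == sc$unit)
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = s0, end = s0 + len,
            strand = strand, total_units = sum(blocks == sc$unit),
            longest_run = max(runs$lengths[runs$values]),
            interruption_count = sum(blocks != sc$unit),
            sequence = locus_seq, stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
        if (!placed) stop("genome too small for the requested microsatellite count")
      }
      seqs[ci] <- paste(bg, collapse = "")
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$chrom, truth$start, truth$strand), , drop = FALSE]
    rownames(truth) <- NULL
    found <- scan_microsatellites(seqs, sc)
    if (identical(
      found[c("chrom", "start", "end", "strand", "total_units", "longest_run", "interruption_count", "sequence")],
      truth[c("chrom", "start", "end", "strand", "total_units", "longest_run", "interruption_count", "sequence")]
    )) {
      return(list(sequences = seqs, loci = truth))
    }
    # chance collision with background: redraw everything
  }
  stop("could not assemble a collision-free genome in 20 attempts")
}

place_avoiding <- function(chrom_len, width, forbidden, tries = 500L) {
  # forbidden: 2-col matrix of half-open intervals to avoid entirely
  for (i in seq_len(tries)) {
    s0 <- sample.int(chrom_len - width, 1L) - 1L
    if (nrow(forbidden) == 0L ||
      all(pmin(forbidden[, 2L], s0 + width) <= pmax(forbidden[, 1L], s0))) {
      return(s0)
    }
  }
  NA_integer_
}

#' Generate ChIP-seq peaks and gene models over a simulated genome
#'
#' Exactly \code{round(msat_fraction * n_loci)} microsatellites receive a
#' covering peak (the peak fully contains the locus); decoy peaks avoid all
#' loci. Exactly \code{round(containing_fraction * n_genes)} genes are placed
#' so that one microsatellite-coincident peak lies fully inside the gene body
#' (so every containment rule agrees); the remaining genes avoid all
#' microsatellite-coincident peaks.
#'
#' @param config a [sim_config()] object.
#' @param genome output of [simulate_genome()].
#' @return list with \code{peaks} (interval data.frame with \code{name},
#'   \code{score}, \code{source}), \code{genes} (gene-model data.frame) and
#'   \code{truth} (\code{peak_msat}: per-peak locus row index or NA;
#'   \code{gene_contains}: named logical per gene).
#' @export
simulate_peaks_genes <- function(config, genome) {
  stopifnot(inherits(config, "ggaa_sim_config"))
  loci <- genome$loci
  chrom_len <- nchar(genome$sequences)
  p <- config$peaks
  gn <- config$genes
  seed_stream(config, "peaks")
  n_cover <- round(p$msat_fraction * nrow(loci))
  covered <- sort(sample(seq_len(nrow(loci)), n_cover))
  peak_rows <- list()
  for (li in covered) {
    locus_len <- loci$end[li] - loci$start[li]
    w <- max(
      sample(seq.int(p$width_range[1L], p$width_range[2L]), 1L),
      locus_len + 8L
    )
    slack <- w - locus_len
    s0 <- loci$start[li] - sample.int(slack + 1L, 1L) + 1L
    s0 <- max(0L, min(s0, chrom_len[[loci$chrom[li]]] - w))
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      chrom = loci$chrom[li], start = s0, end = s0 + w, strand = ".",
      msat_row = li, stringsAsFactors = FALSE
    )
  }
  for (d in seq_len(p$decoy_count)) {
    ci <- sample(names(chrom_len), 1L)
    w <- sample(seq.int(p$width_range[1L], p$width_range[2L]), 1L)
    forb <- as.matrix(loci[loci$chrom == ci, c("start", "end")])
    s0 <- place_avoiding(chrom_len[[ci]], w, forb)
    if (is.na(s0)) stop("could not place a decoy peak avoiding all microsatellites")
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      chrom = ci, start = s0, end = s0 + w, strand = ".",
      msat_row = NA_integer_, stringsAsFactors = FALSE
    )
  }
  peaks <- do.call(rbind, peak_rows)
  ord <- order(peaks$chrom, peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  peaks$name <- sprintf("peak_%04d", seq_len(nrow(peaks)))
  peaks$score <- 0
  peaks$source <- "sim"
  rownames(peaks) <- NULL
  peak_msat <- peaks$msat_row
  names(peak_msat) <- peaks$name
  peaks$msat_row <- NULL

  seed_stream(config, "genes")
  n_genes <- gn$count
  n_contain <- round(gn$containing_fraction * n_genes)
  msat_peaks <- peaks[!is.na(peak_msat), , drop = FALSE]
  if (n_contain > 0L && nrow(msat_peaks) == 0L) {
    stop("containing_fraction > 0 but no microsatellite-coincident peaks exist")
  }
  gene_rows <- list()
  for (gi in seq_len(n_genes)) {
    strand <- if (stats::runif(1) < gn$minus_fraction) "-" else "+"
    if (gi <= n_contain) {
      pk <- msat_peaks[sample.int(nrow(msat_peaks), 1L), ]
      pw <- pk$end - pk$start
      len <- max(
        sample(seq.int(gn$length_range[1L], gn$length_range[2L]), 1L),
        pw + 200L
      )
      s0 <- pk$start - sample.int(len - pw - 1L, 1L)
      s0 <- max(0L, min(s0, chrom_len[[pk$chrom]] - len))
      gene_rows[[gi]] <- data.frame(
        gene_id = "", chrom = pk$chrom, start = s0, end = s0 + len,
        strand = strand, stringsAsFactors = FALSE
      )
    } else {
      placed <- FALSE
      for (try in seq_len(200L)) {
        ci <- sample(names(chrom_len), 1L)
        len <- sample(seq.int(gn$length_range[1L], gn$length_range[2L]), 1L)
        forb <- as.matrix(msat_peaks[msat_peaks$chrom == ci, c("start", "end")])
        s0 <- place_avoiding(chrom_len[[ci]], len, forb, tries = 50L)
        if (!is.na(s0)) {
          gene_rows[[gi]] <- data.frame(
            gene_id = "", chrom = ci, start = s0, end = s0 + len,
            strand = strand, stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place a gene avoiding all microsatellite-coincident peaks")
    }
  }
  genes <- do.call(rbind, gene_rows)
  contains <- rep(c(TRUE, FALSE), c(n_contain, n_genes - n_contain))
  ord <- order(genes$chrom, genes$start)
  genes <- genes[ord, , drop = FALSE]
  contains <- contains[ord]
  genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  names(contains) <- genes$gene_id
  genes <- genes[c("gene_id", "chrom", "start", "end", "strand")]
  list(
    peaks = peaks, genes = genes,
    truth = list(peak_msat = peak_msat, gene_contains = contains)
  )
}

# fill plausible DE statistics around planted direction sets
build_de_table <- function(gene_ids, down_ids, up_ids, lfc_range = c(1, 5),
                           padj_threshold = 0.05, na_padj_fraction = 0.1) {
  n <- length(gene_ids)
  lfc <- stats::runif(n, -0.99, 0.99)
  # sub-threshold genes stay unchanged whatever their padj, since |lfc| < 1
  padj <- stats::runif(n, 0, 1)
  na_idx <- which(stats::runif(n) < na_padj_fraction)
  padj[na_idx] <- NA_real_
  lfc[na_idx] <- stats::runif(length(na_idx), -3, 3) # NA padj silences even large fold changes
  di <- match(down_ids, gene_ids)
  ui <- match(up_ids, gene_ids)
  lfc[di] <- -stats::runif(length(di), lfc_range[1L], lfc_range[2L])
  lfc[ui] <- stats::runif(length(ui), lfc_range[1L], lfc_range[2L])
  padj[c(di, ui)] <- stats::runif(length(di) + length(ui), 0, padj_threshold)
  data.frame(gene_id = gene_ids, log2fc = lfc, padj = padj, stringsAsFactors = FALSE)
}

#' Generate a pair of knockdown DE tables with planted overlap structure
#'
#' Two sampling modes. The default plants exact counts: \code{n_reg_A} and
#' \code{n_reg_B} regulated genes with exactly \code{n_overlap} shared, each
#' shared gene direction-concordant with probability \code{concordance_prob};
#' downstream overlap statistics then recover the planted counts exactly.
#' With \code{de$independent = TRUE}, each gene is regulated independently in
#' each table with probabilities \code{p_reg_A}, \code{p_reg_B} (defaults
#' \code{n_reg_A / n_genes} etc.) — the null world used to check the
#' calibration of the Fisher test.
#'
#' @param config a [sim_config()] object.
#' @return list with \code{table_A}, \code{table_B} (data.frames with
#'   \code{gene_id}, \code{log2fc}, \code{padj}) and \code{truth} (direction
#'   maps and realized overlap/concordance counts).
#' @export
simulate_de_pair <- function(config) {
  stopifnot(inherits(config, "ggaa_sim_config"))
  d <- config$de
  seed_stream(config, "de")
  ids <- sprintf("gene_%05d", seq_len(d$n_genes))
  if (isTRUE(d$independent)) {
    pA <- if (is.null(d$p_reg_A)) d$n_reg_A / d$n_genes else d$p_reg_A
    pB <- if (is.null(d$p_reg_B)) d$n_reg_B / d$n_genes else d$p_reg_B
    reg_A <- ids[stats::runif(d$n_genes) < pA]
    reg_B <- ids[stats::runif(d$n_genes) < pB]
    dir_A <- ifelse(stats::runif(length(reg_A)) < d$frac_down, "down", "up")
    dir_B <- ifelse(stats::runif(length(reg_B)) < d$frac_down, "down", "up")
  } else {
    if (d$n_overlap > min(d$n_reg_A, d$n_reg_B)) {
      stop("n_overlap exceeds a marginal regulated count")
    }
    shared <- sample(ids, d$n_overlap)
    rest <- setdiff(ids, shared)
    a_only <- sample(rest, d$n_reg_A - d$n_overlap)
    b_only <- sample(setdiff(rest, a_only), d$n_reg_B - d$n_overlap)
    reg_A <- c(shared, a_only)
    reg_B <- c(shared, b_only)
    dir_A <- ifelse(stats::runif(length(reg_A)) < d$frac_down, "down", "up")
    names(dir_A) <- reg_A
    flip <- c(down = "up", up = "down")
    dir_shared <- ifelse(
      stats::runif(d$n_overlap) < d$concordance_prob,
      dir_A[shared], flip[dir_A[shared]]
    )
    dir_B <- c(dir_shared, ifelse(stats::runif(length(b_only)) < d$frac_down, "down", "up"))
  }
  names(dir_A) <- reg_A
  names(dir_B) <- reg_B
  table_A <- build_de_table(
    ids, reg_A[dir_A == "down"], reg_A[dir_A == "up"],
    d$lfc_range, 0.05, d$na_padj_fraction
  )
  table_B <- build_de_table(
    ids, reg_B[dir_B == "down"], reg_B[dir_B == "up"],
    d$lfc_range, 0.05, d$na_padj_fraction
  )
  shared_ids <- intersect(reg_A, reg_B)
  concord <- dir_A[shared_ids] == dir_B[shared_ids]
  list(
    table_A = table_A, table_B = table_B,
    truth = list(
      dir_A = dir_A, dir_B = dir_B,
      n_reg_A = length(reg_A), n_reg_B = length(reg_B),
      n_overlap = length(shared_ids),
      concordant_up = sum(concord & dir_A[shared_ids] == "up"),
      concordant_down = sum(concord & dir_A[shared_ids] == "down"),
      discordant = sum(!concord)
    )
  )
}

#' Generate allele-length and expression data with a planted correlation
#'
#' Repeat counts are drawn uniformly from \code{unit_range}; fragment lengths
#' are \code{flank_bp + 4 * repeats}, with a second allele present with
#' probability \code{het_prob}. Expression is the linear-Gaussian construction
#' \code{r * z_length + sqrt(1 - r^2) * noise} (rescaled to positive relative
#' units), so the population correlation with mean allele length equals
#' \code{target_r}; at \code{|r| = 1} the noise term vanishes and the sample
#' correlation is exact.
#'
#' @param config a [sim_config()] object.
#' @return list with \code{alleles} (sample_id, length1, length2),
#'   \code{expression} (sample_id, value) and \code{truth} (per-sample repeat
#'   counts and the planted r).
#' @export
simulate_alleles <- function(config) {
  stopifnot(inherits(config, "ggaa_sim_config"))
  a <- config$alleles
  seed_stream(config, "alleles")
  if (a$n_samples < 4L) stop("need at least 4 samples")
  ids <- sprintf("cell_%02d", seq_len(a$n_samples))
  rng <- seq.int(a$unit_range[1L], a$unit_range[2L])
  rep1 <- sample(rng, a$n_samples, replace = TRUE)
  rep2 <- ifelse(stats::runif(a$n_samples) < a$het_prob,
    sample(rng, a$n_samples, replace = TRUE), NA_integer_
  )
  len1 <- a$flank_bp + 4L * rep1
  len2 <- ifelse(is.na(rep2), NA_integer_, a$flank_bp + 4L * rep2)
  mean_len <- ifelse(is.na(len2), len1, (len1 + len2) / 2)
  z <- (mean_len - mean(mean_len)) / stats::sd(mean_len)
  r <- a$target_r
  lat <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(a$n_samples)
  list(
    alleles = data.frame(
      sample_id = ids, length1 = len1, length2 = len2,
      stringsAsFactors = FALSE
    ),
    expression = data.frame(
      sample_id = ids, value = 10 + 2 * lat,
      stringsAsFactors = FALSE
    ),
    truth = list(repeats1 = rep1, repeats2 = rep2, target_r = r)
  )
}

#' Run every generator and (optionally) write all pipeline input files
#'
#' @param config a [sim_config()] object.
#' @param outdir if non-NULL, writes genome FASTA, truth-locus BED, peak BED,
#'   gene-model TSV, both DE tables (DESeq2-style headers), allele and
#'   expression TSVs, and a provenance JSON recording the seed and resolved
#'   configuration.
#' @return list with components \code{genome}, \code{pg} (peaks and genes),
#'   \code{de}, \code{alleles}, and \code{files} (named paths, when written).
#' @export
simulate_all <- function(config, outdir = NULL) {
  genome <- simulate_genome(config)
  pg <- simulate_peaks_genes(config, genome)
  de <- simulate_de_pair(config)
  al <- simulate_alleles(config)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genome_fasta = file.path(outdir, "genome.fa"),
      truth_loci_bed = file.path(outdir, "truth_loci.bed"),
      peaks_bed = file.path(outdir, "peaks.bed"),
      genes_tsv = file.path(outdir, "genes.tsv"),
      de_table_a = file.path(outdir, "de_table_A.tsv"),
      de_table_b = file.path(outdir, "de_table_B.tsv"),
      alleles_tsv = file.path(outdir, "alleles.tsv"),
      expression_tsv = file.path(outdir, "expression.tsv"),
      provenance = file.path(outdir, "provenance.json")
    )
    write_fasta(genome$sequences, files[["genome_fasta"]])
    loci <- genome$loci
    loci$name <- sprintf("msat_%04d", seq_len(nrow(loci)))
    loci$score <- loci$total_units
    write_bed(
      loci[c(
        "chrom", "start", "end", "name", "score", "strand",
        "total_units", "longest_run", "interruption_count"
      )],
      files[["truth_loci_bed"]]
    )
    write_bed(pg$peaks, files[["peaks_bed"]])
    write_gene_models(pg$genes, files[["genes_tsv"]])
    for (tb in c("a", "b")) {
      t0 <- if (tb == "a") de$table_A else de$table_B
      write_tsv(
        data.frame(
          gene_id = t0$gene_id, log2FoldChange = t0$log2fc,
          padj = t0$padj
        ),
        files[[paste0("de_table_", tb)]]
      )
    }
    write_tsv(al$alleles, files[["alleles_tsv"]])
    write_tsv(al$expression, files[["expression_tsv"]])
    cfg <- unclass(config)
    cfg$msats$scan <- unclass(cfg$msats$scan)
    jsonlite::write_json(
      list(seed = config$seed, config = cfg),
      files[["provenance"]],
      auto_unbox = TRUE, pretty = TRUE, null = "null"
    )
  }
  list(genome = genome, pg = pg, de = de, alleles = al, files = files)
}
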