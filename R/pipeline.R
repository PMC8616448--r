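#' Run the full microsatellite-to-regulation analysis graph
#'
#' Executes the stages in dependency order: microsatellite scan, peak
#' annotation, inside-gene and near-TSS assignment, differential-expression
#' classification (optionally against a transcription-factor catalog),
#' overlap/concordance statistics between the two DE tables, and the
#' allele-length/expression correlation. Every stage that has its inputs
#' runs; stages whose inputs are absent are skipped. All outputs are
#' plain TSVs under \code{outdir}, plus a \code{manifest.json} with the
#' resolved parameters, input checksums, and per-stage row counts.
#'
#' @param outdir output directory (created if needed).
#' @param genome_fasta,peaks_bed,genes_tsv,de_table_a,de_table_b,catalog,alleles_tsv,expression_tsv
#'   input file paths (all optional; see above). \code{catalog} is a one-id-
#'   per-line gene list.
#' @param sim optional [sim_config()]; when given, all inputs are simulated
#'   into \code{outdir/inputs} first and any unset paths point there.
#' @param scan a [scan_config()].
#' @param containment_rule rule for [genes_with_internal_peaks()].
#' @param tss_window window for [nearest_peaks_to_tss()] in bp (default
#'   10000, i.e. 10 kb each side of the TSS).
#' @param lfc_threshold,padj_threshold thresholds for
#'   [classify_regulation()].
#' @param correlation_method,exclude_samples passed to
#'   [correlate_length_expression()].
#' @param flank_bp amplicon flank length for [allele_calls()]; defaults to
#'   the simulation's value when \code{sim} is given, else 0.
#' @return invisibly, a list with each stage's in-memory result and
#'   \code{manifest}.
#' @export
run_pipeline <- function(outdir,
                         genome_fasta = NULL, peaks_bed = NULL,
                         genes_tsv = NULL, de_table_a = NULL,
                         de_table_b = NULL, catalog = NULL,
                         alleles_tsv = NULL, expression_tsv = NULL,
                         sim = NULL,
                         scan = scan_config(),
                         containment_rule = "any-overlap",
                         tss_window = 10000L,
                         lfc_threshold = 1, padj_threshold = 0.05,
                         correlation_method = "pearson",
                         exclude_samples = character(),
                         flank_bp = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim)) {
    simd <- simulate_all(sim, file.path(outdir, "inputs"))
    f <- simd$files
    if (is.null(genome_fasta)) genome_fasta <- f[["genome_fasta"]]
    if (is.null(peaks_bed)) peaks_bed <- f[["peaks_bed"]]
    if (is.null(genes_tsv)) genes_tsv <- f[["genes_tsv"]]
    if (is.null(de_table_a)) de_table_a <- f[["de_table_a"]]
    if (is.null(de_table_b)) de_table_b <- f[["de_table_b"]]
    if (is.null(alleles_tsv)) alleles_tsv <- f[["alleles_tsv"]]
    if (is.null(expression_tsv)) expression_tsv <- f[["expression_tsv"]]
  }
  inputs <- c(
    genome_fasta = genome_fasta, peaks_bed = peaks_bed,
    genes_tsv = genes_tsv, de_table_a = de_table_a,
    de_table_b = de_table_b, catalog = catalog,
    alleles_tsv = alleles_tsv, expression_tsv = expression_tsv
  )
  missing_in <- inputs[!vapply(inputs, file.exists, logical(1L))]
  if (length(missing_in) > 0L) {
    stop(
      "missing input file(s): ",
      paste(names(missing_in), unname(missing_in), sep = " = ", collapse = ", ")
    )
  }
  res <- list()
  counts <- list()

  if (!is.null(genome_fasta)) {
    seqs <- read_fasta(genome_fasta)
    res$loci <- scan_microsatellites(seqs, scan)
    write_tsv(locus_summary(res$loci), file.path(outdir, "msat_loci.tsv"))
    counts$msat_loci <- nrow(res$loci)
  }
  if (!is.null(peaks_bed)) {
    peaks <- read_bed(peaks_bed)
    if (!is.null(res$loci)) {
      peaks <- annotate_peaks_with_msats(peaks, res$loci)
    }
    res$peaks <- peaks
    write_tsv(peaks, file.path(outdir, "peaks_annotated.tsv"))
    counts$peaks <- nrow(peaks)
    counts$peaks_msat_coincident <- sum(peaks$msat_coincident %||% FALSE)
  }
  if (!is.null(genes_tsv)) {
    res$genes <- read_gene_models(genes_tsv)
    counts$genes <- nrow(res$genes)
  }
  if (!is.null(res$genes) && !is.null(res$peaks)) {
    use <- res$peaks
    if ("msat_coincident" %in% names(use)) {
      use <- use[use$msat_coincident, , drop = FALSE]
    }
    res$inside <- genes_with_internal_peaks(res$genes, use, rule = containment_rule)
    write_tsv(res$inside, file.path(outdir, "inside_gene.tsv"))
    res$inside_counts <- count_genes_with_peaks(res$inside$has_internal_peak)
    counts$genes_with_internal_peak <- res$inside_counts$n_with
    res$tss <- nearest_peaks_to_tss(res$genes, use, max_distance_bp = tss_window)
    write_tsv(res$tss, file.path(outdir, "tss_assignments.tsv"))
    counts$tss_assignments <- nrow(res$tss)
  }
  for (tb in c("a", "b")) {
    path <- if (tb == "a") de_table_a else de_table_b
    if (is.null(path)) next
    calls <- classify_regulation(read_de_table(path), lfc_threshold, padj_threshold)
    res[[paste0("calls_", tb)]] <- calls
    write_tsv(
      relabel_to_fusion(calls),
      file.path(outdir, paste0("regulation_calls_", toupper(tb), ".tsv"))
    )
    counts[[paste0("regulated_", tb)]] <- sum(calls$direction != "unchanged")
    if (!is.null(catalog)) {
      cs <- select_catalog_subset(calls, read_gene_list(catalog))
      res[[paste0("catalog_", tb)]] <- cs
      counts[[paste0("catalog_regulated_", tb)]] <- cs$n_down + cs$n_up
    }
  }
  if (!is.null(res$calls_a) && !is.null(res$calls_b)) {
    universe <- intersect(res$calls_a$gene_id, res$calls_b$gene_id)
    res$overlap <- overlap_summary(res$calls_b, res$calls_a, universe)
    ov <- res$overlap
    write_tsv(
      data.frame(
        n_query = ov$n_A, n_reference = ov$n_B, n_overlap = ov$n_overlap,
        universe_size = ov$universe_size, overlap_pct = ov$overlap_pct,
        concordant_up = ov$concordant_up, concordant_down = ov$concordant_down,
        discordant = ov$discordant, p_one_sided = ov$p_one_sided
      ),
      file.path(outdir, "overlap_summary.tsv")
    )
    counts$overlap <- ov$n_overlap
  }
  if (!is.null(alleles_tsv) && !is.null(expression_tsv)) {
    al <- utils::read.delim(alleles_tsv, stringsAsFactors = FALSE)
    ex <- utils::read.delim(expression_tsv, stringsAsFactors = FALSE)
    if (is.null(flank_bp)) {
      flank_bp <- if (!is.null(sim)) sim$alleles$flank_bp else 0L
    }
    calls <- allele_calls(al, flank_bp = flank_bp)
    res$correlation <- correlate_length_expression(
      calls, ex,
      method = correlation_method, exclude = exclude_samples
    )
    cr <- res$correlation
    write_tsv(
      data.frame(
        method = cr$method, r = cr$r, n = cr$n,
        excluded = paste(cr$excluded_samples, collapse = ",")
      ),
      file.path(outdir, "correlation.tsv")
    )
    counts$correlation_pairs <- cr$n
  }

  manifest <- list(
    tool = paste0("ggaareg ", as.character(utils::packageVersion("ggaareg"))),
    parameters = list(
      scan = unclass(scan), containment_rule = containment_rule,
      tss_window = tss_window, lfc_threshold = lfc_threshold,
      padj_threshold = padj_threshold,
      correlation_method = correlation_method,
      exclude_samples = exclude_samples,
      seed = if (!is.null(sim)) sim$seed else NULL
    ),
    inputs = {
      sums <- tools::md5sum(unname(inputs))
      names(sums) <- names(inputs)
      as.list(sums)
    },
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
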