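#' One-sided Fisher's exact test (enrichment direction)
#'
#' Computes the exact upper tail of the hypergeometric distribution at the
#' observed count: \code{P[X >= a]} over all 2x2 tables with the observed
#' margins. The probability terms are built by ratio recursion outward from
#' the distribution's mode (consecutive terms differ by an exact small
#' rational), so the normalized tail keeps better than 12 significant digits
#' even for margins in the tens of thousands — a naive log-factorial sum
#' loses about two digits there through the lgamma error in the exponent.
#'
#' @param a,b,c,d cells of the 2x2 table (\code{a} = joint successes, rows =
#'   set membership, columns = second set membership); non-negative integers
#'   with at least one positive margin.
#' @return the one-sided p-value in (0, 1].
#' @examples
#' fisher_exact_one_sided(39, 28, 1000, 8000)
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be non-negative integers")
  }
  n <- a + b + c + d
  if (n == 0) stop("at least one margin must be positive")
  r1 <- a + b
  c1 <- a + c
  kmin <- max(0, c1 - (c + d))
  kmax <- min(r1, c1)
  if (a <= kmin) return(1)
  # unnormalized pmf relative to the modal term (== 1)
  mode <- min(max(floor((r1 + 1) * (c1 + 1) / (n + 2)), kmin), kmax)
  terms <- numeric(kmax - kmin + 1L)
  terms[mode - kmin + 1L] <- 1
  if (mode < kmax) {
    ks <- seq.int(mode, kmax - 1L)
    up <- cumprod(((r1 - ks) * (c1 - ks)) / ((ks + 1) * (n - r1 - c1 + ks + 1)))
    terms[(mode - kmin + 2L):(kmax - kmin + 1L)] <- up
  }
  if (mode > kmin) {
    ks <- seq.int(mode, kmin + 1L)
    down <- cumprod((ks * (n - r1 - c1 + ks)) / ((r1 - ks + 1) * (c1 - ks + 1)))
    terms[(mode - kmin):(1L)] <- down
  }
  min(1, sum(terms[(a - kmin + 1L):(kmax - kmin + 1L)]) / sum(terms))
}

#' Overlap and directional concordance between two regulated-gene sets
#'
#' Given regulation calls from two knockdown experiments (A is the query set
#' by convention, and defines the percentage denominator), counts the genes
#' regulated in both, splits the overlap into direction-concordant (both up
#' or both down) and discordant genes, and tests whether the overlap exceeds
#' chance with a one-sided Fisher exact test over the stated gene universe.
#'
#' @param calls_A,calls_B outputs of [classify_regulation()]; regulated means
#'   \code{direction != "unchanged"}.
#' @param universe character vector of gene ids defining the sampling frame;
#'   must contain every regulated gene. A sensible default is the genes
#'   present in both DE tables.
#' @return list of class \code{overlap_result}: \code{n_A}, \code{n_B},
#'   \code{n_overlap}, \code{universe_size}, \code{overlap_pct} (percentage of
#'   A also regulated in B, one decimal), \code{concordant_up},
#'   \code{concordant_down}, \code{discordant}, \code{p_one_sided}.
#' @examples
#' # printed-style counts: 67 of 174 query genes also regulated -> 38.5%
#' @export
overlap_summary <- function(calls_A, calls_B, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  reg_A <- calls_A$gene_id[calls_A$direction != "unchanged"]
  reg_B <- calls_B$gene_id[calls_B$direction != "unchanged"]
  out_univ <- setdiff(c(reg_A, reg_B), universe)
  if (length(out_univ) > 0L) {
    stop("regulated gene not in universe: ", out_univ[1L])
  }
  ov <- intersect(reg_A, reg_B)
  dir_A <- calls_A$direction[match(ov, calls_A$gene_id)]
  dir_B <- calls_B$direction[match(ov, calls_B$gene_id)]
  n_A <- length(reg_A)
  n_B <- length(reg_B)
  n_overlap <- length(ov)
  structure(list(
    n_A = n_A, n_B = n_B, n_overlap = n_overlap,
    universe_size = length(universe),
    overlap_pct = if (n_A > 0L) round_half_away(100 * n_overlap / n_A, 1L) else NA_real_,
    concordant_up = sum(dir_A == "up" & dir_B == "up"),
    concordant_down = sum(dir_A == "down" & dir_B == "down"),
    discordant = sum(dir_A != dir_B),
    p_one_sided = fisher_exact_one_sided(
      n_overlap, n_A - n_overlap, n_B - n_overlap,
      length(universe) - n_A - n_B + n_overlap
    )
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "%d of %d query genes also regulated in the second set (%.1f%%)\n",
    x$n_overlap, x$n_A, x$overlap_pct
  ))
  cat(sprintf(
    "concordant: %d up + %d down = %d; discordant: %d\n",
    x$concordant_up, x$concordant_down,
    x$concordant_up + x$concordant_down, x$discordant
  ))
  cat(sprintf(
    "one-sided Fisher exact p = %.4g (universe %d)\n",
    x$p_one_sided, x$universe_size
  ))
  invisible(x)
}

#' Annotation-term over-representation with BH false-discovery control
#'
#' For each term, compares the observed count of query genes annotated to the
#' term with the count expected under hypergeometric sampling from the
#' universe, and reports fold enrichment, the one-sided Fisher p, and
#' Benjamini-Hochberg FDR across terms. Terms with no gene in the universe
#' are skipped with a warning.
#'
#' @param query_set character vector of query gene ids (restricted to the
#'   universe).
#' @param annotation_map named list, term id -> character vector of annotated
#'   gene ids.
#' @param universe character vector of gene ids.
#' @param fdr_method multiple-testing method passed to
#'   \code{stats::p.adjust} (default \code{"BH"}).
#' @return data.frame sorted by p: \code{term_id}, \code{observed},
#'   \code{expected}, \code{fold_enrichment}, \code{p_one_sided}, \code{fdr}.
#' @export
annotation_enrichment <- function(query_set, annotation_map, universe,
                                  fdr_method = "BH") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- intersect(unique(query_set), universe)
  nq <- length(query)
  nu <- length(universe)
  rows <- lapply(names(annotation_map), function(term) {
    genes <- intersect(unique(annotation_map[[term]]), universe)
    if (length(genes) == 0L) {
      warning("term ", term, " has no genes in the universe; skipped")
      return(NULL)
    }
    obs <- length(intersect(query, genes))
    expd <- nq * length(genes) / nu
    data.frame(
      term_id = term, observed = obs, expected = expd,
      fold_enrichment = obs / expd,
      p_one_sided = fisher_exact_one_sided(
        obs, nq - obs, length(genes) - obs,
        nu - nq - length(genes) + obs
      ),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(
      term_id = character(), observed = integer(), expected = numeric(),
      fold_enrichment = numeric(), p_one_sided = numeric(), fdr = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_one_sided, method = fdr_method)
  out <- out[order(out$p_one_sided, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
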