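#' Estimate repeat-unit count from a fragment-analysis allele size
#'
#' Capillary fragment analysis reports the total amplicon length; subtracting
#' the constant flanking (primer-to-repeat) length and dividing by the 4 bp
#' unit gives the repeat count. Ties (x.5) round away from zero.
#'
#' @param length_bp fragment length(s) in bases; must exceed \code{flank_bp}.
#' @param flank_bp non-repeat flank length included in the amplicon.
#' @return integer repeat-unit estimate(s).
#' @examples
#' estimate_repeat_units(112 + 80, 80) # 28
#' @export
estimate_repeat_units <- function(length_bp, flank_bp) {
  if (any(flank_bp < 0)) stop("flank_bp must be >= 0")
  if (any(length_bp <= flank_bp)) stop("fragment length must exceed the flank length")
  as.integer(round_half_away((length_bp - flank_bp) / 4))
}

#' Build per-sample allele calls from fragment sizes
#'
#' Homozygous samples carry one fragment length, heterozygous samples two;
#' the sample's mean allele length is the arithmetic mean of the listed
#' alleles.
#'
#' @param alleles data.frame with columns \code{sample_id}, \code{length1}
#'   and optionally \code{length2} (NA for homozygous samples).
#' @param flank_bp flank length for [estimate_repeat_units()].
#' @return data.frame: \code{sample_id}, \code{length1}, \code{length2},
#'   \code{mean_length_bp}, \code{units1}, \code{units2}.
#' @export
allele_calls <- function(alleles, flank_bp) {
  l2 <- if ("length2" %in% names(alleles)) alleles$length2 else rep(NA_real_, nrow(alleles))
  mean_len <- ifelse(is.na(l2), alleles$length1, (alleles$length1 + l2) / 2)
  units2 <- rep(NA_integer_, nrow(alleles))
  has2 <- !is.na(l2)
  if (any(has2)) units2[has2] <- estimate_repeat_units(l2[has2], flank_bp)
  data.frame(
    sample_id = as.character(alleles$sample_id),
    length1 = alleles$length1, length2 = l2,
    mean_length_bp = mean_len,
    units1 = estimate_repeat_units(alleles$length1, flank_bp),
    units2 = units2,
    stringsAsFactors = FALSE
  )
}

#' Correlate mean microsatellite allele length with expression
#'
#' Pairs samples by id, applies the stated exclusions explicitly (they are
#' recorded in the result, never silently dropped), and computes the
#' product-moment (Pearson, default) or rank (Spearman) correlation between
#' mean allele length and expression level.
#'
#' @param calls output of [allele_calls()] (needs \code{sample_id},
#'   \code{mean_length_bp}).
#' @param expression data.frame with \code{sample_id} and \code{value}
#'   (relative expression units, e.g. 2^-dCt).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param exclude character vector of sample ids to exclude (e.g. an outlier
#'   cell line), recorded in the result.
#' @return list of class \code{correlation_result}: \code{r}, \code{n},
#'   \code{method}, \code{excluded_samples}, and the paired data used
#'   (\code{pairs}).
#' @export
correlate_length_expression <- function(calls, expression,
                                        method = c("pearson", "spearman"),
                                        exclude = character()) {
  method <- match.arg(method)
  common <- intersect(calls$sample_id, expression$sample_id)
  used <- setdiff(common, exclude)
  if (length(used) < 3L) stop("need at least 3 paired samples after exclusions")
  x <- calls$mean_length_bp[match(used, calls$sample_id)]
  y <- expression$value[match(used, expression$sample_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in allele length or expression; correlation undefined")
  }
  structure(list(
    r = stats::cor(x, y, method = method),
    n = length(used), method = method,
    excluded_samples = intersect(exclude, common),
    pairs = data.frame(
      sample_id = used, mean_length_bp = x, expression = y,
      stringsAsFactors = FALSE
    )
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "%s correlation between mean allele length and expression: r = %.3f (n = %d)\n",
    x$method, x$r, x$n
  ))
  if (length(x$excluded_samples) > 0L) {
    cat("excluded:", paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative expression from qPCR cycle thresholds (2^-dCt)
#'
#' @param ct_gene,ct_reference cycle thresholds for the target and the
#'   housekeeping reference (e.g. TBP).
#' @return \code{2^-(ct_gene - ct_reference)}.
#' @examples
#' relative_expression(25, 25) # 1
#' relative_expression(28, 25) # 0.125
#' @export
relative_expression <- function(ct_gene, ct_reference) {
  2^(-(ct_gene - ct_reference))
}

#' Population doublings over a culture interval
#'
#' \code{log2(cells_final / cells_initial)}: a culture growing from 1000 to
#' 8000 cells has accumulated 3 doublings.
#'
#' @param cells_initial,cells_final positive cell counts.
#' @return number of population doublings.
#' @export
population_doublings <- function(cells_initial, cells_final) {
  if (any(cells_initial <= 0) || any(cells_final <= 0)) {
    stop("cell counts must be positive")
  }
  log2(cells_final / cells_initial)
}

#' Doubling time from elapsed time and accumulated doublings
#'
#' @param elapsed time elapsed over the interval (any unit).
#' @param doublings population doublings accumulated; must be positive.
#' @return time per doubling, in the unit of \code{elapsed}.
#' @export
doubling_time <- function(elapsed, doublings) {
  if (any(doublings <= 0)) stop("doubling time undefined for <= 0 doublings")
  elapsed / doublings
}
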