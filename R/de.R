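#' Classify genes as up-, down- or unregulated from a DE table
#'
#' Applies the printed-style inclusive thresholds: a gene is \code{down} when
#' \code{log2fc <= -lfc_threshold} and \code{padj <= padj_threshold}, \code{up}
#' when \code{log2fc >= lfc_threshold} and \code{padj <= padj_threshold}, and
#' \code{unchanged} otherwise. A missing \code{padj} (the DESeq2
#' independent-filtering convention) counts as not significant. Direction is
#' stored relative to the contrast in the table (typically knockdown vs
#' control); see [relabel_to_fusion()] for the fusion-centric framing.
#'
#' @param de_table data.frame with \code{gene_id}, \code{log2fc}, \code{padj}
#'   (see [read_de_table()]).
#' @param lfc_threshold positive log2-fold-change threshold (default 1).
#' @param padj_threshold adjusted-p threshold in (0, 1] (default 0.05).
#' @return data.frame of regulation calls: \code{gene_id}, \code{direction}
#'   (up/down/unchanged), \code{log2fc}, \code{padj}.
#' @export
classify_regulation <- function(de_table, lfc_threshold = 1, padj_threshold = 0.05) {
  if (lfc_threshold <= 0) stop("lfc_threshold must be > 0")
  if (padj_threshold <= 0 || padj_threshold > 1) stop("padj_threshold must be in (0, 1]")
  dup <- de_table$gene_id[duplicated(de_table$gene_id)]
  if (length(dup) > 0L) stop("duplicate gene_id in DE table: ", dup[1L])
  sig <- !is.na(de_table$padj) & de_table$padj <= padj_threshold &
    !is.na(de_table$log2fc)
  direction <- rep("unchanged", nrow(de_table))
  direction[sig & de_table$log2fc <= -lfc_threshold] <- "down"
  direction[sig & de_table$log2fc >= lfc_threshold] <- "up"
  data.frame(
    gene_id = de_table$gene_id, direction = direction,
    log2fc = de_table$log2fc, padj = de_table$padj,
    stringsAsFactors = FALSE
  )
}

#' Relabel knockdown-contrast calls to the fusion-centric framing
#'
#' A gene that goes down upon knockdown of the fusion protein is normally
#' activated by it. This helper maps \code{down} to
#' \code{fusion-activated} and \code{up} to \code{fusion-repressed} for
#' reports; \code{unchanged} is kept.
#'
#' @param calls output of [classify_regulation()].
#' @return the same data.frame with a \code{fusion_relation} column added.
#' @export
relabel_to_fusion <- function(calls) {
  calls$fusion_relation <- c(
    down = "fusion-activated", up = "fusion-repressed",
    unchanged = "unchanged"
  )[calls$direction]
  calls
}

#' Restrict regulation calls to a transcription-factor catalog
#'
#' Matches on exact identifier. The catalog is typically the membership of a
#' Gene Ontology term such as "DNA-binding transcription factor activity";
#' catalog members absent from the DE table are counted separately rather
#' than silently dropped.
#'
#' @param calls output of [classify_regulation()].
#' @param catalog character vector of catalog gene ids (see
#'   [read_gene_list()]).
#' @return list with \code{calls} (rows of \code{calls} restricted to the
#'   catalog), \code{n_down}, \code{n_up}, \code{n_present} (catalog members
#'   found in the table) and \code{n_unmatched} (catalog members absent).
#' @export
select_catalog_subset <- function(calls, catalog) {
  catalog <- unique(catalog)
  sub <- calls[calls$gene_id %in% catalog, , drop = FALSE]
  rownames(sub) <- NULL
  if (nrow(sub) == 0L) {
    warning("no catalog gene ids found in the DE table")
  }
  list(
    calls = sub,
    n_down = sum(sub$direction == "down"),
    n_up = sum(sub$direction == "up"),
    n_present = nrow(sub),
    n_unmatched = sum(!catalog %in% calls$gene_id)
  )
}

#' Percentage of catalog genes regulated
#'
#' @param n_down,n_up regulated counts in each direction.
#' @param n_present catalog members present in the dataset; must be at least
#'   \code{n_down + n_up}, which must be positive.
#' @return integer percentage \code{100 * (n_down + n_up) / n_present},
#'   rounded to the nearest integer (half away from zero).
#' @examples
#' regulated_fraction(89, 135, 1635) # 14
#' @export
regulated_fraction <- function(n_down, n_up, n_present) {
  if (n_present == 0L) stop("n_present must be positive")
  if (n_down + n_up <= 0L || n_present < n_down + n_up) {
    stop("need n_present >= n_down + n_up > 0")
  }
  round_half_away(100 * (n_down + n_up) / n_present)
}
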