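#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet}. Sequence names are
#' the first whitespace-delimited token of each header; sequences are
#' uppercased. Record order is preserved.
#'
#' @param path FASTA file path.
#' @return named character vector of DNA strings.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA record name: ", dup[1L])
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BED3+ file
#'
#' BED is natively 0-based half-open; coordinates are kept verbatim. Optional
#' columns 4-6 become \code{name}, \code{score}, \code{strand}; columns beyond
#' 6 are retained as \code{extra1}, \code{extra2}, ... unless the file carries
#' a \code{#}-prefixed header naming them.
#'
#' @param path BED file path (tab-separated).
#' @return interval data.frame in file order (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  header <- NULL
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  if (length(lines) > 0L && grepl("^#", lines[1L])) {
    header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  }
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(rows) == 0L) {
    return(genomic_intervals(character(), integer(), integer(), character()))
  }
  nf <- lengths(rows)
  if (any(nf < 3L)) {
    stop("BED line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 fields")
  }
  ncol_use <- min(nf)
  mat <- t(vapply(rows, function(r) r[seq_len(ncol_use)], character(ncol_use)))
  if (ncol_use == 1L) mat <- t(mat)
  start <- suppressWarnings(as.integer(mat[, 2L]))
  end <- suppressWarnings(as.integer(mat[, 3L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("BED line ", lineno[bad[1L]], ": non-integer coordinate")
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(
      "BED line ", lineno[bad[1L]], ": start >= end (", start[bad[1L]],
      " >= ", end[bad[1L]], ")"
    )
  }
  df <- data.frame(
    chrom = mat[, 1L], start = start, end = end,
    strand = if (ncol_use >= 6L) mat[, 6L] else ".",
    stringsAsFactors = FALSE
  )
  if (ncol_use >= 4L) df$name <- mat[, 4L]
  if (ncol_use >= 5L) df$score <- suppressWarnings(as.numeric(mat[, 5L]))
  if (ncol_use > 6L) {
    for (j in 7L:ncol_use) {
      nm <- if (!is.null(header) && length(header) >= j) header[j] else paste0("extra", j - 6L)
      v <- utils::type.convert(mat[, j], as.is = TRUE)
      df[[nm]] <- v
    }
  }
  validate_intervals(df)
  df
}

#' Write an interval table as BED
#'
#' Emits BED3, BED6, or BED6+ depending on the columns present; extra columns
#' (anything beyond chrom/start/end/name/score/strand) are appended after
#' column 6 and named in a leading \code{#} header so [read_bed()] round-trips
#' them.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  extra <- setdiff(names(x), c("chrom", "start", "end", "name", "score", "strand"))
  has6 <- length(extra) > 0L || any(c("name", "score", "strand") %in% names(x)) &&
    !(identical(unique(x$strand), ".") && !"name" %in% names(x) && !"score" %in% names(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x) == 0L) return(invisible(path))
  nm <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  sc <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  if (has6 || length(extra) > 0L) {
    cols <- cbind(x$chrom, x$start, x$end, nm, sc, x$strand)
    if (length(extra) > 0L) {
      writeLines(paste(c("#chrom", "start", "end", "name", "score", "strand", extra),
        collapse = "\t"
      ), con)
      cols <- cbind(cols, as.matrix(format(x[extra], trim = TRUE, scientific = FALSE)))
    }
  } else {
    cols <- cbind(x$chrom, x$start, x$end)
  }
  writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read gene models from a TSV or a GTF subset
#'
#' Both dialects describe the same objects: a gene identifier, its genomic
#' span, and a mandatory strand (the strand defines the transcription start
#' site, so \code{.} is rejected). Input coordinates are 1-based inclusive in
#' both dialects and are converted to the internal 0-based half-open
#' convention.
#'
#' @param path input file.
#' @param dialect \code{"tsv"} (header columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}) or \code{"gtf"} (lines whose
#'   feature field is \code{gene}, with a \code{gene_id} attribute).
#' @return data.frame with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (internal coordinates).
#' @export
read_gene_models <- function(path, dialect = c("tsv", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) stop("gene model TSV missing column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(
      gene_id = as.character(df$gene_id), chrom = as.character(df$chrom),
      start = as.integer(df$start) - 1L, end = as.integer(df$end),
      strand = as.character(df$strand), stringsAsFactors = FALSE
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(r) length(r) >= 9L && r[3L] == "gene", logical(1L))]
    if (length(f) == 0L) stop("no 'gene' feature lines in GTF subset: ", path)
    gid <- vapply(f, function(r) {
      m <- regmatches(r[9L], regexec('gene_id[ =]+"?([^";]+)"?', r[9L]))[[1L]]
      if (length(m) < 2L) NA_character_ else m[2L]
    }, character(1L))
    if (any(is.na(gid))) stop("GTF gene line without gene_id attribute")
    out <- data.frame(
      gene_id = gid,
      chrom = vapply(f, `[`, character(1L), 1L),
      start = as.integer(vapply(f, `[`, character(1L), 4L)) - 1L,
      end = as.integer(vapply(f, `[`, character(1L), 5L)),
      strand = vapply(f, `[`, character(1L), 7L),
      stringsAsFactors = FALSE
    )
  }
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(
      "gene ", out$gene_id[bad[1L]], " has strand '", out$strand[bad[1L]],
      "'; + or - required (TSS is strand-defined)"
    )
  }
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0L) stop("duplicate gene_id: ", dup[1L])
  validate_intervals(out)
  out
}

#' Write gene models as the 5-column TSV dialect (1-based inclusive)
#'
#' @param genes gene-model data.frame (internal coordinates).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start + 1L, end = genes$end, strand = genes$strand
  )
  write_tsv(out, path)
}

#' Read a differential-expression result table
#'
#' Accepts DESeq2-style result tables: a gene identifier column, a log2 fold
#' change and a BH-adjusted p-value. Missing (NA) \code{padj} values, which
#' DESeq2 emits under independent filtering, are preserved as NA; the
#' classification stage decides their meaning.
#'
#' @param path TSV file with a header row.
#' @param columns named character vector remapping the expected roles to the
#'   file's column names; defaults follow DESeq2
#'   (\code{c(gene_id = "gene_id", log2fc = "log2FoldChange", padj = "padj")}).
#' @return data.frame with columns \code{gene_id}, \code{log2fc}, \code{padj}.
#' @export
read_de_table <- function(path,
                          columns = c(
                            gene_id = "gene_id",
                            log2fc = "log2FoldChange", padj = "padj"
                          )) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(df))
  if (length(miss) > 0L) stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    gene_id = as.character(df[[columns[["gene_id"]]]]),
    log2fc = as.numeric(df[[columns[["log2fc"]]]]),
    padj = as.numeric(df[[columns[["padj"]]]]),
    stringsAsFactors = FALSE
  )
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0L) stop("duplicate gene_id in DE table: ", dup[1L])
  bad <- which(!is.na(out$padj) & (out$padj < 0 | out$padj > 1))
  if (length(bad) > 0L) stop("padj outside [0, 1] for gene ", out$gene_id[bad[1L]])
  out
}

#' Read a plain gene-id list (one id per line)
#'
#' Used for transcription-factor catalogs such as the membership of a Gene
#' Ontology term. Blank lines and \code{#} comments are skipped; duplicate ids
#' are collapsed.
#'
#' @param path text file, one identifier per line.
#' @return character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !grepl("^#", x)]
  unique(x)
}

#' Write a data.frame as a headered TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA"
  )
  invisible(path)
}
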