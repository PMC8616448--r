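#!/usr/bin/env Rscript
# Stage 3: relate fusion-protein binding peaks to genes.
#
# Peaks are flagged microsatellite-coincident when they overlap a scanned
# locus; genes are flagged when a coincident peak falls inside the gene body
# (any-overlap rule); and for every gene the nearest coincident peak on each
# side of the TSS within 10 kb is reported with a strand-aware distance.

suppressPackageStartupMessages(library(ggaareg))

seqs <- read_fasta("results/sim_inputs/genome.fa")
loci <- scan_microsatellites(seqs, scan_config())
peaks <- annotate_peaks_with_msats(read_bed("results/sim_inputs/peaks.bed"), loci)
genes <- read_gene_models("results/sim_inputs/genes.tsv")
write_tsv(peaks, "results/peaks_annotated.tsv")

coincident <- peaks[peaks$msat_coincident, ]
cat(sprintf(
  "%d of %d peaks are microsatellite-coincident\n",
  nrow(coincident), nrow(peaks)
))

inside <- genes_with_internal_peaks(genes, coincident)
write_tsv(inside, "results/inside_gene.tsv")
counts <- count_genes_with_peaks(inside$has_internal_peak)
cat(sprintf(
  "%d out of %d genes (%d%%) contain a coincident peak inside the gene body\n",
  counts$n_with, counts$n_total, counts$percentage
))

tss <- nearest_peaks_to_tss(genes, coincident, max_distance_bp = 10000L)
write_tsv(tss, "results/tss_assignments.tsv")
cat(sprintf(
  "nearest-peak assignments within 10 kb of a TSS: %d (%d upstream, %d downstream)\n",
  nrow(tss), sum(tss$relation == "upstream"), sum(tss$relation == "downstream")
))
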