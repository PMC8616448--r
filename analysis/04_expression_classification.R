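#!/usr/bin/env Rscript
# Stage 4: classify genes from the knockdown DE tables.
#
# A gene is called down when log2FC <= -1 and padj <= 0.05, up when
# log2FC >= 1 and padj <= 0.05 (boundaries inclusive, NA padj = not
# significant). Direction is relative to the knockdown, so "down upon
# knockdown" means the fusion protein normally activates the gene. A
# transcription-factor catalog (here: a synthetic stand-in for a GO-term
# membership list) restricts the calls to transcriptional regulators.

suppressPackageStartupMessages(library(ggaareg))

set.seed(20240424L)
for (tb in c("A", "B")) {
  de <- read_de_table(sprintf("results/sim_inputs/de_table_%s.tsv", tb))
  calls <- classify_regulation(de)
  write_tsv(relabel_to_fusion(calls), sprintf("results/regulation_calls_%s.tsv", tb))
  cat(sprintf(
    "table %s: %d down, %d up of %d genes\n",
    tb, sum(calls$direction == "down"), sum(calls$direction == "up"),
    nrow(calls)
  ))
}

# catalog cross-reference on table A: sample a catalog that includes a
# fixed share of the regulated genes plus unregulated members and absentees
calls <- classify_regulation(read_de_table("results/sim_inputs/de_table_A.tsv"))
reg <- calls$gene_id[calls$direction != "unchanged"]
unreg <- calls$gene_id[calls$direction == "unchanged"]
catalog <- c(sample(reg, 224), sample(unreg, 1411), sprintf("absent_%02d", 1:39))
writeLines(catalog, "results/tf_catalog.txt")

cs <- select_catalog_subset(calls, read_gene_list("results/tf_catalog.txt"))
cat(sprintf(
  "catalog: %d members present in the dataset, %d absent\n",
  cs$n_present, cs$n_unmatched
))
cat(sprintf(
  "%d down + %d up = %d regulated catalog members (%d%% of those present)\n",
  cs$n_down, cs$n_up, cs$n_down + cs$n_up,
  regulated_fraction(cs$n_down, cs$n_up, cs$n_present)
))
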