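#!/usr/bin/env Rscript
# Stage 5: overlap, concordance and enrichment statistics.
#
# How many genes regulated in the second knockdown (the query set) are also
# regulated in the first, how many agree in direction, and is the overlap
# larger than chance (one-sided Fisher exact test over the genes present in
# both tables)? A generic annotation over-representation with BH FDR rounds
# out the stage.

suppressPackageStartupMessages(library(ggaareg))

calls_A <- classify_regulation(read_de_table("results/sim_inputs/de_table_A.tsv"))
calls_B <- classify_regulation(read_de_table("results/sim_inputs/de_table_B.tsv"))
universe <- intersect(calls_A$gene_id, calls_B$gene_id)

ov <- overlap_summary(calls_B, calls_A, universe)
print(ov)
write_tsv(
  data.frame(
    n_query = ov$n_A, n_reference = ov$n_B, n_overlap = ov$n_overlap,
    universe_size = ov$universe_size, overlap_pct = ov$overlap_pct,
    concordant_up = ov$concordant_up, concordant_down = ov$concordant_down,
    discordant = ov$discordant, p_one_sided = ov$p_one_sided
  ),
  "results/overlap_summary.tsv"
)

# annotation over-representation: plant one genuinely enriched term among
# background terms drawn at random from the universe
set.seed(20240424L)
query <- calls_B$gene_id[calls_B$direction != "unchanged"]
amap <- list(planted_term = c(sample(query, 40), sample(universe, 160)))
for (k in 1:5) amap[[sprintf("background_%d", k)]] <- sample(universe, 200)
enr <- annotation_enrichment(query, amap, universe)
write_tsv(enr, "results/enrichment.tsv")
cat("\ntop enrichment rows:\n")
print(head(enr, 3), digits = 3)
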