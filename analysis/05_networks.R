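#!/usr/bin/env Rscript
# Stage 5: bipartite networks of consistently regulated miRNAs and
# inversely regulated predicted target proteins (support >= 5 algorithms).

suppressMessages(library(mirfine))

ind <- "results/synthetic_study"
out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()

pred <- read_predictions(file.path(ind, "predictions.tsv"))
map_df <- utils::read.delim(file.path(ind, "gene_protein_map.tsv"))
map <- gene_protein_map(map_df$protein_id, map_df$gene_id)
sel <- utils::read.delim("results/expression/consistent_mirnas.tsv")
d3 <- utils::read.delim("results/proteome/protein_d3_vs_native.tsv")
d7 <- utils::read.delim("results/proteome/protein_d7_vs_native.tsv")
tc <- timecourse_directions(d3, d7)

sel <- sel[sel$feature_id %in% unique(pred$mirna), , drop = FALSE]
cat(sprintf("%d selected miRNAs covered by the prediction table\n", nrow(sel)))
if (nrow(sel) == 0) {
  # power-limited selection on the synthetic panel: illustrate the network
  # stage with the ground-truth consistently regulated miRNAs instead
  tr <- utils::read.delim(file.path(ind, "truth_mirna.tsv"))
  cons <- tr[tr$regulated & abs(tr$d3) > log2(1.5) & abs(tr$d7) > log2(1.5) &
               abs(tr$d14) > log2(1.5) & tr$direction != "none", ]
  sel <- data.frame(feature_id = cons$feature_id, direction = cons$direction)
  sel <- sel[sel$feature_id %in% unique(pred$mirna), , drop = FALSE]
  cat(sprintf("falling back to the %d ground-truth consistent miRNAs for illustration\n",
              nrow(sel)))
}
for (dirn in c("down-up", "up-down")) {
  net <- build_inverse_network(sel, tc, pred, map, dirn, cfg$min_support)
  print(net)
  tag <- gsub("-", "_", dirn)
  write_network(net, file.path(out, sprintf("net_%s.graphml", tag)), "graphml")
  write_network(net, file.path(out, sprintf("net_%s.sif", tag)), "sif")
  write_network(net, file.path(out, sprintf("net_%s_edges.tsv", tag)), "edge_tsv")
}
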