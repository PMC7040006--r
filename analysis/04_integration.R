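#!/usr/bin/env Rscript
# Stage 4: transcript-protein integration — coverage, fold-change
# concordance, quadrant and Venn counts, heatmap ordering.

suppressMessages(library(mirfine))

ind <- "results/synthetic_study"
out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()

map_df <- utils::read.delim(file.path(ind, "gene_protein_map.tsv"))
map <- gene_protein_map(map_df$protein_id, map_df$gene_id)

venn_rows <- quad_rows <- corr_rows <- NULL
mirna_sets <- list()
for (tp in c("d3", "d7")) {
  mrna <- utils::read.delim(sprintf("results/expression/mrna_%s_vs_native.tsv", tp))
  prot <- utils::read.delim(sprintf("results/proteome/protein_%s_vs_native.tsv", tp))
  j <- join_omics(mrna, prot, map)
  qc <- quadrant_classify(j, "both_significant", cfg)
  qf <- quadrant_classify(j, "fc_only", cfg)
  quad_rows <- rbind(quad_rows, qc, qf)
  corr_rows <- rbind(corr_rows, data.frame(
    contrast = paste0(tp, "_vs_native"),
    coverage = attr(j, "coverage"), n_pairs = nrow(j),
    r_all = fc_correlation(j, "all"),
    r_significant_mrna = tryCatch(fc_correlation(j, "significant_mrna"),
                                  error = function(e) NA_real_)))
  cat(sprintf("%s: %d joined pairs (coverage %.2f), r=%.2f overall, %d/%d inverse (sig/FC-only)\n",
              tp, nrow(j), attr(j, "coverage"), fc_correlation(j, "all"),
              qc$n_mrna_up_protein_down + qc$n_mrna_down_protein_up,
              qf$n_mrna_up_protein_down + qf$n_mrna_down_protein_up))
}
utils::write.table(quad_rows, file.path(out, "quadrant_counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(corr_rows, file.path(out, "fc_correlations.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# Venn regions of up-/downregulated miRNAs across the three timepoints
for (dirn in c("up", "down")) {
  sets <- lapply(c(d3 = "d3", d7 = "d7", d14 = "d14"), function(tp) {
    d <- utils::read.delim(sprintf("results/expression/mirna_%s_vs_native.tsv", tp))
    d$feature_id[d$direction == dirn]
  })
  v <- venn_counts(sets)
  cat(sprintf("miRNAs %s: ", dirn))
  print(v)
  venn_rows <- rbind(venn_rows, data.frame(direction = dirn,
                                           region = names(v), count = v))
}
utils::write.table(venn_rows, file.path(out, "mirna_venn_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# heatmap ordering of the proteome on log2 abundance
m <- read_matrix(file.path(ind, "protein_abundance.tsv"),
                 file.path(ind, "protein_samples.tsv"))
lg <- m
lg$values <- log2(m$values)
h <- heatmap_order(lg, cv_threshold = 0.01)
cat(sprintf("heatmap: %d of %d proteins pass the CV filter\n",
            length(h$features), nrow(m$values)))
utils::write.table(data.frame(order = seq_along(h$features),
                              feature_id = h$features),
                   file.path(out, "heatmap_feature_order.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
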