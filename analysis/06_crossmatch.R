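#!/usr/bin/env Rscript
# Stage 6: transfection experiments — differential abundance of transfected
# versus control-siRNA cells and the crossmatch with inversely regulated
# predicted targets of the time course.

suppressMessages(library(mirfine))

ind <- "results/synthetic_study"
out <- "results/crossmatch"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()

pred <- read_predictions(file.path(ind, "predictions.tsv"))
map_df <- utils::read.delim(file.path(ind, "gene_protein_map.tsv"))
map <- gene_protein_map(map_df$protein_id, map_df$gene_id)
d3 <- utils::read.delim("results/proteome/protein_d3_vs_native.tsv")
d7 <- utils::read.delim("results/proteome/protein_d7_vs_native.tsv")
tc <- timecourse_directions(d3, d7)

reports <- list()
for (f in list.files(ind, pattern = "^transfection_.*_samples\\.tsv$")) {
  mat_file <- file.path(ind, sub("_samples", "", f))
  m <- read_matrix(mat_file, file.path(ind, f))
  cond <- setdiff(unique(m$samples$condition), "control_sirna")
  mode <- sub(":.*", "", cond)
  mirna <- sub(".*:", "", cond)
  arms <- split_transfection(m)
  d <- transfection_diff(arms$trans, arms$control, cfg)
  cm <- crossmatch(d, pred, mirna, mode, tc, map, "any")
  reports[[cond]] <- cm
  cat(sprintf("%s %s: %d quantified, %d predicted, %d %s-regulated, %d regulated+predicted, overlap %d\n",
              mode, mirna, cm$n_quantified, cm$n_predicted_of_quantified,
              if (mode == "mimic") cm$n_regulated_down else cm$n_regulated_up,
              if (mode == "mimic") "down" else "up",
              cm$n_regulated_expected_direction_and_predicted, cm$n_overlap))
}
write_crossmatch(reports, file.path(out, "crossmatch_reports.tsv"))
cat("crossmatch reports written to", file.path(out, "crossmatch_reports.tsv"), "\n")
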