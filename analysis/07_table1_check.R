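#!/usr/bin/env Rscript
# Stage 7: consistency checks of the packaged expression table of highly
# expressed regulated miRNAs — recompute the printed log2 fold changes from
# the printed CPM means and reproduce the published set logic.

suppressMessages(library(mirfine))

out <- "results/table1"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_table1()
rc <- recompute_table1_fc(tab)
cat(sprintf("fold-change recomputation: %d of %d values match after rounding; max |dev| %.3f\n",
            sum(rc$match), nrow(rc), max(abs(rc$dev))))
utils::write.table(rc, file.path(out, "fc_recomputation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

sets <- classify_cpm100(tab)
cat(sprintf("downregulated from mean CPM > 100: %d miRNAs\n", length(sets$down)))
cat(sprintf("upregulated to mean CPM > 100:    %d miRNAs\n", length(sets$up)))

dt <- table1_difftables(tab)
sel <- select_consistent_mirnas(dt$d3, dt$d7, dt$d14)
cat("consistently downregulated:",
    paste(sel$feature_id[sel$direction == "down"], collapse = ", "), "\n")
cat("consistently upregulated:  ",
    paste(sel$feature_id[sel$direction == "up"], collapse = ", "), "\n")
utils::write.table(sel, file.path(out, "consistent_mirnas.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
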