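# Small builders for matrices and metadata used across test files.

make_meta <- function(ids, line, timepoint, modality, condition = "untreated") {
  data.frame(sample_id = ids, line = line, timepoint = timepoint,
             condition = condition, modality = modality,
             stringsAsFactors = FALSE)
}

# counts matrix: one value per (feature, timepoint), replicated over lines
# with optional per-sample multipliers
toy_counts <- function(values, timepoints, lines = c("4/101", "4/146"),
                       modality = "mirna_counts") {
  stopifnot(ncol(values) == length(timepoints))
  grid <- expand.grid(line = lines, tp = timepoints, stringsAsFactors = FALSE)
  vals <- values[, match(grid$tp, timepoints), drop = FALSE]
  ids <- sprintf("s_%s_%s", gsub("/", "-", grid$line), grid$tp)
  dimnames(vals) <- list(rownames(values), ids)
  omics_matrix(vals, make_meta(ids, grid$line, grid$tp, modality))
}

toy_protein <- function(values, timepoints, lines = paste0("L", 1:3)) {
  grid <- expand.grid(line = lines, tp = timepoints, stringsAsFactors = FALSE)
  stopifnot(ncol(values) == nrow(grid))
  ids <- sprintf("p_%s_%s_%d", gsub("/", "-", grid$line), grid$tp, seq_len(nrow(grid)))
  dimnames(values) <- list(rownames(values), ids)
  omics_matrix(values, make_meta(ids, grid$line, grid$tp, "protein_abundance"))
}

# fast config for simulation-heavy tests; ... overrides any default
small_synth <- function(seed = 1, ...) {
  args <- list(seed = seed, n_mrna = 2000, n_mirna = 150, n_protein = 400)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}
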