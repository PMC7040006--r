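#' Feature-by-sample omics matrix with sample metadata
#'
#' The common container for raw mRNA/miRNA counts and protein abundances.
#' Values are a non-negative numeric matrix (features in rows, samples in
#' columns); `samples` is a data frame of per-sample metadata with one row
#' per column of `values`, in the same order.
#'
#' @param values numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs). Count modalities must hold integers.
#' @param samples data frame with columns `sample_id`, `line`, `timepoint`
#'   (one of `native`, `d3`, `d7`, `d14`), `condition` (`untreated`,
#'   `control_sirna`, `mimic:<miRNA>` or `inhibitor:<miRNA>`) and `modality`
#'   (`mrna_counts`, `mirna_counts` or `protein_abundance`).
#' @param unique_peptides optional named integer vector (protein modality):
#'   unique peptides per protein, used by the ingest filter.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, samples, unique_peptides = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("values must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_("duplicate feature IDs: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (any(is.na(values))) stop_("values contain missing entries")
  if (any(values < 0)) stop_("negative values are not allowed")

  need <- c("sample_id", "line", "timepoint", "condition", "modality")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop_("sample metadata lacks column(s): %s", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop_("duplicate sample_id in metadata")
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop_("metadata rows must match matrix columns in the same order")
  bad_tp <- setdiff(unique(samples$timepoint), TIMEPOINTS)
  if (length(bad_tp)) stop_("unknown timepoint(s): %s", paste(bad_tp, collapse = ", "))
  if (length(unique(samples$modality)) != 1L)
    stop_("a matrix must hold a single modality")
  modality <- samples$modality[1]
  if (!modality %in% MODALITIES) stop_("unknown modality: %s", modality)
  ok_cond <- samples$condition == "untreated" | samples$condition == "control_sirna" |
    grepl("^(mimic|inhibitor):", samples$condition)
  if (!all(ok_cond))
    stop_("unknown condition(s): %s",
          paste(unique(samples$condition[!ok_cond]), collapse = ", "))
  if (modality == "protein_abundance" && any(samples$timepoint == "d14"))
    stop_("protein abundance samples cannot carry timepoint d14")
  if (is_count_modality(modality) && any(values != floor(values)))
    stop_("count modalities must contain integer values")
  if (!is.null(unique_peptides)) {
    unique_peptides <- unique_peptides[rownames(values)]
    if (any(is.na(unique_peptides)))
      stop_("unique_peptides must be named for every feature")
  }

  structure(list(values = values, samples = samples,
                 unique_peptides = unique_peptides),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$samples$modality[1]))
  cat("timepoints:", paste(unique(x$samples$timepoint), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by feature and/or sample
#'
#' @param m an `omics_matrix`.
#' @param features character vector of feature IDs to keep (default all).
#' @param sample_idx logical or integer index over samples (default all).
#' @return an `omics_matrix`.
#' @export
subset_omics <- function(m, features = NULL, sample_idx = NULL) {
  v <- m$values
  up <- m$unique_peptides
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing)) stop_("unknown feature(s): %s", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[features, , drop = FALSE]
    if (!is.null(up)) up <- up[features]
  }
  s <- m$samples
  if (!is.null(sample_idx)) {
    v <- v[, sample_idx, drop = FALSE]
    s <- s[sample_idx, , drop = FALSE]
  }
  omics_matrix(v, s, up)
}

#' Read a feature-by-sample matrix plus its metadata sidecar
#'
#' Matrix files are TAB-separated with the feature ID in the first column and
#' sample IDs in the header; an optional `unique_peptides` column carries the
#' per-protein unique peptide count. The metadata sidecar maps each sample ID
#' to line, timepoint, condition and modality. For the protein modality,
#' features supported by fewer than `min_unique_peptides` unique peptides are
#' dropped at ingest (the count dropped is reported via [message()]), so all
#' downstream statistics refer to the filtered matrix.
#'
#' @param path path to the matrix TSV.
#' @param meta_path path to the metadata TSV.
#' @param min_unique_peptides minimum unique peptides required to quantify a
#'   protein (default 2).
#' @return an `omics_matrix`.
#' @export
read_matrix <- function(path, meta_path, min_unique_peptides = 2) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop_("matrix file %s has no sample columns", path)
  feats <- raw[[1]]
  if (anyDuplicated(feats)) stop_("duplicate feature IDs in %s", path)
  up <- NULL
  if ("unique_peptides" %in% names(raw)[-1]) {
    up <- as.integer(raw[["unique_peptides"]])
    names(up) <- feats
    raw <- raw[, names(raw) != "unique_peptides" | seq_along(raw) == 1, drop = FALSE]
  }
  num <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(num), nrow = nrow(num),
                                  dimnames = list(feats, colnames(num))))
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_("non-numeric cell in %s at feature '%s', sample '%s'",
          path, feats[idx[1]], colnames(vals)[idx[2]])
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing))
    stop_("sample(s) missing from metadata %s: %s", meta_path,
          paste(missing, collapse = ", "))
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  if (meta$modality[1] == "protein_abundance" && !is.null(up)) {
    keep <- up >= min_unique_peptides
    if (any(!keep))
      message(sprintf("read_matrix: dropped %d protein(s) with < %d unique peptides",
                      sum(!keep), min_unique_peptides))
    vals <- vals[keep, , drop = FALSE]
    up <- up[keep]
  }
  omics_matrix(vals, meta, up)
}

#' Write a matrix and its metadata sidecar
#'
#' Numbers are written with enough digits that a write-then-read round trip
#' reproduces them exactly.
#'
#' @param m an `omics_matrix`.
#' @param path matrix TSV destination.
#' @param meta_path metadata TSV destination.
#' @return invisibly, `m`.
#' @export
write_matrix <- function(m, path, meta_path) {
  v <- m$values
  out <- data.frame(feature_id = rownames(v), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) out[[colnames(v)[j]]] <- fmt_num(v[, j])
  if (!is.null(m$unique_peptides)) out$unique_peptides <- m$unique_peptides
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Gene-protein identifier map
#'
#' An explicit two-column map between protein IDs and gene IDs; many-to-one
#' relations are allowed in either direction, exact duplicate pairs are not.
#'
#' @param protein_id,gene_id character vectors of equal length.
#' @return a data frame of class `gene_protein_map`.
#' @export
gene_protein_map <- function(protein_id, gene_id) {
  df <- data.frame(protein_id = as.character(protein_id),
                   gene_id = as.character(gene_id), stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop_("gene-protein map contains duplicated pairs")
  class(df) <- c("gene_protein_map", "data.frame")
  df
}
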