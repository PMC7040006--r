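# Transcript-protein integration: joining differential tables through the
# identifier map, concordance correlations, quadrant and Venn counts, and
# heatmap feature selection/ordering.

#' Join mRNA and protein differential tables through the identifier map
#'
#' Inner join of per-gene and per-protein results for the same contrast.
#' Many-to-many maps are expanded to all pairs with a warning. The fraction
#' of quantified proteins matched by the map (coverage) is attached as an
#' attribute.
#'
#' @param mrna,prot `diff_table`s for the same timepoint-vs-native contrast.
#' @param map a [gene_protein_map()].
#' @return data frame of class `joined_diff` with `gene_id`, `protein_id`
#'   and prefixed mRNA/protein statistics columns; attribute `coverage`.
#' @export
join_omics <- function(mrna, prot, map) {
  if (nrow(map) == 0) stop_("empty gene-protein map")
  if (!is.null(mrna$contrast) && !is.null(prot$contrast) &&
      !identical(mrna$contrast[1], prot$contrast[1]))
    warning(sprintf("contrasts differ: %s vs %s", mrna$contrast[1], prot$contrast[1]))
  if (anyDuplicated(map$protein_id) || anyDuplicated(map$gene_id))
    warning("many-to-many gene-protein map: expanding to all pairs")
  cols <- c("feature_id", "log2fc", "p", "q", "significant", "direction")
  mr <- stats::setNames(mrna[cols], c("gene_id", paste0("mrna_", cols[-1])))
  pr <- stats::setNames(prot[cols], c("protein_id", paste0("prot_", cols[-1])))
  j <- merge(merge(map, mr, by = "gene_id"), pr, by = "protein_id")
  j <- j[order(j$gene_id, j$protein_id), , drop = FALSE]
  rownames(j) <- NULL
  attr(j, "coverage") <- length(intersect(prot$feature_id, map$protein_id)) /
    length(unique(prot$feature_id))
  attr(j, "contrast") <- mrna$contrast[1]
  class(j) <- c("joined_diff", "data.frame")
  j
}

#' Classify joined mRNA-protein pairs into regulation quadrants
#'
#' With `mode = "both_significant"` a pair enters a quadrant cell only if it
#' passes the full significance gate on the respective side(s); with
#' `mode = "fc_only"` the gate is `|log2fc| > log2(fc_cut)` alone,
#' significance ignored (the convention under which inversely regulated
#' pairs are counted independent of statistics).
#'
#' @param j a `joined_diff` frame.
#' @param mode `"both_significant"` or `"fc_only"`.
#' @param cfg a [pipeline_config()] (supplies `fc_cut` for `fc_only`).
#' @return one-row data frame of class `quadrant_counts`.
#' @export
quadrant_classify <- function(j, mode = c("both_significant", "fc_only"),
                              cfg = pipeline_config()) {
  mode <- match.arg(mode)
  if (mode == "both_significant") {
    m_pass <- j$mrna_significant
    p_pass <- j$prot_significant
  } else {
    cut <- log2(cfg$fc_cut)
    m_pass <- !is.na(j$mrna_log2fc) & abs(j$mrna_log2fc) > cut
    p_pass <- !is.na(j$prot_log2fc) & abs(j$prot_log2fc) > cut
  }
  m_up <- !is.na(j$mrna_log2fc) & j$mrna_log2fc > 0
  p_up <- !is.na(j$prot_log2fc) & j$prot_log2fc > 0
  out <- data.frame(
    contrast = attr(j, "contrast") %||% NA_character_, mode = mode,
    n_both_up = sum(m_pass & p_pass & m_up & p_up),
    n_both_down = sum(m_pass & p_pass & !m_up & !p_up),
    n_mrna_up_protein_down = sum(m_pass & p_pass & m_up & !p_up),
    n_mrna_down_protein_up = sum(m_pass & p_pass & !m_up & p_up),
    n_mrna_only_up = sum(m_pass & !p_pass & m_up),
    n_mrna_only_down = sum(m_pass & !p_pass & !m_up),
    n_protein_only_up = sum(!m_pass & p_pass & p_up),
    n_protein_only_down = sum(!m_pass & p_pass & !p_up),
    stringsAsFactors = FALSE)
  class(out) <- c("quadrant_counts", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation of mRNA and protein fold changes
#'
#' Pearson correlation of the joined (mRNA log2FC, protein log2FC) pairs,
#' either over all pairs or restricted to pairs whose mRNA passes the full
#' significance gate.
#'
#' @param j a `joined_diff` frame.
#' @param subset `"all"` or `"significant_mrna"`.
#' @return Pearson correlation coefficient.
#' @export
fc_correlation <- function(j, subset = c("all", "significant_mrna")) {
  subset <- match.arg(subset)
  if (subset == "significant_mrna") j <- j[j$mrna_significant, , drop = FALSE]
  ok <- !is.na(j$mrna_log2fc) & !is.na(j$prot_log2fc)
  if (sum(ok) < 3) stop_("fewer than 3 complete pairs after subsetting")
  stats::cor(j$mrna_log2fc[ok], j$prot_log2fc[ok])
}

#' Venn region counts for two or three named sets
#'
#' Counts every exclusive intersection region (inclusion-exclusion
#' complete); region labels join the member set names with `&` in the order
#' the sets are given.
#'
#' @param sets named list of 2-3 character vectors.
#' @return named integer vector, one entry per non-empty region label.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3) stop_("venn_counts needs 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0)
    memb <- matrix(logical(0), 0, length(sets), dimnames = list(NULL, names(sets)))
  nm <- names(sets)
  idx <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(seq_along(nm), k, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(idx, function(ii) {
    inside <- rowSums(memb[, ii, drop = FALSE]) == length(ii)
    outside <- rowSums(memb[, -ii, drop = FALSE]) == 0
    sum(inside & outside)
  }, integer(1))
  names(counts) <- vapply(idx, function(ii) paste(nm[ii], collapse = "&"), character(1))
  counts
}

#' Heatmap feature selection, clustering order and row scaling
#'
#' Features whose coefficient of variation (sd/mean on the supplied scale)
#' exceeds `cv_threshold` are retained, then features and samples are
#' ordered by hierarchical agglomerative clustering with distance
#' `1 - Pearson r` and, by default, average linkage. Row scaling is the
#' per-row z-score.
#'
#' @param m an `omics_matrix` (CPM or abundances; values on the analysis
#'   scale).
#' @param cv_threshold non-negative CV cutoff (strict inequality).
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list with `features` (ordered IDs), `samples` (ordered IDs),
#'   `scaled` (row-z-scored matrix in clustered order) and the two `hclust`
#'   objects.
#' @export
heatmap_order <- function(m, cv_threshold = 0.1, linkage = "average") {
  if (cv_threshold < 0) stop_("cv_threshold must be non-negative")
  x <- m$values
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  cv <- ifelse(mu == 0, ifelse(sdv == 0, 0, NA), sdv / mu)
  keep <- !is.na(cv) & cv > cv_threshold & sdv > 0
  if (!any(keep)) stop_("no feature passes the CV threshold %g", cv_threshold)
  x <- x[keep, , drop = FALSE]
  feat_d <- stats::as.dist(1 - suppressWarnings(stats::cor(t(x))))
  hc_f <- stats::hclust(feat_d, method = linkage)
  hc_s <- NULL
  samp_order <- seq_len(ncol(x))
  if (ncol(x) > 2) {
    samp_d <- stats::as.dist(1 - suppressWarnings(stats::cor(x)))
    hc_s <- stats::hclust(samp_d, method = linkage)
    samp_order <- hc_s$order
  }
  scaled <- t(scale(t(x)))
  list(features = rownames(x)[hc_f$order], samples = colnames(x)[samp_order],
       scaled = scaled[hc_f$order, samp_order, drop = FALSE],
       hclust_features = hc_f, hclust_samples = hc_s)
}
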