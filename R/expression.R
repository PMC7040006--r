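# Sequencing-count statistics: CPM normalisation, expression filters,
# fold changes versus native cells, per-feature differential tests and the
# consistent-direction miRNA selection.

#' Counts per million
#'
#' Intra-sample normalisation by sequencing depth: each column is scaled by
#' its own total count times 1e6. No between-sample scaling factor is
#' applied.
#'
#' @param m an `omics_matrix` of a counts modality.
#' @return an `omics_matrix` whose values are CPM (modality unchanged,
#'   class gains `cpm_matrix`).
#' @export
compute_cpm <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!is_count_modality(m$samples$modality[1]))
    stop_("compute_cpm expects a counts modality")
  lib <- colSums(m$values)
  if (any(lib == 0)) stop_("zero library size in sample(s): %s",
                           paste(colnames(m$values)[lib == 0], collapse = ", "))
  out <- m
  out$values <- sweep(m$values, 2, lib, "/") * 1e6
  class(out) <- c("cpm_matrix", class(m))
  out
}

# mean CPM per timepoint (across lines), features x timepoints present
timepoint_means <- function(cpm) {
  tps <- intersect(TIMEPOINTS, unique(cpm$samples$timepoint))
  matrix(vapply(tps, function(tp) {
    rowMeans(cpm$values[, cpm$samples$timepoint == tp, drop = FALSE])
  }, numeric(nrow(cpm$values))),
  nrow = nrow(cpm$values), dimnames = list(rownames(cpm$values), tps))
}

#' Low-expression filter
#'
#' Keeps a feature when its mean CPM across lines exceeds `floor` at one or
#' more timepoints. The filter is evaluated at timepoint granularity, not per
#' sample.
#'
#' @param cpm a CPM matrix from [compute_cpm()].
#' @param floor CPM floor (default 1, strict inequality).
#' @return character vector of retained feature IDs, in input order.
#' @export
filter_low_expression <- function(cpm, floor = 1) {
  tm <- timepoint_means(cpm)
  rownames(cpm$values)[apply(tm > floor, 1, any)]
}

#' Protein-coding filter
#'
#' Order-preserving intersection of a feature list with the set of IDs known
#' to encode proteins; removes non-coding transcripts before any
#' transcript-protein comparison.
#'
#' @param features character vector of feature IDs.
#' @param coding_ids character vector (or set) of protein-coding IDs.
#' @return the coding features, in input order.
#' @export
filter_protein_coding <- function(features, coding_ids) {
  if (length(coding_ids) == 0) {
    warning("empty protein-coding list: returning no features")
    return(character(0))
  }
  features[features %in% coding_ids]
}

#' Log2 fold change of a timepoint versus native cells
#'
#' The ratio-of-means convention: `log2((mean CPM at t + pc) / (mean CPM
#' native + pc))`, means taken across cell lines. With `pseudocount = 0` an
#' undefined ratio (zero denominator, or 0/0) is reported as `NA`, never as a
#' silent infinity.
#'
#' @param cpm a CPM matrix (or any `omics_matrix` on a positive scale).
#' @param t target timepoint (`d3`, `d7` or `d14`).
#' @param pseudocount added to both means before the ratio (default 0).
#' @return named numeric vector of log2 fold changes per feature.
#' @export
log2fc_vs_native <- function(cpm, t, pseudocount = 0) {
  if (t == "native") stop_("t must differ from the native reference")
  s <- cpm$samples
  if (!any(s$timepoint == "native")) stop_("no native samples present")
  if (!any(s$timepoint == t)) stop_("no samples at timepoint %s", t)
  m_alt <- rowMeans(cpm$values[, s$timepoint == t, drop = FALSE]) + pseudocount
  m_ref <- rowMeans(cpm$values[, s$timepoint == "native", drop = FALSE]) + pseudocount
  fc <- ifelse(m_ref > 0 & m_alt > 0, log2(m_alt / m_ref),
               ifelse(m_ref > 0 & m_alt == 0, -Inf, NA_real_))
  fc[is.infinite(fc)] <- NA_real_
  names(fc) <- rownames(cpm$values)
  fc
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j >= i} p(j) * m / j` after sorting p ascending, mapped back
#' to input order and capped at 1. Ties are handled by a stable sort.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`, no missing values.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals))) stop_("p-values contain missing values")
  if (any(pvals < 0 | pvals > 1)) stop_("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

# vectorised two-sided Welch t-test on rows of x (group1) vs y (group2)
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows, zero variance in both groups: equal means are a clean
  # null; unequal constant groups carry no variance information, p missing
  degen <- se2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- NA_real_
  data.frame(diff = m1 - m2, t = tt, df = df, p = p)
}

# BH over the non-missing p-values, NA propagated
qvals_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  q
}

new_diff_table <- function(feature_id, contrast, mean_ref, mean_alt,
                           log2fc, log2fc_raw, p, q, cfg) {
  significant <- !is.na(p) & p < cfg$p_cut & q < cfg$q_cut &
    !is.na(log2fc) & abs(log2fc) > log2(cfg$fc_cut)
  df <- data.frame(feature_id = feature_id, contrast = contrast,
                   mean_ref = mean_ref, mean_alt = mean_alt,
                   log2fc = log2fc, log2fc_raw = log2fc_raw,
                   p = p, q = q, significant = significant,
                   direction = direction_of(log2fc, significant),
                   stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("diff_table", "data.frame")
  df
}

#' Differential expression of a timepoint versus native cells
#'
#' Per-feature two-sided Welch t-test on `log2(CPM + 0.5)`, BH correction
#' within the contrast, and the shared significance gate (`p < p_cut`,
#' `q < q_cut`, `|log2fc| > log2(fc_cut)`). The `log2fc` column (used for the
#' gate) is the ratio of pseudocounted mean CPMs; `log2fc_raw` is the same
#' ratio with pseudocount 0, the convention under which printed fold-change
#' tables are reproduced.
#'
#' @param m an `omics_matrix` of counts.
#' @param t target timepoint, contrasted against `native`.
#' @param cfg a [pipeline_config()].
#' @return a `diff_table` data frame with one row per feature.
#' @export
test_differential <- function(m, t, cfg = pipeline_config()) {
  cpm <- if (inherits(m, "cpm_matrix")) m else compute_cpm(m)
  s <- cpm$samples
  n_alt <- sum(s$timepoint == t); n_ref <- sum(s$timepoint == "native")
  if (n_alt < 2) stop_("group '%s' has fewer than 2 replicates", t)
  if (n_ref < 2) stop_("group 'native' has fewer than 2 replicates")
  lg <- log2(cpm$values + 0.5)
  w <- welch_rows(lg[, s$timepoint == t, drop = FALSE],
                  lg[, s$timepoint == "native", drop = FALSE])
  q <- qvals_na(w$p)
  mean_alt <- rowMeans(cpm$values[, s$timepoint == t, drop = FALSE])
  mean_ref <- rowMeans(cpm$values[, s$timepoint == "native", drop = FALSE])
  new_diff_table(rownames(cpm$values), paste0(t, "_vs_native"),
                 mean_ref, mean_alt,
                 log2fc = log2fc_vs_native(cpm, t, cfg$pseudocount),
                 log2fc_raw = log2fc_vs_native(cpm, t, 0),
                 p = w$p, q = q, cfg = cfg)
}

#' Select miRNAs consistently regulated at all three timepoints
#'
#' A miRNA qualifies when it is significant at 3d, 7d and 14d with the same
#' regulation direction.
#'
#' @param d3,d7,d14 `diff_table`s (or any data frames with `feature_id`,
#'   `significant` and `direction` columns) for the three contrasts.
#' @return data frame with `feature_id` and `direction` of the selected
#'   miRNAs.
#' @export
select_consistent_mirnas <- function(d3, d7, d14) {
  tabs <- list(d3 = d3, d7 = d7, d14 = d14)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]]) ||
        !all(c("feature_id", "significant", "direction") %in% names(tabs[[nm]])))
      stop_("contrast '%s' is missing or malformed", nm)
  }
  j <- merge(merge(tabs$d3[c("feature_id", "significant", "direction")],
                   tabs$d7[c("feature_id", "significant", "direction")],
                   by = "feature_id", suffixes = c("_d3", "_d7")),
             stats::setNames(tabs$d14[c("feature_id", "significant", "direction")],
                             c("feature_id", "significant_d14", "direction_d14")),
             by = "feature_id")
  keep <- j$significant_d3 & j$significant_d7 & j$significant_d14 &
    j$direction_d3 == j$direction_d7 & j$direction_d7 == j$direction_d14 &
    j$direction_d3 != "none"
  out <- data.frame(feature_id = j$feature_id[keep],
                    direction = j$direction_d3[keep],
                    stringsAsFactors = FALSE)
  out[order(match(out$feature_id, d3$feature_id)), , drop = FALSE]
}
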