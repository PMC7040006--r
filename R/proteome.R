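# Label-free proteome statistics: per-protein one-way ANOVA across
# timepoints with BH correction, Tukey-Kramer post-hoc tests, replicate
# correlation QC, PCA scores and volcano tables.

# vectorised one-way fixed-effects ANOVA on rows of x, groups g (factor)
anova_rows <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g); N <- ncol(x)
  if (k < 2) stop_("ANOVA needs at least 2 groups")
  ns <- tabulate(g)
  if (any(ns < 2)) stop_("group '%s' has fewer than 2 replicates",
                         levels(g)[which(ns < 2)[1]])
  gm <- matrix(vapply(levels(g), function(l) rowMeans(x[, g == l, drop = FALSE]),
                      numeric(nrow(x))),
               nrow = nrow(x), dimnames = list(rownames(x), levels(g)))
  grand <- rowMeans(x)
  ssb <- rowSums(sweep((gm - grand)^2, 2, ns, "*"))
  ssw <- rowSums((x - gm[, as.integer(g)])^2)
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degen <- ssw == 0 & ssb == 0     # no variance anywhere: undefined
  f[degen] <- NA_real_; p[degen] <- NA_real_
  list(F = f, p = p, mse = msw, df2 = df2, group_means = gm, ns = ns,
       degenerate = degen)
}

#' Per-protein ANOVA across timepoints
#'
#' One-way fixed-effects ANOVA per feature on (by default) log2 abundance,
#' with BH correction across features. Per-timepoint log2 fold changes
#' versus native are mean differences of log2 abundance. Features with zero
#' variance everywhere get a missing p-value and are flagged.
#'
#' @param m an `omics_matrix` of protein abundances (>= 2 timepoints, >= 2
#'   replicates each).
#' @param log_transform log2-transform abundances first (default TRUE; set
#'   FALSE if the matrix is already on a log scale).
#' @return data frame with `feature_id`, `F`, `p`, `q`, `degenerate`, plus
#'   one `log2fc_<tp>` column per non-native timepoint.
#' @export
anova_by_feature <- function(m, log_transform = TRUE) {
  x <- m$values
  if (log_transform) x <- log2(x)
  g <- factor(m$samples$timepoint, levels = intersect(TIMEPOINTS, unique(m$samples$timepoint)))
  a <- anova_rows(x, g)
  pv <- a$p
  q <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  q[ok] <- bh_fdr(pv[ok])
  out <- data.frame(feature_id = rownames(x), F = a$F, p = pv, q = q,
                    degenerate = a$degenerate, stringsAsFactors = FALSE)
  for (tp in setdiff(levels(g), "native"))
    out[[paste0("log2fc_", tp)]] <- a$group_means[, tp] - a$group_means[, "native"]
  attr(out, "anova") <- a
  out
}

#' Tukey-Kramer post-hoc tests
#'
#' All pairwise timepoint comparisons per feature via the studentized-range
#' distribution, using the ANOVA mean square error; unequal group sizes use
#' the Tukey-Kramer standard error.
#'
#' @param m an `omics_matrix` of protein abundances.
#' @param feature_ids features to test (typically the ANOVA-significant
#'   ones).
#' @param log_transform as in [anova_by_feature()].
#' @return data frame with `feature_id`, `a`, `b` (the timepoint pair),
#'   `diff` (mean log2 difference, b minus a), and `p`.
#' @export
tukey_posthoc <- function(m, feature_ids, log_transform = TRUE) {
  x <- m$values[feature_ids, , drop = FALSE]
  if (log_transform) x <- log2(x)
  g <- factor(m$samples$timepoint, levels = intersect(TIMEPOINTS, unique(m$samples$timepoint)))
  a <- anova_rows(x, g)
  lv <- levels(g); k <- length(lv)
  pairs <- utils::combn(lv, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    n1 <- a$ns[match(l1, lv)]; n2 <- a$ns[match(l2, lv)]
    d <- a$group_means[, l2] - a$group_means[, l1]
    se <- sqrt(a$mse / 2 * (1 / n1 + 1 / n2))
    qstat <- abs(d) / se
    p <- stats::ptukey(qstat, nmeans = k, df = a$df2, lower.tail = FALSE)
    p[a$degenerate] <- NA_real_
    data.frame(feature_id = feature_ids, a = l1, b = l2, diff = d, p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Differential protein abundance versus native cells
#'
#' The full published gate, in order: per-protein ANOVA across timepoints
#' (BH `q < q_cut`), Tukey post-hoc `p < p_cut` for the timepoint against
#' native, and `|log2FC| > log2(fc_cut)`. Emits one `diff_table` per XXL
#' timepoint; its `p` column is the Tukey p-value (missing for proteins not
#' reaching the ANOVA gate) and `q` the ANOVA BH q-value.
#'
#' @param m an `omics_matrix` of protein abundances.
#' @param cfg a [pipeline_config()].
#' @param log_transform as in [anova_by_feature()].
#' @return list with `anova` (per-feature frame), `tukey` (post-hoc frame on
#'   ANOVA-significant features) and `diff` (named list of `diff_table`s).
#' @export
protein_differential <- function(m, cfg = pipeline_config(), log_transform = TRUE) {
  an <- anova_by_feature(m, log_transform)
  sig_ids <- an$feature_id[!is.na(an$q) & an$q < cfg$q_cut]
  tk <- if (length(sig_ids)) tukey_posthoc(m, sig_ids, log_transform) else
    data.frame(feature_id = character(0), a = character(0), b = character(0),
               diff = numeric(0), p = numeric(0))
  tps <- setdiff(intersect(TIMEPOINTS, unique(m$samples$timepoint)), "native")
  raw_means <- matrix(vapply(c("native", tps), function(tp)
    rowMeans(m$values[, m$samples$timepoint == tp, drop = FALSE]),
    numeric(nrow(m$values))),
    nrow = nrow(m$values), dimnames = list(rownames(m$values), c("native", tps)))
  diffs <- stats::setNames(lapply(tps, function(tp) {
    fc <- an[[paste0("log2fc_", tp)]]
    tk_t <- tk[(tk$a == "native" & tk$b == tp) | (tk$a == tp & tk$b == "native"), ]
    p <- tk_t$p[match(an$feature_id, tk_t$feature_id)]
    new_diff_table(an$feature_id, paste0(tp, "_vs_native"),
                   mean_ref = raw_means[, "native"], mean_alt = raw_means[, tp],
                   log2fc = fc, log2fc_raw = fc, p = p, q = an$q, cfg = cfg)
  }), tps)
  list(anova = an, tukey = tk, diff = diffs)
}

#' Count direction flips between two contrasts
#'
#' Reports how many features are significant in both contrasts with opposite
#' directions — the published observation is that no protein flips between
#' 3d and 7d; here it is a check, not an assumption.
#'
#' @param d_a,d_b two `diff_table`s over the same features.
#' @return integer count of direction-flipping features.
#' @export
direction_flip_count <- function(d_a, d_b) {
  j <- merge(d_a[c("feature_id", "significant", "direction")],
             d_b[c("feature_id", "significant", "direction")],
             by = "feature_id", suffixes = c("_a", "_b"))
  sum(j$significant_a & j$significant_b & j$direction_a != j$direction_b &
        j$direction_a != "none" & j$direction_b != "none")
}

#' Pairwise replicate correlation
#'
#' Pearson correlation between samples on log2 abundance over shared
#' quantified features. Constant samples yield missing correlations.
#'
#' @param m an `omics_matrix` of protein abundances (values > 0).
#' @param log_transform log2-transform first (default TRUE).
#' @return sample-by-sample correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(m, log_transform = TRUE) {
  if (ncol(m$values) < 2) stop_("need at least 2 samples")
  x <- m$values
  if (log_transform) x <- log2(x)
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}

#' Principal component scores of samples
#'
#' Features with missing values are dropped (complete-case); each feature is
#' centred, and the scores are the projections of samples onto the top
#' right-singular vectors. The sign of each component is fixed by forcing
#' the loading of the first feature to be non-negative, so runs are
#' reproducible.
#'
#' @param m an `omics_matrix`.
#' @param n_components number of components (default 2).
#' @param log_transform log2-transform first (default TRUE).
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `eigenvalues` (all, not just top-k).
#' @export
pca_scores <- function(m, n_components = 2, log_transform = TRUE) {
  x <- m$values
  if (log_transform) x <- log2(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < n_components) stop_("fewer samples than requested components")
  xc <- x - rowMeans(x)
  sv <- svd(t(xc))               # samples x features
  k <- seq_len(n_components)
  flip <- ifelse(sv$v[1, k] < 0, -1, 1)
  scores <- sweep(sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components), 2, flip, "*")
  loadings <- sweep(sv$v[, k, drop = FALSE], 2, flip, "*")
  rownames(scores) <- colnames(x)
  rownames(loadings) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", k)
  list(scores = scores, loadings = loadings, eigenvalues = sv$d^2)
}

#' Volcano-plot table
#'
#' @param diff a `diff_table`.
#' @return data frame with `feature_id`, `log2fc`, `neg_log10_p` (p floored
#'   at the smallest positive double) and `significant`.
#' @export
volcano_table <- function(diff) {
  data.frame(feature_id = diff$feature_id, log2fc = diff$log2fc,
             neg_log10_p = -log10(pmax(diff$p, .Machine$double.xmin)),
             significant = diff$significant, stringsAsFactors = FALSE)
}
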