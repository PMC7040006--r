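#' Pipeline thresholds
#'
#' The shared significance rule of the whole pipeline: a feature is called
#' regulated when `p < p_cut`, BH `q < q_cut` and fold change `> fc_cut`
#' (i.e. `|log2FC| > log2(fc_cut)`). `cpm_floor` is the low-expression filter
#' (mean CPM at at least one timepoint must exceed it), `cpm_high` the
#' highly-expressed cutoff used to shortlist miRNAs, `min_support` the
#' minimum number of prediction algorithms required for a network edge.
#'
#' @param p_cut per-test p-value cutoff (default 0.01).
#' @param q_cut BH q-value cutoff (default 0.05).
#' @param fc_cut fold-change cutoff on the natural scale (default 1.5).
#' @param cpm_floor CPM floor for the low-expression filter (default 1).
#' @param cpm_high mean-CPM threshold defining highly expressed miRNAs
#'   (default 100).
#' @param min_support minimum number of supporting prediction algorithms for
#'   a network edge (default 5).
#' @param n_algorithms number of prediction algorithms (default 12).
#' @param pseudocount pseudocount added to mean CPM for the test's effect
#'   column (default 0.5); the reported fold-change column always uses 0.
#' @param seed optional integer seed recorded alongside results.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_cut = 0.01, q_cut = 0.05, fc_cut = 1.5,
                            cpm_floor = 1, cpm_high = 100,
                            min_support = 5, n_algorithms = 12,
                            pseudocount = 0.5, seed = NULL) {
  if (!(p_cut > 0 && p_cut <= 1)) stop_("p_cut must be in (0, 1]")
  if (!(q_cut > 0 && q_cut <= 1)) stop_("q_cut must be in (0, 1]")
  if (!(fc_cut > 1)) stop_("fc_cut must exceed 1")
  if (cpm_floor < 0) stop_("cpm_floor must be non-negative")
  if (!(min_support >= 1 && min_support <= n_algorithms))
    stop_("min_support must lie in [1, n_algorithms]")
  if (pseudocount < 0) stop_("pseudocount must be non-negative")
  structure(list(p_cut = p_cut, q_cut = q_cut, fc_cut = fc_cut,
                 cpm_floor = cpm_floor, cpm_high = cpm_high,
                 min_support = as.integer(min_support),
                 n_algorithms = as.integer(n_algorithms),
                 pseudocount = pseudocount, seed = seed),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "pipeline_config: p<%g, q<%g, FC>%g, CPM floor %g, CPM high %g, support >= %d/%d\n",
    x$p_cut, x$q_cut, x$fc_cut, x$cpm_floor, x$cpm_high,
    x$min_support, x$n_algorithms))
  invisible(x)
}
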