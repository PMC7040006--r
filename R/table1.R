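# The packaged expression table of highly expressed regulated miRNAs:
# mean CPM at four timepoints, printed log2 fold changes to one decimal, and
# per-timepoint significance flags. Used to check that the ratio-of-means
# fold-change convention and the set logic reproduce the published summary.

#' Read the packaged miRNA expression table
#'
#' @param path path to the TSV; defaults to the copy shipped with the
#'   package.
#' @return data frame of class `table1` with columns `mirna`, `regulation`
#'   (`down`/`up` section), four mean-CPM columns, three printed log2FC
#'   columns, three significance flags, and the `transfected`/`acceptance`
#'   marker columns.
#' @export
read_table1 <- function(path = system.file("extdata", "table1_mirna.tsv",
                                           package = "mirfine")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "regulation", "cpm_native", "cpm_d3", "cpm_d7", "cpm_d14",
            "log2fc_d3", "log2fc_d7", "log2fc_d14",
            "sig_d3", "sig_d7", "sig_d14")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_("table is missing column(s): %s", paste(miss, collapse = ", "))
  class(tab) <- c("table1", "data.frame")
  tab
}

#' Recompute printed log2 fold changes from the printed CPM means
#'
#' For every row and XXL timepoint, recomputes `log2(mean CPM_t / mean
#' CPM_native)` from the table's CPM columns, rounds half away from zero to
#' one decimal, and compares with the printed value.
#'
#' @param tab a `table1` data frame.
#' @param digits decimals of the printed values (default 1).
#' @return long data frame with one row per (miRNA, timepoint):
#'   `recomputed` (unrounded), `rounded`, `printed`, `dev` (unrounded minus
#'   printed) and `match`.
#' @export
recompute_table1_fc <- function(tab, digits = 1) {
  tps <- c("d3", "d7", "d14")
  out <- do.call(rbind, lapply(tps, function(tp) {
    fc <- log2(tab[[paste0("cpm_", tp)]] / tab$cpm_native)
    printed <- tab[[paste0("log2fc_", tp)]]
    data.frame(mirna = tab$mirna, timepoint = tp,
               recomputed = fc, rounded = round_half_away(fc, digits),
               printed = printed, dev = fc - printed,
               match = round_half_away(fc, digits) == printed,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Highly expressed regulated miRNA sets
#'
#' The published shortlist logic: miRNAs *downregulated from* a mean CPM
#' above `cpm_high` in native cells, and miRNAs *upregulated to* a mean CPM
#' above `cpm_high` at one or more XXL timepoints.
#'
#' @param tab a `table1` data frame (or any frame with `regulation` and the
#'   four CPM columns).
#' @param cpm_high CPM threshold (default 100, strict inequality).
#' @return list with character vectors `down` and `up`.
#' @export
classify_cpm100 <- function(tab, cpm_high = 100) {
  xxl_high <- tab$cpm_d3 > cpm_high | tab$cpm_d7 > cpm_high | tab$cpm_d14 > cpm_high
  list(down = tab$mirna[tab$regulation == "down" & tab$cpm_native > cpm_high],
       up = tab$mirna[tab$regulation == "up" & xxl_high])
}

#' Per-timepoint differential tables derived from the printed table
#'
#' Converts the printed log2 fold changes and significance flags into
#' minimal `diff_table`-shaped frames, one per XXL timepoint, so the
#' consistent-direction selection can run on the published values.
#'
#' @param tab a `table1` data frame.
#' @return named list of data frames (`d3`, `d7`, `d14`) with `feature_id`,
#'   `log2fc`, `significant` and `direction` columns.
#' @export
table1_difftables <- function(tab) {
  stats::setNames(lapply(c("d3", "d7", "d14"), function(tp) {
    fc <- tab[[paste0("log2fc_", tp)]]
    sig <- tab[[paste0("sig_", tp)]]
    data.frame(feature_id = tab$mirna, log2fc = fc, significant = sig,
               direction = direction_of(fc, sig), stringsAsFactors = FALSE)
  }), c("d3", "d7", "d14"))
}
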