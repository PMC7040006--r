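# Internal helpers shared across modules.

TIMEPOINTS <- c("native", "d3", "d7", "d14")
MODALITIES <- c("mrna_counts", "mirna_counts", "protein_abundance")

#' Round half away from zero
#'
#' Commercial rounding used when comparing recomputed log2 fold changes with
#' values printed to one decimal: 0.05 rounds to 0.1, -0.05 to -0.1
#' (unlike [round()], which rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# format doubles so that write-then-read round-trips exactly
fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 2^53, sprintf("%.0f", x),
                sprintf("%.17g", x)))
}

is_count_modality <- function(modality) {
  modality %in% c("mrna_counts", "mirna_counts")
}

#' Regulation direction from fold change and significance
#'
#' `up`/`down` for significant features according to the sign of the fold
#' change, `none` otherwise.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param significant logical vector.
#' @return character vector of directions.
#' @export
direction_of <- function(log2fc, significant) {
  d <- rep("none", length(log2fc))
  d[significant & log2fc > 0] <- "up"
  d[significant & log2fc < 0] <- "down"
  d
}
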