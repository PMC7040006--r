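# miRNA-target prediction handling and the inverse-regulation /
# transfection-crossmatch workflows.

#' The twelve target-prediction algorithms
#'
#' Canonical names of the individual algorithms whose combined output makes
#' up a prediction table; the per-pair support count is the number of
#' distinct algorithms reporting the pair (1-12).
#'
#' @export
PREDICTION_ALGORITHMS <- c("miRWalk", "miRDB", "PITA", "MicroT4", "miRMap",
                           "RNA22", "miRanda", "miRNAMap", "RNAhybrid",
                           "miRBridge", "PicTar2", "Targetscan")

#' Canonical miRNA names
#'
#' Case-insensitive normalisation with an optional `hsa-` prefix on input;
#' names are stored with the prefix and conventional capitalisation
#' (`hsa-miR-221-5p`, `hsa-let-7i-5p`).
#'
#' @param x character vector of miRNA names.
#' @return canonical names.
#' @export
normalize_mirna <- function(x) {
  body <- tolower(sub("^hsa-", "", x, ignore.case = TRUE))
  body <- sub("^mir", "miR", body)
  paste0("hsa-", body)
}

#' Build a validated prediction table
#'
#' Long format: one row per (miRNA, gene, algorithm) triple. Algorithm names
#' must come from [PREDICTION_ALGORITHMS] (an unknown name is an error that
#' lists the offenders); duplicate triples — e.g. from transcript isoforms —
#' are collapsed, so support counts distinct algorithms only.
#'
#' @param df data frame with columns `mirna`, `gene_id`, `algorithm`.
#' @return data frame of class `prediction_table`.
#' @export
prediction_table <- function(df) {
  need <- c("mirna", "gene_id", "algorithm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("prediction table lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$algorithm), PREDICTION_ALGORITHMS)
  if (length(bad)) stop_("unknown prediction algorithm(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(mirna = normalize_mirna(df$mirna),
                    gene_id = as.character(df$gene_id),
                    algorithm = as.character(df$algorithm),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Read a prediction table from TSV
#'
#' @param path TSV with columns `mirna`, `gene_id`, `algorithm`.
#' @return a `prediction_table`.
#' @export
read_predictions <- function(path) {
  prediction_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Per-pair support counts
#'
#' @param pred a `prediction_table`.
#' @param mirnas optional miRNA subset (canonicalised).
#' @return data frame with `mirna`, `gene_id`, `support` (distinct
#'   algorithms) and `algorithms` (comma-joined names).
#' @export
support_counts <- function(pred, mirnas = NULL) {
  if (!is.null(mirnas)) pred <- pred[pred$mirna %in% normalize_mirna(mirnas), , drop = FALSE]
  if (nrow(pred) == 0)
    return(data.frame(mirna = character(0), gene_id = character(0),
                      support = integer(0), algorithms = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(pred$mirna, pred$gene_id, sep = "\r")
  alg <- split(pred$algorithm, key)
  first <- pred[!duplicated(key), c("mirna", "gene_id")]
  first <- first[match(names(alg), paste(first$mirna, first$gene_id, sep = "\r")), ]
  out <- data.frame(first, support = lengths(alg),
                    algorithms = vapply(alg, function(a)
                      paste(sort(a), collapse = ","), character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$mirna, out$gene_id), , drop = FALSE]
}

#' Filter predicted pairs by algorithm support
#'
#' @param pred a `prediction_table`.
#' @param mirnas miRNAs of interest.
#' @param min_support minimum number of distinct predicting algorithms
#'   (default 5).
#' @return data frame of retained pairs with their support counts.
#' @export
support_filter <- function(pred, mirnas, min_support = 5) {
  if (min_support < 1 || min_support > length(PREDICTION_ALGORITHMS))
    stop_("min_support must lie in [1, %d]", length(PREDICTION_ALGORITHMS))
  sc <- support_counts(pred, mirnas)
  out <- sc[sc$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significant protein directions over the time course
#'
#' Union of proteins significant at 3d and/or 7d; the direction is taken
#' from whichever timepoint is significant and, when both are, they must
#' agree (a direction flip is a validation error).
#'
#' @param d3,d7 protein `diff_table`s.
#' @return data frame with `protein_id` and `direction`.
#' @export
timecourse_directions <- function(d3, d7) {
  j <- merge(d3[c("feature_id", "significant", "direction")],
             d7[c("feature_id", "significant", "direction")],
             by = "feature_id", all = TRUE, suffixes = c("_d3", "_d7"))
  j$significant_d3[is.na(j$significant_d3)] <- FALSE
  j$significant_d7[is.na(j$significant_d7)] <- FALSE
  keep <- j$significant_d3 | j$significant_d7
  j <- j[keep, , drop = FALSE]
  both <- j$significant_d3 & j$significant_d7
  flip <- both & j$direction_d3 != j$direction_d7
  if (any(flip))
    stop_("direction flip between 3d and 7d for: %s",
          paste(j$feature_id[flip], collapse = ", "))
  data.frame(protein_id = j$feature_id,
             direction = ifelse(j$significant_d3, j$direction_d3, j$direction_d7),
             stringsAsFactors = FALSE)
}

#' Bipartite network of regulated miRNAs and inversely regulated targets
#'
#' Connects each miRNA of the given direction with every significant protein
#' of the opposite direction whose gene is predicted as a target of that
#' miRNA by at least `min_support` algorithms. Protein nodes carry the
#' number of predicting miRNAs (their degree).
#'
#' @param mirna_set data frame with `feature_id` (miRNA) and `direction`
#'   (from [select_consistent_mirnas()]).
#' @param protein_dirs data frame with `protein_id`, `direction` (from
#'   [timecourse_directions()]).
#' @param pred a `prediction_table`.
#' @param map a [gene_protein_map()] translating predicted genes to
#'   proteins.
#' @param direction `"down-up"` (down miRNAs vs up proteins) or `"up-down"`.
#' @param min_support minimum algorithm support per edge (default 5).
#' @return an object of class `mir_target_network`.
#' @export
build_inverse_network <- function(mirna_set, protein_dirs, pred, map,
                                  direction = c("down-up", "up-down"),
                                  min_support = 5) {
  direction <- match.arg(direction)
  mdir <- if (direction == "down-up") "down" else "up"
  pdir <- if (direction == "down-up") "up" else "down"
  mirnas <- normalize_mirna(mirna_set$feature_id[mirna_set$direction == mdir])
  prots <- protein_dirs[protein_dirs$direction == pdir, , drop = FALSE]
  edges <- data.frame(mirna = character(0), protein_id = character(0),
                      support = integer(0), algorithms = character(0),
                      stringsAsFactors = FALSE)
  if (length(mirnas) && nrow(prots)) {
    sf <- support_filter(pred, mirnas, min_support)
    sf <- merge(sf, map, by = "gene_id")
    sf <- sf[sf$protein_id %in% prots$protein_id, , drop = FALSE]
    edges <- sf[order(sf$mirna, sf$protein_id),
                c("mirna", "protein_id", "support", "algorithms")]
    rownames(edges) <- NULL
  }
  deg <- table(edges$protein_id)
  prot_nodes <- data.frame(protein_id = names(deg),
                           direction = rep(pdir, length(deg)),
                           n_predicting_mirnas = as.integer(deg),
                           stringsAsFactors = FALSE)
  net <- structure(list(
    mirnas = data.frame(name = mirnas, direction = mdir, stringsAsFactors = FALSE),
    proteins = prot_nodes, edges = edges,
    min_support = as.integer(min_support), direction = direction),
    class = "mir_target_network")
  net
}

#' @export
print.mir_target_network <- function(x, ...) {
  cat(sprintf("mir_target_network (%s, support >= %d): %d miRNAs, %d proteins, %d edges\n",
              x$direction, x$min_support, nrow(x$mirnas), nrow(x$proteins),
              nrow(x$edges)))
  invisible(x)
}

#' Differential abundance in transfected versus control cells
#'
#' Per-protein two-sided Welch t-test on log2 abundance between transfected
#' and control-siRNA samples, BH correction, and the shared significance
#' gate.
#'
#' @param trans,control `omics_matrix` objects of protein abundances at 3d
#'   (>= 2 replicates each); group sizes may differ.
#' @param cfg a [pipeline_config()].
#' @return a `diff_table` (`log2fc` is transfected minus control, in log2).
#' @export
transfection_diff <- function(trans, control, cfg = pipeline_config()) {
  common <- intersect(rownames(trans$values), rownames(control$values))
  if (ncol(trans$values) < 2) stop_("group 'transfected' has fewer than 2 replicates")
  if (ncol(control$values) < 2) stop_("group 'control' has fewer than 2 replicates")
  lt <- log2(trans$values[common, , drop = FALSE])
  lc <- log2(control$values[common, , drop = FALSE])
  w <- welch_rows(lt, lc)
  q <- qvals_na(w$p)
  new_diff_table(common, "transfected_vs_control",
                 mean_ref = rowMeans(control$values[common, , drop = FALSE]),
                 mean_alt = rowMeans(trans$values[common, , drop = FALSE]),
                 log2fc = w$diff, log2fc_raw = w$diff, p = w$p, q = q, cfg = cfg)
}

#' Transfection-response crossmatch
#'
#' The set-algebra workflow behind the transfection experiments: from the
#' quantified proteins of a transfection experiment, count the predicted
#' targets of the transfected miRNA, the proteins regulated in each
#' direction, the regulated-in-the-expected-direction predicted targets
#' (expected: lower abundance after a mimic, higher after an inhibitor),
#' and their overlap with the predicted targets that were inversely
#' regulated in the non-transfected time course (inverse = opposite to the
#' transfection's expected effect).
#'
#' @param diff `diff_table` from [transfection_diff()] (features = the
#'   quantified proteins).
#' @param pred a `prediction_table`.
#' @param mirna the transfected miRNA.
#' @param mode `"mimic"` or `"inhibitor"`.
#' @param timecourse_inverse data frame with `protein_id`, `direction`: the
#'   significant time-course proteins (from [timecourse_directions()]).
#' @param map a [gene_protein_map()].
#' @param support_rule `"any"` (predicted by >= 1 algorithm, the convention
#'   for transfection crossmatches) or an integer minimum support.
#' @return one-row data frame of class `crossmatch_report`.
#' @export
crossmatch <- function(diff, pred, mirna, mode = c("mimic", "inhibitor"),
                       timecourse_inverse, map, support_rule = "any") {
  mode <- match.arg(mode)
  mirna <- normalize_mirna(mirna)
  if (!mirna %in% pred$mirna) stop_("miRNA %s absent from the prediction table", mirna)
  min_sup <- if (identical(support_rule, "any")) 1L else as.integer(support_rule)
  quantified <- unique(diff$feature_id)
  pred_genes <- support_filter(pred, mirna, min_sup)$gene_id
  pred_prots <- unique(map$protein_id[map$gene_id %in% pred_genes])
  predicted <- intersect(quantified, pred_prots)
  up <- diff$feature_id[diff$significant & diff$direction == "up"]
  down <- diff$feature_id[diff$significant & diff$direction == "down"]
  expected_dir <- if (mode == "mimic") "down" else "up"
  reg_expected <- if (expected_dir == "down") down else up
  reg_expected_pred <- intersect(reg_expected, predicted)
  tc_dir <- if (expected_dir == "down") "up" else "down"
  tc_set <- timecourse_inverse$protein_id[timecourse_inverse$direction == tc_dir]
  tc_inverse_pred <- intersect(tc_set, pred_prots)
  out <- data.frame(
    mirna = mirna, mode = mode,
    n_quantified = length(quantified),
    n_predicted_of_quantified = length(predicted),
    n_regulated_up = length(up),
    n_regulated_down = length(down),
    n_regulated_expected_direction_and_predicted = length(reg_expected_pred),
    n_inverse_regulated_predicted_in_timecourse = length(tc_inverse_pred),
    n_overlap = length(intersect(reg_expected_pred, tc_inverse_pred)),
    stringsAsFactors = FALSE)
  class(out) <- c("crossmatch_report", "data.frame")
  out
}

#' Fraction of quantified proteins that are predicted targets
#'
#' @param quantified character vector of quantified protein IDs.
#' @param pred a `prediction_table`.
#' @param mirna the miRNA of interest.
#' @param map a [gene_protein_map()].
#' @return fraction of quantified proteins predicted by >= 1 algorithm.
#' @export
predicted_coverage_check <- function(quantified, pred, mirna, map) {
  if (length(quantified) == 0) stop_("empty quantified set")
  genes <- support_filter(pred, normalize_mirna(mirna), 1)$gene_id
  prots <- unique(map$protein_id[map$gene_id %in% genes])
  length(intersect(quantified, prots)) / length(unique(quantified))
}
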